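#' Configuration for the synthetic multi-environment trial generator
#'
#' Bundles every knob of the synthetic Genomes-to-Fields-shaped data generator
#' into a validated list.  The defaults describe a desk-scale maize hybrid
#' trial network: a few hundred hybrids genotyped at biallelic variants, grown
#' over a grid of locations (grouped into states) by years, with unbalanced,
#' climate-adapted sampling of hybrids into environments, environment means
#' partly driven by environmental covariates, additive marker genetics with
#' environment-specific variances and between-environment genetic
#' correlations, heteroscedastic residuals, and injected quality-control
#' artifacts (yield outliers, low stand counts, disease trials).
#'
#' @param n_hybrids Number of hybrids (>= 2).
#' @param n_markers Number of biallelic variants (>= 1).
#' @param n_locations Number of field locations; each belongs to one state.
#' @param n_years Number of trial years; every location runs every year, so the
#'   simulation has `n_locations * n_years` environments.
#' @param n_states Number of states the locations are spread over.
#' @param h2_within_env Plot-level within-environment heritability in `[0, 1)`:
#'   the ratio of genetic to genetic-plus-residual variance inside each
#'   environment (exact per environment by construction).
#' @param var_env_mean Variance of environment mean yield, (Mg/ha)^2.  Split
#'   50% environmental covariates, 30% location effects, 20% year effects.
#' @param var_within_env Average within-environment phenotypic variance
#'   (genetic + residual), (Mg/ha)^2; scaled per environment by a
#'   covariate-driven factor so residuals are heteroscedastic.
#' @param rho_gxe_within_state Genetic correlation between environments in the
#'   same state.
#' @param rho_gxe_between_state Genetic correlation between environments in
#'   different states.
#' @param frac_hybrids_per_env Fraction of hybrids grown in each environment
#'   (in `(0, 1]`); hybrids "adapted" to an environment's state are
#'   oversampled 3:1, so environments within a state share more hybrids.
#' @param outlier_rate Fraction of plots replaced by gross yield outliers at
#'   +/- 6 within-environment SD.
#' @param low_stand_rate Fraction of plots given a stand count drawn uniformly
#'   from 5..19 (below the usual quality-control threshold of 20).
#' @param disease_trial_rate Fraction of environments tagged as disease trials
#'   in their treatment string.
#' @param seed Integer seed; fixed seed gives bit-identical bundles.
#'
#' @return A list of class `gxe_sim_config`.
#' @examples
#' cfg <- sim_config(n_hybrids = 50, n_markers = 100, seed = 1)
#' @export
sim_config <- function(n_hybrids = 300,
                       n_markers = 1000,
                       n_locations = 8,
                       n_years = 4,
                       n_states = 4,
                       h2_within_env = 0.5,
                       var_env_mean = 4,
                       var_within_env = 2.25,
                       rho_gxe_within_state = 0.7,
                       rho_gxe_between_state = 0.4,
                       frac_hybrids_per_env = 0.25,
                       outlier_rate = 0.01,
                       low_stand_rate = 0.01,
                       disease_trial_rate = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_hybrids = n_hybrids, n_markers = n_markers,
    n_locations = n_locations, n_years = n_years, n_states = n_states,
    h2_within_env = h2_within_env, var_env_mean = var_env_mean,
    var_within_env = var_within_env,
    rho_gxe_within_state = rho_gxe_within_state,
    rho_gxe_between_state = rho_gxe_between_state,
    frac_hybrids_per_env = frac_hybrids_per_env,
    outlier_rate = outlier_rate, low_stand_rate = low_stand_rate,
    disease_trial_rate = disease_trial_rate, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "gxe_sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_hybrids", "n_markers", "n_locations", "n_years", "n_states")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != round(v)) {
      stop_gxe(sprintf("`%s` must be a positive integer (got %s)", nm, format(v)),
               class = "gxe_config_error")
    }
  }
  if (cfg$n_hybrids < 2) {
    stop_gxe("`n_hybrids` must be at least 2", class = "gxe_config_error")
  }
  fracs <- c("h2_within_env", "frac_hybrids_per_env", "outlier_rate",
             "low_stand_rate", "disease_trial_rate")
  for (nm in fracs) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop_gxe(sprintf("`%s` must be a fraction in [0, 1]", nm),
               class = "gxe_config_error")
    }
  }
  if (cfg$h2_within_env >= 1) {
    stop_gxe("`h2_within_env` must be < 1 (some residual variance is required)",
             class = "gxe_config_error")
  }
  for (nm in c("rho_gxe_within_state", "rho_gxe_between_state")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < -1 || v > 1) {
      stop_gxe(sprintf("`%s` must be a correlation in [-1, 1]", nm),
               class = "gxe_config_error")
    }
  }
  for (nm in c("var_env_mean", "var_within_env")) {
    if (cfg[[nm]] < 0) {
      stop_gxe(sprintf("`%s` must be non-negative", nm), class = "gxe_config_error")
    }
  }
  if (cfg$frac_hybrids_per_env * cfg$n_hybrids < 2) {
    stop_gxe("`frac_hybrids_per_env * n_hybrids` must be at least 2",
             class = "gxe_config_error")
  }
  if (cfg$n_states > cfg$n_locations) {
    stop_gxe("`n_states` cannot exceed `n_locations`", class = "gxe_config_error")
  }
  invisible(cfg)
}

#' @export
print.gxe_sim_config <- function(x, ...) {
  cat("<gxe_sim_config>\n")
  cat(sprintf("  %d hybrids x %d markers; %d locations x %d years (%d states)\n",
              x$n_hybrids, x$n_markers, x$n_locations, x$n_years, x$n_states))
  cat(sprintf("  h2 within env %.2f; rho GxE within/between state %.2f/%.2f\n",
              x$h2_within_env, x$rho_gxe_within_state, x$rho_gxe_between_state))
  cat(sprintf("  frac hybrids/env %.2f; artifacts: outlier %.3f, low-stand %.3f, disease %.3f\n",
              x$frac_hybrids_per_env, x$outlier_rate, x$low_stand_rate,
              x$disease_trial_rate))
  invisible(x)
}
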