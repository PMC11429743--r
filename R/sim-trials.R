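#' Simulate plot-level trials, metadata, covariates and ground truth
#'
#' Generates a full multi-environment hybrid trial from a marker matrix under
#' the additive model `phenotype = environment mean + environment-specific
#' genetic value + block effect + heteroscedastic noise`, where the matrix of
#' genetic values over hybrids and environments is drawn with Kronecker
#' covariance `Sigma_g (x) K` (between-environment genetic covariance crossed
#' with the additive genomic relationship of the simulated markers).
#'
#' Environments are every location-by-year combination.  Each environment
#' grows a stratified sample of hybrids (`frac_hybrids_per_env`, with hybrids
#' "adapted" to the environment's state oversampled 3:1, so environments in
#' the same state share more hybrids), with two replicates per hybrid.
#' Environment means are a linear function of three environmental covariates
#' plus location, year, irrigation, treatment and previous-crop effects.
#' The between-environment genetic correlation matrix is block-structured
#' (within-state vs between-state) and projected to the nearest PSD matrix;
#' per-environment genetic variances scale with a covariate so residuals are
#' heteroscedastic while the plot-level within-environment heritability stays
#' exactly `h2_within_env`.
#'
#' Quality-control artifacts are injected in disjoint plot sets and flagged in
#' the truth bundle: gross outliers at +/- 6 realized within-environment SD,
#' low stand counts drawn uniformly from 5..19, and whole environments tagged
#' "Disease trial" in their treatment string.
#'
#' @param config A [sim_config()].
#' @param markers A `gxe_marker_matrix` from [simulate_marker_matrix()].
#' @return A list of class `gxe_bundle` with elements `trials` (plot-level
#'   tibble), `meta` (environment metadata tibble), `ec` (environment
#'   covariates tibble), `truth` (`gxe_truth` list: `env` tibble with true
#'   means/SDs, `genetic_values` hybrid-by-environment matrix, `Sigma_g`,
#'   `artifacts` plot-level flag tibble), `markers`, and `template` (the
#'   test-year submission template: final-year environments by their sampled
#'   hybrids, `yield_mg_ha` empty).
#' @examples
#' cfg <- sim_config(n_hybrids = 40, n_markers = 100, n_locations = 4,
#'                   n_years = 2, n_states = 2, seed = 1)
#' b <- simulate_trials(cfg, simulate_marker_matrix(cfg))
#' dplyr::count(b$trials, env_id)
#' @export
simulate_trials <- function(config, markers) {
  stopifnot(inherits(config, "gxe_sim_config"), inherits(markers, "gxe_marker_matrix"))
  validate_sim_config(config)
  n <- config$n_hybrids
  if (nrow(markers$dosage) != n) {
    stop_gxe("marker matrix does not match `n_hybrids` in the config",
             "gxe_config_error")
  }
  n_env_hyb <- max(2L, round(config$frac_hybrids_per_env * n))
  set.seed(config$seed + 1L)

  hybrids <- markers$hybrids
  years <- 2014L + seq_len(config$n_years) - 1L
  loc <- sprintf("L%02d", seq_len(config$n_locations))
  loc_state <- sprintf("ST%d", rep_len(seq_len(config$n_states), config$n_locations))
  envs <- tidyr::expand_grid(location_code = loc, year = years) |>
    dplyr::mutate(env_id = paste0(.data$location_code, "_", .data$year)) |>
    dplyr::left_join(tibble::tibble(location_code = loc, state = loc_state),
                     by = "location_code")
  E <- nrow(envs)

  # --- environment metadata ---------------------------------------------------
  state_lat <- 32 + 2.5 * seq_len(config$n_states)
  state_lon <- -104 + 3 * seq_len(config$n_states)
  loc_irr <- runif(config$n_locations) < 0.3
  loc_lat <- state_lat[match(loc_state, sprintf("ST%d", seq_len(config$n_states)))] +
    runif(config$n_locations, -0.8, 0.8)
  loc_lon <- state_lon[match(loc_state, sprintf("ST%d", seq_len(config$n_states)))] +
    runif(config$n_locations, -0.8, 0.8)
  treat_pool <- c("Standard", "Dryland stress", "Late planted")
  prev_pool <- c("Soybean", "Corn", "Wheat", "Fallow", "Cotton")
  meta <- envs |>
    dplyr::mutate(
      station = .data$location_code,
      latitude = loc_lat[match(.data$location_code, loc)],
      longitude = loc_lon[match(.data$location_code, loc)],
      irrigated = loc_irr[match(.data$location_code, loc)],
      treatment = sample(treat_pool, E, replace = TRUE, prob = c(0.7, 0.15, 0.15)),
      previous_crop = sample(prev_pool, E, replace = TRUE)
    )
  disease_env <- runif(E) < config$disease_trial_rate
  meta$treatment[disease_env] <- "Disease trial"

  # --- environmental covariates ----------------------------------------------
  q <- 6L
  ec_mat <- matrix(rnorm(E * q), E, q, dimnames = list(meta$env_id, paste0("ec", 1:q)))
  ec <- tibble::as_tibble(ec_mat, rownames = "env_id")

  # --- environment means ------------------------------------------------------
  v <- config$var_env_mean
  beta_ec <- sqrt(0.5 * v / 3)
  loc_eff <- rnorm(config$n_locations, 0, sqrt(0.3 * v))
  yr_eff <- rnorm(config$n_years, 0, sqrt(0.2 * v))
  treat_eff <- c("Standard" = 0, "Dryland stress" = -0.8, "Late planted" = -0.5,
                 "Disease trial" = -1)
  prev_eff <- c(Soybean = 0.3, Corn = -0.2, Wheat = 0.1, Fallow = 0, Cotton = 0)
  mu_cov <- drop(ec_mat[, 1:3] %*% rep(beta_ec, 3))
  mu <- 10 + mu_cov +
    loc_eff[match(meta$location_code, loc)] +
    yr_eff[match(meta$year, years)] +
    0.5 * meta$irrigated +
    treat_eff[meta$treatment] +
    prev_eff[meta$previous_crop]
  mu <- unname(mu)

  # --- genetic covariance and genetic values ---------------------------------
  same_state <- outer(meta$state, meta$state, "==")
  R <- ifelse(same_state, config$rho_gxe_within_state, config$rho_gxe_between_state)
  diag(R) <- 1
  R <- project_psd(R, floor_frac = 0)
  d <- sqrt(diag(R))
  R <- R / outer(d, d)  # back to unit diagonal after projection
  s_env <- exp(0.3 * ec_mat[, 4])
  s_env <- s_env / mean(s_env)
  vg <- config$h2_within_env * config$var_within_env * s_env
  if (config$h2_within_env > 0) {
    ve <- vg * (1 - config$h2_within_env) / config$h2_within_env
  } else {
    ve <- config$var_within_env * s_env
  }
  Sigma_g <- outer(sqrt(vg), sqrt(vg)) * R
  dimnames(Sigma_g) <- list(meta$env_id, meta$env_id)

  K <- additive_grm(markers)$matrix
  G <- mat_sqrt(K) %*% matrix(rnorm(n * E), n, E) %*% t(mat_sqrt(Sigma_g))
  dimnames(G) <- list(hybrids, meta$env_id)

  # --- incidence: stratified, climate-adapted sampling ------------------------
  hyb_state <- sample(rep_len(sprintf("ST%d", seq_len(config$n_states)), n))
  env_hybrids <- lapply(seq_len(E), function(j) {
    w <- ifelse(hyb_state == meta$state[j], 3, 1)
    sort(sample(hybrids, n_env_hyb, prob = w))
  })

  # --- plot records -----------------------------------------------------------
  block_sd <- 0.3
  trials <- purrr::map_dfr(seq_len(E), function(j) {
    h <- env_hybrids[[j]]
    b_eff <- rnorm(2, 0, block_sd)
    tidyr::expand_grid(hybrid = h, replicate = 1:2) |>
      dplyr::mutate(
        env_id = meta$env_id[j], year = meta$year[j],
        location_code = meta$location_code[j],
        yield_mg_ha = mu[j] + G[.data$hybrid, j] + b_eff[.data$replicate] +
          rnorm(dplyr::n(), 0, sqrt(ve[j])),
        block = paste0("B", .data$replicate)
      )
  })
  trials <- trials |>
    dplyr::mutate(
      stand_count = pmax(20L, as.integer(round(rnorm(dplyr::n(), 75, 5)))),
      discarded_flag = FALSE,
      plot_id = dplyr::row_number()
    )

  # --- artifact injection (disjoint plot sets, outside disease trials) -------
  eligible <- trials$plot_id[!(trials$env_id %in% meta$env_id[disease_env])]
  n_out <- rbinom(1, length(eligible), config$outlier_rate)
  out_ids <- sample(eligible, n_out)
  n_low <- rbinom(1, length(eligible) - n_out, config$low_stand_rate)
  low_ids <- sample(setdiff(eligible, out_ids), n_low)
  env_stats <- trials |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(m = mean(.data$yield_mg_ha), s = sd(.data$yield_mg_ha))
  if (n_out > 0) {
    idx <- match(trials$env_id[out_ids], env_stats$env_id)
    trials$yield_mg_ha[out_ids] <- env_stats$m[idx] +
      sample(c(-6, 6), n_out, replace = TRUE) * env_stats$s[idx]
  }
  if (n_low > 0) {
    trials$stand_count[low_ids] <- sample(5:19, n_low, replace = TRUE)
  }
  artifacts <- trials |>
    dplyr::transmute(
      .data$plot_id, .data$env_id, .data$hybrid, .data$replicate,
      is_outlier = .data$plot_id %in% out_ids,
      is_low_stand = .data$plot_id %in% low_ids,
      is_disease_env = .data$env_id %in% meta$env_id[disease_env]
    )
  trials$plot_id <- NULL

  # --- submission template for the final (test) year --------------------------
  test_envs <- meta$env_id[meta$year == max(years)]
  template <- purrr::map_dfr(match(test_envs, meta$env_id), function(j) {
    tibble::tibble(env_id = meta$env_id[j], hybrid = env_hybrids[[j]],
                   yield_mg_ha = NA_real_)
  })

  truth <- structure(list(
    env = tibble::tibble(
      env_id = meta$env_id,
      true_env_mean = mu,
      true_env_sd = sqrt(vg + ve + block_sd^2),
      true_genetic_sd = sqrt(vg),
      true_residual_var = ve,
      is_disease_env = disease_env
    ),
    genetic_values = G,
    Sigma_g = Sigma_g,
    artifacts = artifacts
  ), class = "gxe_truth")

  meta_out <- meta |>
    dplyr::select("env_id", "state", "station", "latitude", "longitude",
                  "irrigated", "treatment", "previous_crop")
  trials_out <- trials |>
    dplyr::select("env_id", "year", "location_code", "hybrid", "yield_mg_ha",
                  "stand_count", "replicate", "block", "discarded_flag")

  structure(list(trials = trials_out, meta = meta_out, ec = ec, truth = truth,
                 markers = markers, template = template, config = config),
            class = "gxe_bundle")
}

#' Simulate a complete competition-shaped bundle
#'
#' Convenience wrapper: markers plus trials in one call.
#'
#' @param config A [sim_config()].
#' @return A `gxe_bundle`; see [simulate_trials()].
#' @export
simulate_g2f_bundle <- function(config) {
  simulate_trials(config, simulate_marker_matrix(config))
}

# Symmetric PSD square root via eigendecomposition (tolerates singular input,
# e.g. a zero genetic covariance at h2 = 0 or perfect GxE correlations).
mat_sqrt <- function(S) {
  if (all(S == 0)) return(S)
  ee <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  vals[vals < 1e-12 * max(vals)] <- 0  # exact low-rank square roots
  ee$vectors %*% (sqrt(vals) * t(ee$vectors))
}

#' @export
print.gxe_bundle <- function(x, ...) {
  cat(sprintf("<gxe_bundle> %d plots, %d environments, %d hybrids, %d markers\n",
              nrow(x$trials), dplyr::n_distinct(x$trials$env_id),
              length(x$markers$hybrids), ncol(x$markers$dosage)))
  invisible(x)
}
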