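#' Deterministic accuracy of one environment's hybrids predicting another's
#'
#' A kernel-based proxy for the deterministic accuracy of environment `i`
#' predicting environment `k`: the mean cross-relationship between the two
#' hybrid sets, rescaled by the mean within-set relationship of the target
#' set `k` and clamped to `[0, 1]`.  Identical sets score 1; genetically
#' unrelated sets score near 0; training sets containing individuals more
#' related to the target's individuals score higher.
#'
#' @param kernel A `gxe_kernel`.
#' @param hybrids_i Hybrids observed in the candidate training environment.
#' @param hybrids_k Hybrids of the target environment.
#' @return A single number in `[0, 1]`.
#' @examples
#' M <- simulate_marker_matrix(sim_config(n_hybrids = 20, n_markers = 100, seed = 1))
#' K <- arc_cosine_kernel(M)
#' pair_accuracy(K, M$hybrids[1:10], M$hybrids[1:10])
#' @export
pair_accuracy <- function(kernel, hybrids_i, hybrids_k) {
  stopifnot(inherits(kernel, "gxe_kernel"))
  if (length(hybrids_i) == 0 || length(hybrids_k) == 0) {
    stop_gxe("both hybrid sets must be non-empty", "gxe_format_error")
  }
  unknown <- setdiff(c(hybrids_i, hybrids_k), kernel$hybrids)
  if (length(unknown) > 0) {
    stop_gxe(sprintf("hybrid(s) absent from the kernel: %s",
                     paste(head(unknown, 5), collapse = ", ")), "gxe_format_error")
  }
  cross <- mean(kernel$matrix[hybrids_i, hybrids_k, drop = FALSE])
  within_k <- mean(kernel$matrix[hybrids_k, hybrids_k, drop = FALSE])
  if (within_k <= 0) return(0)
  min(max(cross / within_k, 0), 1)
}

#' Weights of training environments for predicting a target environment
#'
#' Raw weight = deterministic accuracy times a geography multiplier —
#' same station 1.0, same state but different station 0.75, different state
#' 0.5 (configurable) — normalized to sum to 1, so environments at the same
#' station rank above same-state ones, which rank above farther ones, all
#' scaled by how related their hybrids are to the target's.
#'
#' @param accuracies Tibble `env_id`, `accuracy` (non-negative) for the
#'   candidate training environments, e.g. from [pair_accuracy()].
#' @param meta Environment metadata with `env_id`, `state`, `station`
#'   covering the training environments and the target.
#' @param target_k Target environment id.
#' @param multipliers Named numeric: `same_station`, `same_state`,
#'   `different_state`.
#' @return Tibble `env_id`, `weight` (non-negative, summing to 1).  If every
#'   raw weight is zero the weights are uniform, with a warning.
#' @export
location_weights <- function(accuracies, meta, target_k,
                             multipliers = c(same_station = 1, same_state = 0.75,
                                             different_state = 0.5)) {
  check_columns(accuracies, c("env_id", "accuracy"), "accuracies")
  check_columns(meta, c("env_id", "state", "station"), "metadata")
  if (any(accuracies$accuracy < 0)) {
    stop_gxe("accuracies must be non-negative", "gxe_format_error")
  }
  tk <- meta[match(target_k, meta$env_id), ]
  if (anyNA(tk$env_id)) {
    stop_gxe(sprintf("target environment `%s` absent from metadata", target_k),
             "gxe_format_error")
  }
  mi <- meta[match(accuracies$env_id, meta$env_id), ]
  geo <- dplyr::case_when(
    mi$station == tk$station ~ multipliers[["same_station"]],
    mi$state == tk$state ~ multipliers[["same_state"]],
    .default = multipliers[["different_state"]]
  )
  raw <- accuracies$accuracy * geo
  if (sum(raw) <= 0) {
    warn_gxe(sprintf("all raw weights are zero for target `%s`; using uniform weights",
                     target_k))
    raw <- rep(1, length(raw))
  }
  tibble::tibble(env_id = accuracies$env_id, weight = raw / sum(raw))
}

#' Selection-index genetic merit for a target environment
#'
#' The predicted genetic merit of each hybrid in target environment `k` is a
#' weighted linear combination of its genomic values in the observed
#' environments, `u_k = sigma_k * sum_i g_i w_{i,k}`: the raw index is
#' z-scored across the target hybrids (normalization removes the shrinkage
#' of the regularized genomic values) and rescaled to the predicted
#' environment standard deviation `sigma_k`, so the SD of the returned merit
#' equals `sigma_k` exactly.
#'
#' @param fit A `gxe_mgblup` (supplies the dense genomic values `g_i`).
#' @param weights Tibble `env_id`, `weight` over observed environments
#'   (non-negative, summing to 1), e.g. from [location_weights()].
#' @param sigma_k Predicted standard deviation of the target environment
#'   (Mg/ha, positive).
#' @param hybrids_target Hybrids to score.
#' @return Tibble `hybrid`, `u` (Mg/ha deviations, SD = `sigma_k`).
#' @export
selection_index <- function(fit, weights, sigma_k, hybrids_target) {
  stopifnot(inherits(fit, "gxe_mgblup"))
  check_columns(weights, c("env_id", "weight"), "weights")
  if (!is.numeric(sigma_k) || length(sigma_k) != 1 || sigma_k <= 0) {
    stop_gxe("`sigma_k` must be a single positive number", "gxe_format_error")
  }
  if (any(weights$weight < 0) || abs(sum(weights$weight) - 1) > 1e-8) {
    stop_gxe("weights must be non-negative and sum to 1", "gxe_format_error")
  }
  missing_env <- setdiff(weights$env_id, fit$envs)
  if (length(missing_env) > 0) {
    stop_gxe(sprintf("environment(s) not in the multivariate fit: %s",
                     paste(missing_env, collapse = ", ")), "gxe_format_error")
  }
  missing_h <- setdiff(hybrids_target, fit$hybrids)
  if (length(missing_h) > 0) {
    stop_gxe(sprintf("hybrid(s) not covered by the fit: %s",
                     paste(head(missing_h, 5), collapse = ", ")), "gxe_format_error")
  }
  raw <- drop(fit$g[hybrids_target, weights$env_id, drop = FALSE] %*% weights$weight)
  s <- sd(raw)
  if (!is.finite(s) || s < 1e-12) {
    stop_gxe("raw selection index has zero variance across target hybrids; rescaling undefined",
             class = "gxe_numeric_error")
  }
  tibble::tibble(hybrid = hybrids_target,
                 u = unname(sigma_k * (raw - mean(raw)) / s))
}

#' Assemble Model B predictions from environment means and selection indices
#'
#' `yhat(k, hybrid) = m_k + u_k(hybrid)`: the debiased predicted environment
#' mean plus the rescaled selection-index genetic merit.
#'
#' @param env_means Tibble `env_id`, `env_mean_pred` covering every template
#'   environment (from [predict_env_means()]).
#' @param indices Named list of selection-index tibbles (one per template
#'   environment, names = env ids), from [selection_index()].
#' @param template Tibble of `(env_id, hybrid)` pairs to predict.
#' @return Prediction tibble `env_id`, `hybrid`, `yield_mg_ha` with attribute
#'   `model = "B"`; template order preserved.
#' @export
model_b_predictions <- function(env_means, indices, template) {
  check_columns(template, c("env_id", "hybrid"), "template")
  check_columns(env_means, c("env_id", "env_mean_pred"), "environment means")
  envs <- unique(template$env_id)
  no_mean <- setdiff(envs, env_means$env_id)
  if (length(no_mean) > 0) {
    stop_gxe(sprintf("no predicted mean for environment(s): %s",
                     paste(no_mean, collapse = ", ")), "gxe_format_error")
  }
  no_idx <- setdiff(envs, names(indices))
  if (length(no_idx) > 0) {
    stop_gxe(sprintf("no selection index for environment(s): %s",
                     paste(no_idx, collapse = ", ")), "gxe_format_error")
  }
  m_k <- stats::setNames(env_means$env_mean_pred, env_means$env_id)
  u <- purrr::imap_dfr(indices[envs], function(ix, env) {
    dplyr::mutate(ix, env_id = env)
  })
  out <- template |>
    dplyr::left_join(u, by = c("env_id", "hybrid")) |>
    dplyr::mutate(yield_mg_ha = m_k[.data$env_id] + .data$u) |>
    dplyr::select("env_id", "hybrid", "yield_mg_ha")
  if (anyNA(out$yield_mg_ha)) {
    bad <- out[is.na(out$yield_mg_ha), ]
    stop_gxe(sprintf("template pair(s) without index coverage, e.g. %s / %s",
                     bad$env_id[1], bad$hybrid[1]), "gxe_format_error")
  }
  attr(out, "model") <- "B"
  out
}

#' Element-wise average of prediction sets
#'
#' The simple ensemble: the arithmetic mean of member predictions for each
#' `(env_id, hybrid)` pair.  All members must cover exactly the same pairs.
#' By norm convexity the per-environment RMSE of the ensemble never exceeds
#' the mean of the members' per-environment RMSEs.
#'
#' @param preds List of prediction tibbles (`env_id`, `hybrid`,
#'   `yield_mg_ha`).
#' @return Prediction tibble with attribute `model = "ensemble"`.
#' @export
ensemble_average <- function(preds) {
  stopifnot(is.list(preds), length(preds) >= 1)
  ref <- preds[[1]]
  check_columns(ref, c("env_id", "hybrid", "yield_mg_ha"), "prediction set")
  key <- function(p) paste(p$env_id, p$hybrid, sep = "\r")
  ref_key <- key(ref)
  acc <- ref$yield_mg_ha
  for (p in preds[-1]) {
    check_columns(p, c("env_id", "hybrid", "yield_mg_ha"), "prediction set")
    miss <- setdiff(ref_key, key(p))
    extra <- setdiff(key(p), ref_key)
    if (length(miss) > 0 || length(extra) > 0) {
      bad <- gsub("\r", " / ", c(head(miss, 3), head(extra, 3)))
      stop_gxe(sprintf("prediction sets do not cover the same pairs (e.g. %s)",
                       paste(bad, collapse = "; ")), "gxe_format_error")
    }
    acc <- acc + p$yield_mg_ha[match(ref_key, key(p))]
  }
  out <- dplyr::mutate(ref, yield_mg_ha = acc / length(preds))
  attr(out, "model") <- "ensemble"
  out
}

#' Write a submission file
#'
#' `submission.csv` with columns `Env`, `Hybrid`, `Yield_Mg_ha`, template
#' order preserved, six decimal places.
#'
#' @param pred Prediction tibble (`env_id`, `hybrid`, `yield_mg_ha`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(pred, path) {
  check_columns(pred, c("env_id", "hybrid", "yield_mg_ha"), "predictions")
  out <- tibble::tibble(Env = pred$env_id, Hybrid = pred$hybrid,
                        Yield_Mg_ha = sprintf("%.6f", pred$yield_mg_ha))
  readr::write_csv(out, path)
  invisible(path)
}
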