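#' Configuration for the end-to-end prediction pipeline
#'
#' Collects every tunable of the simulate - preprocess - fit - ensemble -
#' score workflow.  One master seed fans out to named per-stage seeds via a
#' documented multiplicative hash (see [run_pipeline()]), so each stage is
#' individually reproducible and no two stages share a stream.
#'
#' @param sim A [sim_config()] to simulate a bundle, or `NULL` when
#'   `bundle_dir` points at an existing bundle on disk.
#' @param bundle_dir Directory of a written bundle (see [read_bundle()]);
#'   ignored when `sim` is given.
#' @param model Which predictions to produce: `"ensemble"` (average of A and
#'   B, default), `"A"`, `"B"`, or `"mean_only"` (predicted environment mean
#'   for every pair — the no-genetics baseline).
#' @param test_year Year held out as the prediction target (default: the
#'   last year in the data).
#' @param sd_threshold,min_stand,drop_disease QC settings ([qc_filter()]).
#' @param kernel `"arc_cosine"` (default) or `"additive"`.
#' @param max_iter,tol,min_hybrids_per_env Multivariate EM settings
#'   ([fit_multivariate_gblup()]).
#' @param sd_target Scale target for the selection index: `"genetic"`
#'   (default; per-environment genotypic SD from the multivariate fit,
#'   see [genetic_env_sds()]) or `"phenotypic"` (per-environment SD of
#'   QC-filtered plot yields).
#' @param ridge_eps Ridge fraction for kernel projection inverses.
#' @param multipliers Geography multipliers for [location_weights()].
#' @param num_trees Random-forest size for the environment models.
#' @param seed Master seed.
#' @return A list of class `gxe_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), bundle_dir = NULL,
                            model = c("ensemble", "A", "B", "mean_only"),
                            test_year = NULL,
                            sd_threshold = 3, min_stand = 20, drop_disease = TRUE,
                            kernel = c("arc_cosine", "additive"),
                            max_iter = 500, tol = 1e-6, min_hybrids_per_env = 30,
                            sd_target = c("genetic", "phenotypic"),
                            ridge_eps = 1e-8,
                            multipliers = c(same_station = 1, same_state = 0.75,
                                            different_state = 0.5),
                            num_trees = 500, seed = 1L) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  sd_target <- match.arg(sd_target)
  if (is.null(sim) && is.null(bundle_dir)) {
    stop_gxe("either `sim` or `bundle_dir` must be given", "gxe_config_error")
  }
  if (!is.null(sim)) validate_sim_config(sim)
  stopifnot(sd_threshold > 0, min_stand >= 0, max_iter >= 1, tol > 0,
            ridge_eps >= 0, num_trees >= 1)
  if (!all(c("same_station", "same_state", "different_state") %in%
           names(multipliers))) {
    stop_gxe("`multipliers` must name same_station, same_state, different_state",
             "gxe_config_error")
  }
  structure(list(sim = sim, bundle_dir = bundle_dir, model = model,
                 test_year = test_year, sd_threshold = sd_threshold,
                 min_stand = min_stand, drop_disease = drop_disease,
                 kernel = kernel, max_iter = max_iter, tol = tol,
                 min_hybrids_per_env = min_hybrids_per_env,
                 sd_target = sd_target,
                 ridge_eps = ridge_eps, multipliers = multipliers,
                 num_trees = num_trees, seed = as.integer(seed)),
            class = "gxe_pipeline_config")
}

#' Run the full simulate - preprocess - fit - ensemble - score pipeline
#'
#' Orchestrates the two-model workflow end to end:
#'
#' 1. simulate (or read) a competition-shaped bundle and split it at
#'    `test_year`;
#' 2. aggregate metadata, QC-filter the training plots, compute environment
#'    summaries, and standardize phenotypes within environment;
#' 3. build the genomic kernel;
#' 4. **Model A** — univariate GBLUP with metadata fixed effects, predicted
#'    onto the template;
#' 5. **Model B** — debiased composite environment means, random-forest
#'    environment SDs, multivariate GBLUP, and per-target selection indices;
#' 6. ensemble average (or the single model requested) and, when the bundle
#'    carries test-year observations, the per-environment RMSE score.
#'
#' Deterministic given the master seed: stage `k` of the named stages
#' (`markers`, `trials`, `env_mean_rf`, `env_sd_rf`) receives seed
#' `(seed * 7919 + k) mod (2^31 - 1)`.
#'
#' @param config A [pipeline_config()].
#' @return A `gxe_pipeline_result`: `predictions` (template tibble with
#'   `yield_mg_ha`), `score` (`gxe_score` or `NULL`), `manifest` (seeds,
#'   settings, per-stage record counts), plus the fitted component models.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "gxe_pipeline_config"))
  seeds <- stage_seeds(config$seed,
                       c("markers", "trials", "env_mean_rf", "env_sd_rf"))
  manifest <- list(seed = config$seed, stage_seeds = as.list(seeds),
                   model = config$model, kernel = config$kernel,
                   counts = list())

  # stage 1: data
  if (!is.null(config$sim)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- unname(seeds["markers"])
    bundle <- simulate_g2f_bundle(sim_cfg)
  } else {
    bundle <- read_bundle(config$bundle_dir)
  }
  test_year <- config$test_year %||% max(bundle$trials$year)
  train <- dplyr::filter(bundle$trials, .data$year < test_year)
  test <- dplyr::filter(bundle$trials, .data$year == test_year)
  if (nrow(train) == 0 || nrow(bundle$template) == 0) {
    stop_gxe("pipeline needs non-empty training data and template",
             "gxe_config_error")
  }
  template <- dplyr::filter(bundle$template,
                            .data$env_id %in% unique(test$env_id) |
                              nrow(test) == 0)
  if (nrow(template) == 0) template <- bundle$template
  manifest$counts$train_plots <- nrow(train)
  manifest$counts$template_pairs <- nrow(template)

  # stage 2: preprocess
  meta <- aggregate_metadata(bundle$meta)
  train_qc <- qc_filter(train, sd_threshold = config$sd_threshold,
                        min_stand = config$min_stand,
                        drop_disease = config$drop_disease, meta = bundle$meta)
  manifest$counts$qc_removed <- as.list(qc_removals(train_qc))
  summ <- env_summaries(train_qc)
  ystar <- standardize_spatial(train_qc)

  # stage 3: kernel
  K <- if (config$kernel == "arc_cosine") {
    arc_cosine_kernel(bundle$markers)
  } else {
    additive_grm(bundle$markers)
  }

  train_meta <- dplyr::inner_join(
    train_qc, dplyr::select(meta, -dplyr::any_of(c("latitude", "longitude"))),
    by = "env_id")
  test_envs <- unique(template$env_id)

  # stage 4: Model A (only metadata columns that vary in training can enter)
  a_terms <- Filter(function(v) dplyr::n_distinct(train_meta[[v]]) > 1,
                    c("station", "irrigated", "treatment_class",
                      "previous_crop_class"))
  a_fixed <- stats::as.formula(
    paste("~", if (length(a_terms)) paste(a_terms, collapse = " + ") else "1"))
  fit_a <- fit_univariate_gblup(train_meta, K, fixed = a_fixed,
                                drop_aliased = TRUE)
  pred_a <- suppressWarnings(predict_model_a(
    fit_a, template, meta_new = meta, K_cross = K$matrix,
    ridge_eps = config$ridge_eps))

  # stage 5: Model B
  em_model <- fit_env_mean_model(
    dplyr::select(summ, "env_id", "env_mean"), bundle$ec, meta,
    num_trees = config$num_trees, seed = unname(seeds["env_mean_rf"]))
  mean_pred <- suppressWarnings(predict_env_means(
    em_model, dplyr::filter(bundle$ec, .data$env_id %in% test_envs), meta))
  fit_mv <- fit_multivariate_gblup(
    ystar, K, max_iter = config$max_iter, tol = config$tol,
    min_hybrids_per_env = config$min_hybrids_per_env)

  sd_train <- if (config$sd_target == "genetic") {
    genetic_env_sds(fit_mv, ystar)
  } else {
    dplyr::transmute(summ, env_id = .data$env_id, env_sd = .data$env_sd)
  }
  sd_model <- fit_env_sd_model(
    sd_train, bundle$ec, num_trees = config$num_trees,
    seed = unname(seeds["env_sd_rf"]))
  sd_pred <- predict_env_sd(
    sd_model, dplyr::filter(bundle$ec, .data$env_id %in% test_envs))
  env_sets <- split(ystar$values$hybrid, ystar$values$env_id)
  env_sets <- env_sets[fit_mv$envs]
  indices <- lapply(test_envs, function(k) {
    hyb_k <- unique(template$hybrid[template$env_id == k])
    acc <- tibble::tibble(
      env_id = fit_mv$envs,
      accuracy = vapply(fit_mv$envs, function(i) {
        pair_accuracy(K, env_sets[[i]], hyb_k)
      }, numeric(1)))
    w <- location_weights(acc, bundle$meta, k, multipliers = config$multipliers)
    selection_index(fit_mv, w,
                    sd_pred$env_sd_pred[match(k, sd_pred$env_id)], hyb_k)
  })
  names(indices) <- test_envs
  pred_b <- model_b_predictions(
    dplyr::select(mean_pred, "env_id", "env_mean_pred"), indices, template)
  pred_mean_only <- template |>
    dplyr::mutate(yield_mg_ha =
                    mean_pred$env_mean_pred[match(.data$env_id, mean_pred$env_id)]) |>
    dplyr::select("env_id", "hybrid", "yield_mg_ha")

  # stage 6: combine + score
  predictions <- switch(config$model,
    A = pred_a,
    B = pred_b,
    mean_only = pred_mean_only,
    ensemble = ensemble_average(list(pred_a, pred_b))
  )
  score <- NULL
  if (nrow(test) > 0) {
    truth <- test |>
      dplyr::group_by(.data$env_id, .data$hybrid) |>
      dplyr::summarise(yield_mg_ha = mean(.data$yield_mg_ha), .groups = "drop")
    score <- score_predictions(predictions, truth)
    manifest$counts$scored_pairs <- score$summary$n_pairs
  }
  manifest$counts$em_iterations <- fit_mv$iterations

  structure(list(
    predictions = predictions, score = score, manifest = manifest,
    components = list(model_a = fit_a, multivariate = fit_mv,
                      env_mean = em_model, env_sd = sd_model,
                      pred_a = pred_a, pred_b = pred_b,
                      pred_mean_only = pred_mean_only),
    bundle = bundle
  ), class = "gxe_pipeline_result")
}

#' @export
print.gxe_pipeline_result <- function(x, ...) {
  cat(sprintf("<gxe_pipeline_result> model = %s, %d predictions\n",
              x$manifest$model, nrow(x$predictions)))
  if (!is.null(x$score)) print(x$score)
  invisible(x)
}

#' @export
glance.gxe_pipeline_result <- function(x, ...) {
  out <- tibble::tibble(model = x$manifest$model, seed = x$manifest$seed,
                        n_predictions = nrow(x$predictions))
  if (!is.null(x$score)) out <- dplyr::bind_cols(out, x$score$summary)
  out
}

#' Write the run manifest as JSON
#'
#' @param result A `gxe_pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
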