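#' Fit the debiased composite model for environment mean yields
#'
#' Predicts environment mean yield (Mg/ha) for unobserved environments from
#' environmental covariates and location metadata in two steps:
#'
#' 1. a **biased composite**: the average of three sub-models — a random
#'    forest of the environmental covariates, a ridge regression of the
#'    environmental covariates (penalty chosen by generalized
#'    cross-validation), and a least-squares fit of the location metadata
#'    (station, irrigation, treatment class, previous-crop class);
#' 2. a **debiasing step**: ordinary least squares of the observed training
#'    means on the composite gives `(a, b)`; the debiased predictor is
#'    `a + b * composite`, which removes the shrinkage of the regularized
#'    composite (regressing observed on debiased predictions returns slope 1
#'    and intercept 0 by construction).
#'
#' Missing covariate values are imputed by training-set medians before
#' modeling, and the same medians are reused at prediction.
#'
#' @param env_means Tibble `env_id`, `env_mean` (e.g. from [env_summaries()]).
#' @param ecs Tibble `env_id` plus numeric covariate columns.
#' @param meta Aggregated environment metadata ([aggregate_metadata()]) with
#'   `station`, `irrigated`, `treatment_class`, `previous_crop_class`.
#' @param num_trees Random-forest size (default 500).
#' @param seed Seed for the forest (default 1).
#' @return A `gxe_env_mean_model` with sub-models, debias coefficients
#'   `a`, `b`, training diagnostics (per-sub-model R^2), and the fitted
#'   debiased training predictions.
#' @export
fit_env_mean_model <- function(env_means, ecs, meta, num_trees = 500, seed = 1L) {
  check_columns(env_means, c("env_id", "env_mean"), "environment means")
  check_columns(ecs, "env_id", "covariates")
  check_columns(meta, c("env_id", "irrigated", "treatment_class",
                        "previous_crop_class"), "metadata")
  if (nrow(env_means) < 20) {
    warn_gxe(sprintf("only %d training environments (< 20); expect noisy fits",
                     nrow(env_means)))
  }
  envs <- env_means$env_id
  yobs <- env_means$env_mean

  ec_cols <- setdiff(names(ecs), "env_id")
  Xec <- as.matrix(ecs[match(envs, ecs$env_id), ec_cols, drop = FALSE])
  medians <- apply(Xec, 2, median, na.rm = TRUE)
  for (j in seq_along(ec_cols)) Xec[is.na(Xec[, j]), j] <- medians[j]
  ecdf_train <- as.data.frame(Xec)

  # sub-model 1: random forest of the covariates
  rf_dat <- cbind(.y = yobs, ecdf_train)
  rf <- ranger::ranger(.y ~ ., data = rf_dat, num.trees = num_trees,
                       seed = seed)
  rf_pred <- predict(rf, ecdf_train)$predictions

  # sub-model 2: ridge of the covariates, GCV-selected penalty
  if (length(ec_cols) >= 2) {
    lambdas <- c(0, 10^seq(-4, 4, length.out = 81))
    rr <- MASS::lm.ridge(.y ~ ., data = rf_dat, lambda = lambdas)
    lam <- lambdas[which.min(rr$GCV)]
    rr <- MASS::lm.ridge(.y ~ ., data = rf_dat, lambda = lam)
    rr_coef <- coef(rr)
  } else {
    # a single covariate: ordinary least squares (no useful shrinkage axis)
    lam <- 0
    rr_coef <- coef(lm(.y ~ ., data = rf_dat))
    rr_coef[is.na(rr_coef)] <- 0
  }
  rr_pred <- drop(cbind(1, Xec) %*% rr_coef)

  # sub-model 3: least squares of the location metadata (main effects)
  md <- meta[match(envs, meta$env_id), , drop = FALSE]
  ls_form <- env_meta_formula(md)
  ls_dat <- cbind(.y = yobs, as.data.frame(md))
  ls_fit <- lm(ls_form, data = ls_dat)
  ls_pred <- unname(fitted(ls_fit))

  composite <- (rf_pred + rr_pred + ls_pred) / 3
  if (sd(composite) < 1e-10) {
    stop_gxe("composite prediction is constant over training environments; debias slope undefined",
             class = "gxe_numeric_error")
  }
  deb <- lm(yobs ~ composite)
  a <- unname(coef(deb)[1]); b <- unname(coef(deb)[2])
  if (!is.finite(b) || b <= 0) {
    stop_gxe(sprintf("debias slope must be finite and positive (got %.4g)", b),
             class = "gxe_numeric_error")
  }
  r2 <- function(p) 1 - sum((yobs - p)^2) / sum((yobs - mean(yobs))^2)
  structure(list(
    rf = rf, ridge_coef = rr_coef, ridge_lambda = lam, ls = ls_fit,
    ls_formula = ls_form, a = a, b = b,
    ec_cols = ec_cols, ec_medians = medians,
    meta_levels = lapply(Filter(is.factor, ls_fit$model), levels),
    fitted = tibble::tibble(env_id = envs, observed = yobs,
                            composite = composite,
                            debiased = a + b * composite),
    diagnostics = tibble::tibble(
      submodel = c("random_forest", "ridge", "least_squares", "debiased"),
      r_squared = c(rf$r.squared, r2(rr_pred), summary(ls_fit)$r.squared,
                    r2(a + b * composite)))
  ), class = "gxe_env_mean_model")
}

# main-effects metadata formula; station absorbs state when several stations
# are present, otherwise fall back to intercept-only pieces that vary
env_meta_formula <- function(md) {
  terms <- c()
  if ("station" %in% names(md) && dplyr::n_distinct(md$station) > 1) {
    terms <- c(terms, "factor(station)")
  } else if ("state" %in% names(md) && dplyr::n_distinct(md$state) > 1) {
    terms <- c(terms, "factor(state)")
  }
  for (v in c("irrigated", "treatment_class", "previous_crop_class")) {
    if (v %in% names(md) && dplyr::n_distinct(md[[v]]) > 1) {
      terms <- c(terms, if (v == "irrigated") v else sprintf("factor(%s)", v))
    }
  }
  if (length(terms) == 0) terms <- "1"
  stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
}

#' Predict environment means for new environments
#'
#' Applies the debiased composite, `a + b * composite(env)`.  Covariate
#' columns must match training (error naming any missing column); missing
#' values are imputed with the training medians; unseen metadata levels fall
#' back to the training reference level.
#'
#' @param model A `gxe_env_mean_model`.
#' @param ecs_new Covariates for the new environments (`env_id` + columns).
#' @param meta_new Aggregated metadata for the new environments.
#' @return Tibble `env_id`, `env_mean_pred` (Mg/ha), plus the raw
#'   `composite`.
#' @export
predict_env_means <- function(model, ecs_new, meta_new) {
  stopifnot(inherits(model, "gxe_env_mean_model"))
  check_columns(ecs_new, "env_id", "covariates")
  missing_ec <- setdiff(model$ec_cols, names(ecs_new))
  if (length(missing_ec) > 0) {
    stop_gxe(sprintf("missing covariate column(s): %s",
                     paste(missing_ec, collapse = ", ")), "gxe_format_error")
  }
  envs <- ecs_new$env_id
  Xec <- as.matrix(ecs_new[, model$ec_cols, drop = FALSE])
  for (j in seq_along(model$ec_cols)) {
    Xec[is.na(Xec[, j]), j] <- model$ec_medians[j]
  }
  rf_pred <- predict(model$rf, as.data.frame(Xec))$predictions
  rr_pred <- drop(cbind(1, Xec) %*% model$ridge_coef)
  md <- meta_new[match(envs, meta_new$env_id), , drop = FALSE]
  ls_pred <- predict_ls_meta(model, md)
  composite <- (rf_pred + rr_pred + ls_pred) / 3
  tibble::tibble(env_id = envs, composite = composite,
                 env_mean_pred = model$a + model$b * composite)
}

# least-squares sub-model prediction with unseen-level fallback
predict_ls_meta <- function(model, md) {
  df <- as.data.frame(md)
  xl <- model$ls$xlevels
  fellback <- character(0)
  for (v in names(xl)) {
    raw <- sub("^factor\\((.*)\\)$", "\\1", v)
    vals <- as.character(df[[raw]])
    bad <- !vals %in% xl[[v]]
    if (any(bad)) {
      fellback <- c(fellback, unique(vals[bad]))
      vals[bad] <- xl[[v]][1]
    }
    df[[raw]] <- vals
  }
  if (length(fellback) > 0) {
    warn_gxe(sprintf("unseen metadata level(s) mapped to the reference: %s",
                     paste(unique(fellback), collapse = ", ")))
  }
  unname(suppressWarnings(predict(model$ls, newdata = df)))
}

#' @export
print.gxe_env_mean_model <- function(x, ...) {
  cat(sprintf("<gxe_env_mean_model> %d training environments\n", nrow(x$fitted)))
  cat(sprintf("  debias: a = %.3f, b = %.3f (ridge lambda = %.3g)\n",
              x$a, x$b, x$ridge_lambda))
  print(x$diagnostics)
  invisible(x)
}

#' @export
tidy.gxe_env_mean_model <- function(x, ...) x$diagnostics

#' @export
glance.gxe_env_mean_model <- function(x, ...) {
  tibble::tibble(n_envs = nrow(x$fitted), debias_intercept = x$a,
                 debias_slope = x$b, ridge_lambda = x$ridge_lambda)
}

#' Observed vs debiased environment means
#'
#' @param object A `gxe_env_mean_model`.
#' @param ... Unused.
#' @return A ggplot of observed training means against raw composite and
#'   debiased predictions, with the identity line.
#' @export
autoplot.gxe_env_mean_model <- function(object, ...) {
  d <- object$fitted |>
    tidyr::pivot_longer(c("composite", "debiased"),
                        names_to = "predictor", values_to = "pred")
  ggplot2::ggplot(d, ggplot2::aes(.data$pred, .data$observed,
                                  colour = .data$predictor)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "predicted environment mean (Mg/ha)",
                  y = "observed environment mean (Mg/ha)") +
    ggplot2::theme_minimal()
}

#' Fit / apply the environment standard-deviation model
#'
#' A random forest of the environmental covariates predicting a
#' per-environment standard deviation, `sigma = RF(W) + e` — the scale used
#' to rescale selection-index genetic predictions.  The caller chooses the
#' training target: the *genotypic* SD of each environment (from a
#' multivariate fit, see [genetic_env_sds()]; the pipeline default, since
#' genetic merit rescaled to the full phenotypic SD is overdispersed and
#' provably cannot improve squared-error loss unless index accuracy exceeds
#' the ratio of phenotypic to twice the genetic SD) or the phenotypic
#' per-environment SD of QC-filtered plot yields.  Predictions are floored
#' at 10% of the smallest training SD so they stay strictly positive.
#'
#' @param env_sds Tibble `env_id`, `env_sd` (positive, Mg/ha).
#' @param ecs Covariates tibble (`env_id` + columns).
#' @param num_trees,seed Forest size and seed.
#' @return `fit_env_sd_model()` returns a `gxe_env_sd_model`;
#'   `predict_env_sd()` a tibble `env_id`, `env_sd_pred`.
#' @export
fit_env_sd_model <- function(env_sds, ecs, num_trees = 500, seed = 1L) {
  check_columns(env_sds, c("env_id", "env_sd"), "environment SDs")
  check_columns(ecs, "env_id", "covariates")
  dat <- dplyr::filter(env_sds, !is.na(.data$env_sd))
  if (nrow(dat) < 5) {
    stop_gxe("at least 5 training environments with an SD are required",
             "gxe_config_error")
  }
  if (any(dat$env_sd <= 0)) {
    stop_gxe("environment SDs must be positive", "gxe_format_error")
  }
  ec_cols <- setdiff(names(ecs), "env_id")
  Xec <- as.matrix(ecs[match(dat$env_id, ecs$env_id), ec_cols, drop = FALSE])
  medians <- apply(Xec, 2, median, na.rm = TRUE)
  for (j in seq_along(ec_cols)) Xec[is.na(Xec[, j]), j] <- medians[j]
  rf <- ranger::ranger(.y ~ ., data = cbind(.y = dat$env_sd, as.data.frame(Xec)),
                       num.trees = num_trees, seed = seed)
  structure(list(rf = rf, ec_cols = ec_cols, ec_medians = medians,
                 floor = 0.1 * min(dat$env_sd), n_envs = nrow(dat)),
            class = "gxe_env_sd_model")
}

#' @rdname fit_env_sd_model
#' @param model A `gxe_env_sd_model`.
#' @param ecs_new Covariates for the target environments.
#' @export
predict_env_sd <- function(model, ecs_new) {
  stopifnot(inherits(model, "gxe_env_sd_model"))
  check_columns(ecs_new, "env_id", "covariates")
  missing_ec <- setdiff(model$ec_cols, names(ecs_new))
  if (length(missing_ec) > 0) {
    stop_gxe(sprintf("missing covariate column(s): %s",
                     paste(missing_ec, collapse = ", ")), "gxe_format_error")
  }
  Xec <- as.matrix(ecs_new[, model$ec_cols, drop = FALSE])
  for (j in seq_along(model$ec_cols)) {
    Xec[is.na(Xec[, j]), j] <- model$ec_medians[j]
  }
  pred <- predict(model$rf, as.data.frame(Xec))$predictions
  tibble::tibble(env_id = ecs_new$env_id,
                 env_sd_pred = pmax(pred, model$floor))
}

#' Per-environment genotypic standard deviations on the Mg/ha scale
#'
#' Maps the estimated environment genetic variances of a multivariate fit
#' (standardized scale) back to Mg/ha: the genetic SD of environment `j` is
#' `sqrt(Sigma_g[j, j]) * scale[j]`, with `scale` the per-environment SD
#' used by [standardize_spatial()].  The usual training target for
#' [fit_env_sd_model()].
#'
#' @param fit A `gxe_mgblup`.
#' @param std A `gxe_std_pheno` (supplies the standardization scales), or a
#'   tibble `env_id`, `scale`.
#' @return Tibble `env_id`, `env_sd` (genotypic SD, Mg/ha).
#' @export
genetic_env_sds <- function(fit, std) {
  stopifnot(inherits(fit, "gxe_mgblup"))
  sc <- if (inherits(std, "gxe_std_pheno")) std$scale else std
  check_columns(sc, c("env_id", "scale"), "standardization scale")
  s <- sc$scale[match(fit$envs, sc$env_id)]
  if (anyNA(s)) {
    stop_gxe("standardization scale missing for some fitted environments",
             "gxe_format_error")
  }
  tibble::tibble(env_id = fit$envs,
                 env_sd = unname(sqrt(pmax(diag(fit$Sigma_g), 0)) * s))
}

#' @export
print.gxe_env_sd_model <- function(x, ...) {
  cat(sprintf("<gxe_env_sd_model> %d training environments, floor %.3f Mg/ha\n",
              x$n_envs, x$floor))
  invisible(x)
}
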