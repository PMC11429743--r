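#' Fit a univariate GBLUP by spectral REML
#'
#' Fits the linear mixed model `y = X beta + Z g + e`, with `g ~ N(0, Vg K)`
#' the polygenic term (`K` a genomic kernel over hybrids, `Z` the incidence
#' of records to hybrids) and `e ~ N(0, Ve I)`.  This is Model A of the
#' two-model ensemble: fixed effects carry the location metadata (state /
#' station, irrigation, treatment class, previous-crop class) and all genetic
#' signal flows through the kernel.
#'
#' Estimation is exact REML through a single eigendecomposition of
#' `K^{1/2} Z'Z K^{1/2}` (`Z'Z` is diagonal, so the whole likelihood profile
#' collapses to a 1-D search in the variance ratio `gamma = Vg/Ve`): every
#' evaluation of the profiled restricted likelihood is O(n) after the
#' decomposition, and there is no iterative convergence to tune.  With
#' `fixed = NULL` no fixed effects are fitted and the criterion is the plain
#' likelihood.
#'
#' @param data Tibble of training records containing the response and hybrid
#'   columns plus any fixed-effect covariates.
#' @param kernel A `gxe_kernel` covering every hybrid in `data`.
#' @param fixed One-sided formula for the fixed effects (default `~ 1`), or
#'   `NULL` for a no-fixed-effect (maximum likelihood) fit.
#' @param response,hybrid Column names of the response and hybrid id.
#' @param drop_aliased Drop aliased fixed-effect columns with a message
#'   instead of erroring? Default `FALSE` (error listing the columns).
#' @return A `gxe_ugblup` object: variance components `Vg`, `Ve`, plot-level
#'   `h2`, fixed effects `beta`, genomic values `g` (named, Mg/ha
#'   deviations, one per training hybrid), `loglik` (restricted), fitted
#'   values, and the training kernel pieces needed by [predict_model_a()].
#' @examples
#' cfg <- sim_config(n_hybrids = 60, n_markers = 200, seed = 2)
#' M <- simulate_marker_matrix(cfg)
#' K <- additive_grm(M)
#' g <- drop(mat_sqrt(K$matrix) %*% rnorm(60))
#' d <- tibble::tibble(hybrid = M$hybrids, y = g + rnorm(60))
#' fit <- fit_univariate_gblup(d, K, response = "y")
#' glance(fit)
#' @export
fit_univariate_gblup <- function(data, kernel, fixed = ~1,
                                 response = "yield_mg_ha", hybrid = "hybrid",
                                 drop_aliased = FALSE) {
  stopifnot(inherits(kernel, "gxe_kernel"))
  check_columns(data, c(response, hybrid), "training data")
  data <- dplyr::filter(data, !is.na(.data[[response]]))
  y <- data[[response]]
  N <- length(y)
  hyb <- as.character(data[[hybrid]])
  unknown <- setdiff(unique(hyb), kernel$hybrids)
  if (length(unknown) > 0) {
    stop_gxe(sprintf("hybrid(s) absent from the kernel: %s",
                     paste(head(unknown, 5), collapse = ", ")),
             class = "gxe_format_error")
  }
  h_obs <- intersect(kernel$hybrids, unique(hyb))
  n <- length(h_obs)
  Kt <- kernel$matrix[h_obs, h_obs, drop = FALSE]

  ee <- eigen(Kt, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * sum(diag(Kt)) / n) {
    stop_gxe("kernel is not positive semidefinite", "gxe_numeric_error")
  }
  B <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))  # K^{1/2}

  # fixed design
  xinfo <- NULL
  if (!is.null(fixed)) {
    mf <- stats::model.frame(fixed, data, na.action = stats::na.fail)
    X <- stats::model.matrix(fixed, mf)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      if (drop_aliased) {
        inform(sprintf("dropping aliased fixed-effect column(s): %s",
                       paste(aliased, collapse = ", ")))
        X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
      } else {
        stop_gxe(sprintf("fixed-effect design is singular; aliased column(s): %s",
                         paste(aliased, collapse = ", ")),
                 class = "gxe_design_error")
      }
    }
    xinfo <- list(terms = stats::terms(mf), xlevels = stats::.getXlevels(stats::terms(mf), mf),
                  colnames = colnames(X))
  } else {
    X <- NULL
  }
  p <- if (is.null(X)) 0L else ncol(X)

  # sufficient statistics through the hybrid incidence (Z'Z diagonal)
  id <- match(hyb, h_obs)
  counts <- tabulate(id, n)
  zy_full <- drop(rowsum(y, factor(id, levels = seq_len(n))))
  M0 <- B %*% (counts * B)
  eM <- eigen((M0 + t(M0)) / 2, symmetric = TRUE)
  Q <- eM$vectors
  theta <- pmax(eM$values, 0)
  Fty <- drop(B %*% zy_full)          # F'y with F = Z B
  Py <- drop(crossprod(Q, Fty))
  yy <- sum(y^2)
  if (p > 0) {
    ZX <- rowsum(X, factor(id, levels = seq_len(n)))
    FtX <- B %*% ZX
    PX <- crossprod(Q, FtX)
    Xy <- drop(crossprod(X, y))
    XX <- crossprod(X)
  }

  obj <- function(lg) {
    g <- exp(lg)
    w <- g / (1 + g * theta)
    ldV0 <- sum(log1p(g * theta))
    yVy <- yy - sum(w * Py^2)
    if (p > 0) {
      XVy <- Xy - drop(crossprod(PX, w * Py))
      XVX <- XX - crossprod(PX, w * PX)
      cX <- chol_safe(XVX)
      beta <- backsolve(cX, forwardsolve(t(cX), XVy))
      rss <- max(yVy - sum(beta * XVy), 1e-12)
      ve <- rss / (N - p)
      -0.5 * ((N - p) * (log(2 * pi * ve) + 1) + ldV0 + 2 * sum(log(diag(cX))))
    } else {
      ve <- max(yVy, 1e-12) / N
      -0.5 * (N * (log(2 * pi * ve) + 1) + ldV0)
    }
  }
  opt <- optimize(obj, interval = c(-15, 15), maximum = TRUE, tol = 1e-9)
  gam <- exp(opt$maximum)
  w <- gam / (1 + gam * theta)
  yVy <- yy - sum(w * Py^2)
  if (p > 0) {
    XVy <- Xy - drop(crossprod(PX, w * Py))
    XVX <- XX - crossprod(PX, w * PX)
    beta <- drop(solve(XVX, XVy))
    names(beta) <- colnames(X)
    Ve <- max(yVy - sum(beta * XVy), 1e-12) / (N - p)
    resid <- y - drop(X %*% beta)
  } else {
    beta <- NULL
    Ve <- max(yVy, 1e-12) / N
    resid <- y
  }
  # treat a boundary fit (gamma at the lower search bound) as Vg = 0
  Vg <- if (opt$maximum <= -15 + 1e-6) 0 else gam * Ve

  # BLUP: g_hat = gamma K Z' V0^{-1} r
  Ftr <- drop(B %*% drop(rowsum(resid, factor(id, levels = seq_len(n)))))
  Pr <- drop(crossprod(Q, Ftr))
  V0inv_r <- resid - drop((B %*% (Q %*% (w * Pr)))[id])
  ZtV0r <- drop(rowsum(V0inv_r, factor(id, levels = seq_len(n))))
  ghat <- (Vg / Ve) * drop(Kt %*% ZtV0r)
  names(ghat) <- h_obs
  fitted <- (if (p > 0) drop(X %*% beta) else 0) + ghat[id]

  structure(list(
    Vg = Vg, Ve = Ve, h2 = Vg / (Vg + Ve), gamma = Vg / Ve,
    beta = beta, g = ghat, loglik = opt$objective,
    fitted = fitted, n_records = N, n_hybrids = n,
    xinfo = xinfo, K_train = Kt, hybrids = h_obs,
    reml = !is.null(X)
  ), class = "gxe_ugblup")
}

#' @export
print.gxe_ugblup <- function(x, ...) {
  cat(sprintf("<gxe_ugblup> %d records, %d hybrids\n", x$n_records, x$n_hybrids))
  cat(sprintf("  Vg = %.4f, Ve = %.4f (h2 = %.3f), %s logLik = %.2f\n",
              x$Vg, x$Ve, x$h2, if (x$reml) "REML" else "ML", x$loglik))
  invisible(x)
}

#' @export
tidy.gxe_ugblup <- function(x, ...) {
  vc <- tibble::tibble(term = c("Vg", "Ve"), type = "variance",
                       estimate = c(x$Vg, x$Ve))
  if (!is.null(x$beta)) {
    vc <- dplyr::bind_rows(
      tibble::tibble(term = names(x$beta), type = "fixed",
                     estimate = unname(x$beta)), vc)
  }
  vc
}

#' @export
glance.gxe_ugblup <- function(x, ...) {
  tibble::tibble(Vg = x$Vg, Ve = x$Ve, h2 = x$h2, logLik = x$loglik,
                 n_records = x$n_records, n_hybrids = x$n_hybrids,
                 criterion = if (x$reml) "REML" else "ML")
}

#' Genomic values of a univariate GBLUP as a tibble
#'
#' @param fit A `gxe_ugblup`.
#' @return Tibble `hybrid`, `g` (Mg/ha deviation).
#' @export
genomic_values <- function(fit) {
  stopifnot(inherits(fit, "gxe_ugblup"))
  tibble::tibble(hybrid = names(fit$g), g = unname(fit$g))
}

#' Predict yields from a univariate GBLUP (Model A)
#'
#' Predictions are `x(env)' beta + g(hybrid)`: metadata fixed effects for the
#' target environment plus the hybrid's genomic value.  Genomic values of
#' hybrids not in the training set are kernel-projected,
#' `g_new = K_cross K_train^{-1} g_train` with a ridge-stabilized inverse;
#' a new hybrid whose markers duplicate a training hybrid recovers that
#' hybrid's value.  Unseen metadata factor levels fall back to the training
#' reference level with a warning.
#'
#' @param fit A `gxe_ugblup`.
#' @param template Tibble of `(env_id, hybrid)` pairs to predict.
#' @param meta_new Environment metadata for the template environments,
#'   containing every fixed-effect column used at training.
#' @param K_cross Relationship matrix of template hybrids (rows) to training
#'   hybrids (columns), e.g. a slice of a kernel over all hybrids.  May be
#'   omitted when every template hybrid was in training.
#' @param ridge_eps Ridge added to `K_train` before inversion, as a fraction
#'   of its mean diagonal (default 1e-8).
#' @return A prediction tibble `env_id`, `hybrid`, `yield_mg_ha` with
#'   attribute `model = "A"`.
#' @export
predict_model_a <- function(fit, template, meta_new = NULL, K_cross = NULL,
                            ridge_eps = 1e-8) {
  stopifnot(inherits(fit, "gxe_ugblup"))
  check_columns(template, c("env_id", "hybrid"), "template")
  new_hyb <- setdiff(unique(template$hybrid), fit$hybrids)
  g_all <- fit$g
  if (length(new_hyb) > 0) {
    if (is.null(K_cross)) {
      stop_gxe(sprintf("no genotypes (K_cross) for new hybrid(s): %s",
                       paste(head(new_hyb, 5), collapse = ", ")),
               class = "gxe_format_error")
    }
    missing_k <- setdiff(new_hyb, rownames(K_cross))
    if (length(missing_k) > 0) {
      stop_gxe(sprintf("hybrid(s) absent from K_cross: %s",
                       paste(head(missing_k, 5), collapse = ", ")),
               class = "gxe_format_error")
    }
    Kc <- K_cross[new_hyb, fit$hybrids, drop = FALSE]
    Kt <- fit$K_train
    Kreg <- Kt + diag(ridge_eps * mean(diag(Kt)), nrow(Kt))
    g_new <- drop(Kc %*% solve(Kreg, fit$g))
    g_all <- c(g_all, stats::setNames(g_new, new_hyb))
  }
  envs <- unique(template$env_id)
  has_terms <- !is.null(fit$xinfo) &&
    length(attr(stats::delete.response(fit$xinfo$terms), "term.labels")) > 0
  if (!is.null(fit$xinfo) && !has_terms) {
    # intercept-only design: no metadata needed
    xb <- stats::setNames(rep(unname(fit$beta[1]), length(envs)), envs)
  } else if (has_terms) {
    if (is.null(meta_new)) {
      stop_gxe("`meta_new` is required: the fit has metadata fixed effects",
               "gxe_format_error")
    }
    check_columns(meta_new, "env_id", "metadata")
    meta_use <- meta_new[match(envs, meta_new$env_id), , drop = FALSE]
    if (anyNA(meta_use$env_id)) {
      stop_gxe("metadata missing for some template environments", "gxe_format_error")
    }
    xb <- stats::setNames(env_fixed_effects(fit, meta_use), envs)
  } else {
    xb <- stats::setNames(rep(0, length(envs)), envs)
  }
  out <- template |>
    dplyr::mutate(yield_mg_ha = unname(xb[.data$env_id] + g_all[.data$hybrid])) |>
    dplyr::select("env_id", "hybrid", "yield_mg_ha")
  attr(out, "model") <- "A"
  out
}

# Evaluate x(env)'beta for new environment metadata, mapping unseen factor
# levels to the training reference level (with a warning).
env_fixed_effects <- function(fit, meta_use) {
  tt <- stats::delete.response(fit$xinfo$terms)
  xlev <- fit$xinfo$xlevels
  df <- as.data.frame(meta_use)
  fellback <- character(0)
  for (v in names(xlev)) {
    if (!v %in% names(df)) {
      stop_gxe(sprintf("metadata column `%s` required for prediction", v),
               "gxe_format_error")
    }
    df[[v]] <- as.character(df[[v]])
    bad <- !df[[v]] %in% xlev[[v]]
    if (any(bad)) {
      fellback <- c(fellback, unique(df[[v]][bad]))
      df[[v]][bad] <- xlev[[v]][1]
    }
    df[[v]] <- factor(df[[v]], levels = xlev[[v]])
  }
  if (length(fellback) > 0) {
    warn_gxe(sprintf("unseen metadata level(s) mapped to the reference: %s",
                     paste(unique(fellback), collapse = ", ")))
  }
  mf <- stats::model.frame(tt, df, xlev = xlev)
  Xn <- stats::model.matrix(tt, mf)
  Xn <- Xn[, fit$xinfo$colnames, drop = FALSE]
  drop(Xn %*% fit$beta)
}
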