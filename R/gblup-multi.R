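#' Fit the multivariate (unstructured) multi-environment GBLUP by EM
#'
#' Fits the model `y* = g + e` on standardized phenotypes, where the stacked
#' genetic values over environments and hybrids have Kronecker covariance
#' `g ~ N(0, Sigma_g (x) K)` — an unstructured environment-by-environment
#' genetic covariance `Sigma_g` crossed with the genomic kernel `K` — and
#' residuals are independent with a per-environment plot-level variance,
#' `e ~ N(0, Sigma_e (x) I)`.
#'
#' Estimation is an exact expectation-maximization on the latent genetic
#' matrix, with the unbalanced hybrid-by-environment incidence handled by
#' conditional expectations: the E-step conditions the full genetic matrix
#' (every genotyped hybrid in every environment) on the observed cells, so
#' the output `g` is dense — predictions of every individual in every
#' environment — including pairs never observed.  The likelihood is the
#' plot-level one: replicates are summarized losslessly into cell means
#' (variance `Sigma_e[j] / n_reps`) plus within-cell residual sums of
#' squares, so replicate contrasts anchor the residual variances directly
#' and the genetic/residual partition does not lean on the kernel alone.
#' The per-iteration work reduces to one Cholesky factorization of the
#' observed-cell covariance; the observed-data log-likelihood is computed
#' from the same factor and asserted non-decreasing at every iteration.
#' `Sigma_g` is projected to the nearest PSD matrix (eigenvalue clipping)
#' each iteration.
#'
#' @param ystar A `gxe_std_pheno` from [standardize_spatial()], or a tibble
#'   with columns `env_id`, `hybrid`, `ystar`.
#' @param kernel A `gxe_kernel` covering every observed hybrid.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the relative change of the parameters
#'   (default 1e-6).
#' @param min_hybrids_per_env Environments with fewer observed hybrids are
#'   dropped with a warning (default 30).
#' @param envs Optional character vector restricting the fit to a subset of
#'   environments (default: all that pass `min_hybrids_per_env`).
#' @return A `gxe_mgblup` object: `g` (dense hybrid-by-environment matrix of
#'   genetic values on the standardized scale), `Sigma_g`, `Sigma_e` (named
#'   per-environment residual variances), `loglik_trace`, `iterations`,
#'   `converged`.
#' @export
fit_multivariate_gblup <- function(ystar, kernel, max_iter = 500, tol = 1e-6,
                                   min_hybrids_per_env = 30, envs = NULL) {
  stopifnot(inherits(kernel, "gxe_kernel"))
  vals <- if (inherits(ystar, "gxe_std_pheno")) ystar$values else ystar
  check_columns(vals, c("env_id", "hybrid", "ystar"), "standardized phenotypes")

  # summarize replicates losslessly: cell means + within-cell SS
  cells <- vals |>
    dplyr::group_by(.data$env_id, .data$hybrid) |>
    dplyr::summarise(y = mean(.data$ystar), r = dplyr::n(),
                     ssw = sum((.data$ystar - mean(.data$ystar))^2),
                     .groups = "drop")
  if (!is.null(envs)) cells <- dplyr::filter(cells, .data$env_id %in% envs)
  keep <- cells |>
    dplyr::count(.data$env_id) |>
    dplyr::filter(.data$n >= min_hybrids_per_env)
  dropped <- setdiff(unique(cells$env_id), keep$env_id)
  if (length(dropped) > 0) {
    warn_gxe(sprintf("dropping environment(s) with < %d hybrids: %s",
                     min_hybrids_per_env, paste(dropped, collapse = ", ")))
    cells <- dplyr::filter(cells, .data$env_id %in% keep$env_id)
  }
  env_ids <- sort(unique(cells$env_id))
  E <- length(env_ids)
  if (E < 1) stop_gxe("no environments left to fit", "gxe_config_error")
  unknown <- setdiff(unique(cells$hybrid), kernel$hybrids)
  if (length(unknown) > 0) {
    stop_gxe(sprintf("hybrid(s) absent from the kernel: %s",
                     paste(head(unknown, 5), collapse = ", ")), "gxe_format_error")
  }
  hybrids <- kernel$hybrids
  n <- length(hybrids)
  K <- kernel$matrix

  # identifiability: some pair of environments must share hybrids
  if (E > 1) {
    sets <- split(cells$hybrid, cells$env_id)
    overlaps <- utils::combn(E, 2, function(ix) {
      length(intersect(sets[[env_ids[ix[1]]]], sets[[env_ids[ix[2]]]]))
    })
    if (all(overlaps == 0)) {
      stop_gxe(paste("no pair of environments shares any hybrid;",
                     "between-environment genetic covariances are unidentifiable"),
               class = "gxe_design_error")
    }
  }

  cells <- dplyr::arrange(cells, match(.data$env_id, env_ids), .data$hybrid)
  i_idx <- match(cells$hybrid, hybrids)
  j_idx <- match(cells$env_id, env_ids)
  y <- cells$y
  r_c <- cells$r
  N <- length(y)

  K_oo <- K[i_idx, i_idx, drop = FALSE]
  K_o <- K[i_idx, , drop = FALSE]
  Kinv <- inv_sympd(K, jitter = 1e-8)
  dK_oo <- diag(K_oo)
  jfac <- factor(j_idx, levels = seq_len(E))
  ssw_j <- drop(tapply(cells$ssw, jfac, sum)); ssw_j[is.na(ssw_j)] <- 0
  plots_j <- drop(tapply(r_c, jfac, sum)); plots_j[is.na(plots_j)] <- 0
  cells_j <- tabulate(j_idx, E)

  # moment-based initialization: residual variance from within-cell
  # (replicate) contrasts where available, genetic variance as the remainder
  # of the cell-mean variance, off-diagonals from pairwise-complete
  # covariances of the cell means
  Ymat <- matrix(NA_real_, n, E, dimnames = list(hybrids, env_ids))
  Ymat[cbind(i_idx, j_idx)] <- y
  v_env <- pmax(drop(tapply(y, jfac, var)), 1e-6)
  rbar_j <- plots_j / pmax(cells_j, 1)
  df_w <- plots_j - cells_j
  sig2 <- ifelse(df_w > 0, ssw_j / pmax(df_w, 1), 0.5 * v_env * rbar_j)
  sig2 <- pmax(sig2, 1e-8)
  vg0 <- pmax(v_env - sig2 / rbar_j, 0.1 * v_env)
  C0 <- suppressWarnings(stats::cov(Ymat, use = "pairwise.complete.obs"))
  C0[!is.finite(C0)] <- 0
  R0 <- C0 / sqrt(outer(diag(C0) + 1e-12, diag(C0) + 1e-12))
  R0[!is.finite(R0)] <- 0
  R0 <- pmin(pmax(R0, -0.95), 0.95)
  diag(R0) <- 1
  Sigma_g <- project_psd(outer(sqrt(vg0), sqrt(vg0)) * R0)
  dimnames(Sigma_g) <- list(env_ids, env_ids)
  sig2 <- stats::setNames(sig2, env_ids)

  estep <- function(Sg, se) {
    em_estep(y, r_c, ssw_j, plots_j, i_idx, j_idx, jfac,
             K_oo, K_o, Kinv, dK_oo, Sg, se, n, E)
  }
  mstep <- function(step) {
    Sg <- project_psd(step$Sigma_g_new)
    dimnames(Sg) <- dimnames(Sigma_g)
    list(Sg = Sg, se = pmax(step$sig2_new, 1e-10))
  }

  pack <- function(th) c(th$Sg, th$se)
  record_ll <- function(ll_trace, ll, it) {
    # monotone log-likelihood is a structural guarantee of EM; a violation
    # beyond numerical noise means an update is wrong, so fail loudly
    if (length(ll_trace) > 0 &&
        ll < ll_trace[length(ll_trace)] - 1e-6 * (1 + abs(ll))) {
      stop_gxe(sprintf(
        "EM log-likelihood decreased at iteration %d (%.8g -> %.8g)",
        it, ll_trace[length(ll_trace)], ll), "gxe_numeric_error")
    }
    c(ll_trace, ll)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0
  th0 <- list(Sg = Sigma_g, se = sig2)
  # squared-extrapolation acceleration: each cycle takes two plain EM steps,
  # extrapolates along the curvature-corrected direction, and accepts the
  # jump only if the log-likelihood does not drop (the recorded trace stays
  # monotone; rejected proposals fall back to the second plain EM step)
  while (it < max_iter) {
    it <- it + 1
    s0 <- estep(th0$Sg, th0$se)
    ll_trace <- record_ll(ll_trace, s0$loglik, it)
    th1 <- mstep(s0)
    delta <- max(abs(pack(th1) - pack(th0))) / (max(abs(pack(th0))) + 1e-12)
    if (delta < tol) {
      th0 <- th1
      converged <- TRUE
      break
    }
    if (it >= max_iter) {
      th0 <- th1
      break
    }
    it <- it + 1
    s1 <- estep(th1$Sg, th1$se)
    ll_trace <- record_ll(ll_trace, s1$loglik, it)
    th2 <- mstep(s1)
    r <- pack(th1) - pack(th0)
    v <- (pack(th2) - pack(th1)) - r
    vnorm <- sqrt(sum(v^2))
    if (!is.finite(vnorm) || vnorm < 1e-14 || it >= max_iter) {
      th0 <- th2
      next
    }
    alpha <- max(-sqrt(sum(r^2)) / vnorm, -256)
    alpha <- min(alpha, -1)
    prop <- pack(th0) - 2 * alpha * r + alpha^2 * v
    Sg_p <- project_psd(matrix(prop[seq_len(E * E)], E, E,
                               dimnames = dimnames(th0$Sg)))
    se_p <- pmax(prop[E * E + seq_len(E)], 1e-10)
    names(se_p) <- names(th0$se)
    it <- it + 1
    s_p <- estep(Sg_p, se_p)
    if (s_p$loglik >= ll_trace[length(ll_trace)]) {
      ll_trace <- c(ll_trace, s_p$loglik)
      th0 <- mstep(s_p)
    } else {
      th0 <- th2
    }
  }
  Sigma_g <- th0$Sg
  sig2 <- th0$se
  # final E-step so g is consistent with the reported parameters
  step <- em_estep(y, r_c, ssw_j, plots_j, i_idx, j_idx, jfac,
                   K_oo, K_o, Kinv, dK_oo, Sigma_g, sig2, n, E)
  ghat <- step$ghat
  dimnames(ghat) <- list(hybrids, env_ids)

  structure(list(
    g = ghat, Sigma_g = Sigma_g, Sigma_e = sig2,
    envs = env_ids, hybrids = hybrids,
    loglik_trace = c(ll_trace, step$loglik),
    loglik = step$loglik, iterations = it, converged = converged,
    n_cells = N
  ), class = "gxe_mgblup")
}

# One E-step (plus the M-step sufficient statistics) of the Kronecker EM,
# computed entirely in the observed-cell space.  Cells are replicate means
# with residual variance sig2[j]/r_c; replicate (within-cell) contrasts enter
# the likelihood and the sig2 update through their sums of squares.
#   S = Sigma_g[j_r, j_s] * K_oo + diag(d_r),  d_r = sig2[j_r]/r_r
#   ghat_l = K_o' (Sigma_g[j, l] * W y),       W = S^{-1}
#   E[G' K^{-1} G] = ghat' K^{-1} ghat + n Sigma_g - Sigma_g A Sigma_g,
#     with A the per-environment-pair sums of K_oo * W
#   posterior cell variances from the identities U = S - diag(d),
#     W U = I - W diag(d), so diag(U' W U) needs no extra factorization.
em_estep <- function(y, r_c, ssw_j, plots_j, i_idx, j_idx, jfac,
                     K_oo, K_o, Kinv, dK_oo, Sigma_g, sig2, n, E) {
  N <- length(y)
  d_r <- sig2[j_idx] / r_c
  S <- Sigma_g[j_idx, j_idx, drop = FALSE] * K_oo
  diag(S) <- diag(S) + d_r
  cS <- chol_safe(S)
  W <- chol2inv(cS)
  v <- drop(W %*% y)
  cells_j <- tabulate(j_idx, E)
  ll_within <- -0.5 * sum((plots_j - cells_j) * log(2 * pi * sig2) +
                            ssw_j / sig2)
  loglik <- -0.5 * (N * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(y * v)) +
    ll_within

  A1 <- v * Sigma_g[j_idx, , drop = FALSE]           # N x E
  ghat <- crossprod(K_o, A1)                         # n x E
  G1 <- Kinv %*% ghat
  M1 <- crossprod(ghat, G1)                          # E x E

  T0 <- K_oo * W
  A <- rowsum(t(rowsum(T0, jfac)), jfac)             # E x E pair sums
  Cmat <- Sigma_g %*% A %*% Sigma_g
  Sigma_g_new <- (M1 + n * Sigma_g - Cmat) / n
  Sigma_g_new <- (Sigma_g_new + t(Sigma_g_new)) / 2

  U <- S
  diag(U) <- diag(U) - d_r
  V <- -sweep(W, 2, d_r, "*")
  diag(V) <- diag(V) + 1
  q <- colSums(U * V)
  var_cell <- pmax(Sigma_g[cbind(j_idx, j_idx)] * dK_oo - q, 0)
  resid2 <- (y - ghat[cbind(i_idx, j_idx)])^2
  sig2_new <- drop(rowsum(r_c * (resid2 + var_cell), jfac)) + ssw_j
  sig2_new <- sig2_new / pmax(plots_j, 1)
  names(sig2_new) <- names(sig2)

  list(loglik = loglik, ghat = ghat, Sigma_g_new = Sigma_g_new,
       sig2_new = sig2_new)
}

#' @export
print.gxe_mgblup <- function(x, ...) {
  cat(sprintf("<gxe_mgblup> %d environments, %d hybrids, %d observed cells\n",
              length(x$envs), length(x$hybrids), x$n_cells))
  cat(sprintf("  EM: %d iterations, %s, logLik = %.2f\n", x$iterations,
              if (x$converged) "converged" else "NOT converged", x$loglik))
  invisible(x)
}

#' Tidy the estimated genetic covariance of a multivariate GBLUP
#'
#' @param x A `gxe_mgblup`.
#' @param ... Unused.
#' @return Long tibble `env_1`, `env_2`, `covariance`, `correlation` plus the
#'   per-environment residual variance on the diagonal rows.
#' @export
tidy.gxe_mgblup <- function(x, ...) {
  d <- sqrt(diag(x$Sigma_g))
  corr <- x$Sigma_g / outer(pmax(d, 1e-12), pmax(d, 1e-12))
  tibble::as_tibble(x$Sigma_g, rownames = "env_1") |>
    tidyr::pivot_longer(-"env_1", names_to = "env_2", values_to = "covariance") |>
    dplyr::mutate(correlation = as.vector(corr),
                  residual_var = ifelse(.data$env_1 == .data$env_2,
                                        x$Sigma_e[.data$env_1], NA_real_))
}

#' @export
glance.gxe_mgblup <- function(x, ...) {
  tibble::tibble(n_envs = length(x$envs), n_hybrids = length(x$hybrids),
                 n_cells = x$n_cells, iterations = x$iterations,
                 converged = x$converged, logLik = x$loglik)
}

#' Heatmap of the estimated between-environment genetic correlation
#'
#' @param object A `gxe_mgblup`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gxe_mgblup <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$env_1, .data$env_2,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "genetic\ncorrelation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
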