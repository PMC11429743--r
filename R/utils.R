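#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm rbinom runif sd var cor coef lm model.matrix optimize
#'   predict quantile median rpois pt setNames complete.cases
#' @importFrom utils head
#' @import tibble
NULL

# Internal: consistent condition helpers -------------------------------------

stop_gxe <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "gxeyield_error"), ...)
}

warn_gxe <- function(msg, class = "gxeyield_warning") {
  rlang::warn(msg, class = class)
}

# Check that a data frame has the given columns, error naming the missing ones.
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_gxe(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "gxe_format_error"
    )
  }
  invisible(df)
}

# Derive a named per-stage seed from one master seed.  Documented fan-out:
# stage k gets (master * 7919 + k) mod (2^31 - 1), 7919 being the 1000th prime.
# Keeps every stage seed a valid 32-bit integer and distinct across stages.
stage_seeds <- function(master, stages) {
  stopifnot(is.numeric(master), length(master) == 1)
  m <- 2147483647
  s <- (as.double(master) %% m * 7919 + seq_along(stages)) %% m
  stats::setNames(as.integer(s), stages)
}

# Project a symmetric matrix to the nearest (Frobenius) PSD matrix by
# eigenvalue clipping; `floor_frac` clips at floor_frac * max eigenvalue.
project_psd <- function(S, floor_frac = 1e-8) {
  S <- (S + t(S)) / 2
  ee <- eigen(S, symmetric = TRUE)
  lo <- max(ee$values) * floor_frac
  vals <- pmax(ee$values, max(lo, 0))
  out <- ee$vectors %*% (vals * t(ee$vectors))
  dimnames(out) <- dimnames(S)
  (out + t(out)) / 2
}

# Cholesky with a diagonal jitter fallback for numerically semi-definite input.
chol_safe <- function(S, jitter = 1e-8) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  tries <- 0
  while (is.null(out) && tries < 6) {
    S <- S + diag(jitter * mean(diag(S)), nrow(S))
    out <- tryCatch(chol(S), error = function(e) NULL)
    jitter <- jitter * 10
    tries <- tries + 1
  }
  if (is.null(out)) stop_gxe("matrix is not positive definite", "gxe_numeric_error")
  out
}

# Symmetric matrix inverse via Cholesky.
inv_sympd <- function(S, jitter = 1e-10) chol2inv(chol_safe(S, jitter))

rmse <- function(x, y) sqrt(mean((x - y)^2))
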