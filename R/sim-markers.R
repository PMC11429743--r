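#' Simulate a hybrid-by-variant dosage matrix
#'
#' Draws biallelic dosages (0/1/2) for `n_hybrids` hybrids at `n_markers`
#' variants under Hardy-Weinberg proportions, with allele frequencies drawn
#' Uniform(0.1, 0.9) so every marker is informative and downstream genomic
#' kernels stay well conditioned.  Monomorphic columns (which cannot happen
#' with frequencies strictly inside (0, 1) but are guarded against anyway in
#' finite samples) are re-drawn to be polymorphic.
#'
#' @param config A [sim_config()].
#' @return A `gxe_marker_matrix`: list with `dosage` (integer matrix, hybrids
#'   in rows with names `H0001`, ...), and `freq` (drawn allele frequencies).
#' @examples
#' M <- simulate_marker_matrix(sim_config(n_hybrids = 20, n_markers = 50, seed = 1))
#' dim(M$dosage)
#' @export
simulate_marker_matrix <- function(config) {
  stopifnot(inherits(config, "gxe_sim_config"))
  validate_sim_config(config)
  n <- config$n_hybrids
  m <- config$n_markers
  set.seed(config$seed)
  freq <- runif(m, 0.1, 0.9)
  dosage <- vapply(seq_len(m), function(j) rbinom(n, 2L, freq[j]), integer(n))
  dosage <- matrix(as.integer(dosage), nrow = n)
  # Guard: re-draw any column fixed in this finite sample (possible for tiny n)
  for (j in seq_len(m)) {
    tries <- 0
    while (length(unique(dosage[, j])) == 1L && tries < 100) {
      dosage[, j] <- rbinom(n, 2L, freq[j])
      tries <- tries + 1
    }
    if (length(unique(dosage[, j])) == 1L) {
      # frequency so extreme the sample is always fixed
      stop_gxe(sprintf("marker %d is monomorphic (allele frequency %.3f)", j, freq[j]),
               class = "gxe_config_error")
    }
  }
  rownames(dosage) <- sprintf("H%04d", seq_len(n))
  colnames(dosage) <- sprintf("V%05d", seq_len(m))
  new_marker_matrix(dosage, freq)
}

#' Construct a marker matrix object from a dosage matrix
#'
#' @param dosage Matrix of 0/1/2 dosages, hybrids in rows (rownames required).
#' @param freq Optional allele frequency vector; estimated as column means / 2
#'   when omitted.
#' @return A `gxe_marker_matrix`.
#' @export
new_marker_matrix <- function(dosage, freq = NULL) {
  if (is.null(rownames(dosage))) {
    stop_gxe("dosage matrix must have hybrid rownames", "gxe_format_error")
  }
  if (anyNA(dosage)) {
    stop_gxe("dosage matrix must not contain missing values (impute upstream)",
             "gxe_format_error")
  }
  if (!all(dosage %in% c(0, 1, 2))) {
    stop_gxe("dosages must be 0, 1 or 2", "gxe_format_error")
  }
  if (is.null(freq)) freq <- colMeans(dosage) / 2
  if (any(freq <= 0 | freq >= 1)) {
    bad <- which(freq <= 0 | freq >= 1)
    stop_gxe(sprintf("monomorphic marker(s): %s (allele frequency must lie in (0,1))",
                     paste(head(colnames(dosage)[bad], 5), collapse = ", ")),
             class = "gxe_format_error")
  }
  structure(list(dosage = dosage, freq = freq, hybrids = rownames(dosage)),
            class = "gxe_marker_matrix")
}

#' @export
print.gxe_marker_matrix <- function(x, ...) {
  cat(sprintf("<gxe_marker_matrix> %d hybrids x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Tidy a marker matrix into a long tibble
#'
#' @param x A `gxe_marker_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `hybrid`, `variant`, `dosage`.
#' @export
tidy.gxe_marker_matrix <- function(x, ...) {
  tibble::as_tibble(x$dosage, rownames = "hybrid") |>
    tidyr::pivot_longer(-"hybrid", names_to = "variant", values_to = "dosage")
}
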