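#' Center a dosage matrix by twice the allele frequency
#'
#' Column `j` of the dosage matrix is shifted by `2 * p_j`, the standard
#' centering that turns dosages into additive allele-content deviations and
#' makes the angle between two hybrid rows a genuine genetic correlation
#' angle.
#'
#' @param M A `gxe_marker_matrix`.
#' @return Numeric matrix of centered dosages (hybrids in rows).
#' @examples
#' M <- simulate_marker_matrix(sim_config(n_hybrids = 10, n_markers = 20, seed = 1))
#' colMeans(center_markers(M))
#' @export
center_markers <- function(M) {
  stopifnot(inherits(M, "gxe_marker_matrix"))
  sweep(M$dosage, 2, 2 * M$freq)
}

new_genomic_kernel <- function(mat, kind) {
  stopifnot(isTRUE(all.equal(mat, t(mat), tolerance = 1e-10)))
  structure(list(matrix = (mat + t(mat)) / 2, kind = kind,
                 hybrids = rownames(mat)),
            class = "gxe_kernel")
}

#' First-order arc-cosine genomic kernel
#'
#' Computes the pairwise relationship among hybrids from centered marker
#' vectors with the first-order arc-cosine function
#' \deqn{k(x, x') = \frac{1}{\pi} \|x\| \|x'\| \left(\sin\theta +
#'   (\pi - \theta)\cos\theta\right), \qquad
#'   \theta = \arccos\frac{x \cdot x'}{\|x\|\|x'\|},}
#' the kernel of an infinitely wide one-layer rectifier network and a
#' nonlinear alternative to the additive relationship matrix.  With
#' `normalize = TRUE` (default) the kernel is rescaled to unit diagonal,
#' \eqn{\bar k(x,x') = k(x,x') / \sqrt{k(x,x)k(x',x')}}, so identical rows
#' score 1, orthogonal rows \eqn{1/\pi}, and antipodal rows 0.
#'
#' Higher-order (recursive) compositions are available through `order`, but
#' the first order is the default and the one used throughout the package.
#'
#' @param M A `gxe_marker_matrix`.
#' @param normalize Rescale to unit diagonal? Default `TRUE`.
#' @param order Number of arc-cosine layers (>= 1); default 1.
#' @return A `gxe_kernel` with kind `"arc_cosine"`.
#' @examples
#' M <- simulate_marker_matrix(sim_config(n_hybrids = 10, n_markers = 50, seed = 1))
#' K <- arc_cosine_kernel(M)
#' range(diag(K$matrix))
#' @export
arc_cosine_kernel <- function(M, normalize = TRUE, order = 1L) {
  Z <- center_markers(M)
  nrm2 <- rowSums(Z^2)
  if (any(nrm2 == 0)) {
    stop_gxe(sprintf("zero-norm centered genotype for hybrid(s): %s",
                     paste(rownames(Z)[nrm2 == 0], collapse = ", ")),
             class = "gxe_numeric_error")
  }
  Kmat <- tcrossprod(Z)
  for (i in seq_len(order)) {
    Kmat <- arc_cosine_step(Kmat)
  }
  if (normalize) {
    d <- sqrt(diag(Kmat))
    Kmat <- Kmat / outer(d, d)
    diag(Kmat) <- 1
  }
  dimnames(Kmat) <- list(rownames(Z), rownames(Z))
  new_genomic_kernel(Kmat, "arc_cosine")
}

# One arc-cosine layer applied to a Gram matrix: the closed form above with
# the cosine clipped to [-1, 1] before arccos.
arc_cosine_step <- function(Gram) {
  d <- sqrt(diag(Gram))
  ct <- Gram / outer(d, d)
  ct <- pmin(pmax(ct, -1), 1)
  theta <- acos(ct)
  out <- outer(d, d) * (sin(theta) + (pi - theta) * cos(theta)) / pi
  (out + t(out)) / 2
}

#' Additive genomic relationship matrix (VanRaden form)
#'
#' `Z Z' / (2 * sum(p_j (1 - p_j)))` with `Z` the 2p-centered dosage matrix;
#' the standard additive GRM, used as the simulation truth kernel and as a
#' baseline for the arc-cosine choice.
#'
#' @param M A `gxe_marker_matrix`.
#' @return A `gxe_kernel` with kind `"additive"`.
#' @export
additive_grm <- function(M) {
  Z <- center_markers(M)
  c0 <- 2 * sum(M$freq * (1 - M$freq))
  Kmat <- tcrossprod(Z) / c0
  dimnames(Kmat) <- list(rownames(Z), rownames(Z))
  new_genomic_kernel(Kmat, "additive")
}

#' @export
print.gxe_kernel <- function(x, ...) {
  cat(sprintf("<gxe_kernel> %s, %d hybrids\n", x$kind, nrow(x$matrix)))
  invisible(x)
}

#' Tidy a genomic kernel into a long tibble of pairwise relationships
#'
#' @param x A `gxe_kernel`.
#' @param ... Unused.
#' @return Tibble with columns `hybrid_1`, `hybrid_2`, `value`.
#' @export
tidy.gxe_kernel <- function(x, ...) {
  tibble::as_tibble(x$matrix, rownames = "hybrid_1") |>
    tidyr::pivot_longer(-"hybrid_1", names_to = "hybrid_2", values_to = "value")
}

#' Write / read a genomic kernel as labelled CSV
#'
#' @param kernel A `gxe_kernel`.
#' @param path File path.
#' @param kind Kernel kind tag to restore on read.
#' @return `write_kernel()` returns `path` invisibly; `read_kernel()` a
#'   `gxe_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  df <- tibble::as_tibble(kernel$matrix, rownames = "hybrid")
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path, kind = "arc_cosine") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df$hybrid
  new_genomic_kernel(mat, kind)
}
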