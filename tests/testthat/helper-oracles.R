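# Independent oracles used by the model tests.

# Plain EM for the no-fixed-effect one-way random-effects model
# y_ij = g_i + e_ij with g ~ N(0, Vg I): an independent maximum-likelihood
# algorithm to cross-check the spectral variance-component solver.
em_random_effect_ml <- function(y, id, iter = 5000, tol = 1e-12) {
  id <- as.integer(factor(id))
  n <- max(id)
  ni <- tabulate(id, n)
  ybar <- as.numeric(tapply(y, id, mean))
  vg <- var(ybar) / 2
  ve <- vg
  for (k in seq_len(iter)) {
    v_i <- 1 / (1 / vg + ni / ve)
    m_i <- v_i * ni / ve * ybar
    vg_new <- mean(m_i^2 + v_i)
    resid2 <- (y - m_i[id])^2
    ve_new <- (sum(resid2) + sum(ni * v_i)) / length(y)
    if (max(abs(c(vg_new - vg, ve_new - ve))) < tol * (vg + ve)) {
      vg <- vg_new; ve <- ve_new
      break
    }
    vg <- vg_new; ve <- ve_new
  }
  c(Vg = vg, Ve = ve)
}

# Brute-force E-step for the Kronecker model: full posterior of vec(G) given
# the observed cells, dense linear algebra, no structure exploited.
brute_force_estep <- function(y, r_c, ssw, i_idx, j_idx, K, Sg, se, n, E) {
  N <- length(y)
  Sig <- kronecker(Sg, K)
  Z <- matrix(0, N, n * E)
  for (r in seq_len(N)) Z[r, (j_idx[r] - 1) * n + i_idx[r]] <- 1
  S <- Z %*% Sig %*% t(Z) + diag(se[j_idx] / r_c, N)
  Sinv <- solve(S)
  ghat <- matrix(Sig %*% t(Z) %*% Sinv %*% y, n, E)
  Cpost <- Sig - Sig %*% t(Z) %*% Sinv %*% Z %*% Sig
  Kinv <- solve(K)
  EGKG <- matrix(0, E, E)
  for (j in seq_len(E)) for (l in seq_len(E)) {
    blk <- Cpost[(j - 1) * n + seq_len(n), (l - 1) * n + seq_len(n)]
    EGKG[j, l] <- t(ghat[, j]) %*% Kinv %*% ghat[, l] + sum(Kinv * t(blk))
  }
  v_cell <- vapply(seq_len(N), function(r) {
    pos <- (j_idx[r] - 1) * n + i_idx[r]
    Cpost[pos, pos]
  }, numeric(1))
  plots_j <- as.numeric(tapply(r_c, factor(j_idx, seq_len(E)), sum))
  ssw_j <- as.numeric(tapply(ssw, factor(j_idx, seq_len(E)), sum))
  resid2 <- (y - ghat[cbind(i_idx, j_idx)])^2
  sig2_new <- as.numeric(tapply(r_c * (resid2 + v_cell),
                                factor(j_idx, seq_len(E)), sum))
  sig2_new <- (sig2_new + ssw_j) / plots_j
  cells_j <- tabulate(j_idx, E)
  ll <- -0.5 * (N * log(2 * pi) + determinant(S)$modulus +
                  drop(t(y) %*% Sinv %*% y)) -
    0.5 * sum((plots_j - cells_j) * log(2 * pi * se) + ssw_j / se)
  list(loglik = as.numeric(ll), ghat = ghat, Sigma_g_new = EGKG / n,
       sig2_new = sig2_new)
}
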