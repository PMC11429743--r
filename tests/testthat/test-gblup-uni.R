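sim_gblup_data <- function(n = 80, m = 200, h2 = 0.5, seed = 1, reps = 1) {
  cfg <- sim_config(n_hybrids = n, n_markers = m, seed = seed)
  M <- simulate_marker_matrix(cfg)
  K <- additive_grm(M)
  set.seed(seed + 1000)
  g <- drop(gxeyield:::mat_sqrt(K$matrix) %*% rnorm(n))
  g <- g / sd(g)
  ve <- (1 - h2) / h2
  d <- tidyr::expand_grid(hybrid = M$hybrids, rep = seq_len(reps)) |>
    dplyr::mutate(y = 10 + g[match(.data$hybrid, M$hybrids)] +
                    rnorm(dplyr::n(), 0, sqrt(ve)))
  list(data = d, K = K, g = g, M = M)
}

test_that("identity-kernel fit matches an independent EM oracle and lme4", {
  set.seed(3)
  n <- 60
  g <- rnorm(n, 0, 1.2)
  d <- tibble::tibble(hybrid = rep(sprintf("H%02d", 1:n), each = 3),
                      y = rep(g, each = 3) + rnorm(3 * n))
  Kid <- gxeyield:::new_genomic_kernel(
    diag(1, n, n) |> `dimnames<-`(list(sprintf("H%02d", 1:n),
                                       sprintf("H%02d", 1:n))), "additive")
  # ML route (no fixed effects) against the independent EM implementation
  fit_ml <- fit_univariate_gblup(d, Kid, fixed = NULL, response = "y")
  oracle <- em_random_effect_ml(d$y, d$hybrid)
  expect_equal(fit_ml$Vg, unname(oracle["Vg"]), tolerance = 1e-6)
  expect_equal(fit_ml$Ve, unname(oracle["Ve"]), tolerance = 1e-6)
  # REML route (intercept) against lme4
  skip_if_not_installed("lme4")
  fit_reml <- fit_univariate_gblup(d, Kid, fixed = ~1, response = "y")
  lmm <- lme4::lmer(y ~ 1 + (1 | hybrid), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_equal(fit_reml$Vg, vc$vcov[vc$grp == "hybrid"], tolerance = 1e-5)
  expect_equal(fit_reml$Ve, vc$vcov[vc$grp == "Residual"], tolerance = 1e-5)
  expect_equal(unname(fit_reml$beta[1]), unname(lme4::fixef(lmm)[1]),
               tolerance = 1e-5)
})

test_that("GBLUP equals closed-form ridge regression with lambda = Ve*c/Vg", {
  s <- sim_gblup_data(n = 50, m = 100, seed = 4)
  fit <- fit_univariate_gblup(s$data, s$K, response = "y")
  Z <- center_markers(s$M)
  c0 <- 2 * sum(s$M$freq * (1 - s$M$freq))
  lam <- fit$Ve * c0 / fit$Vg
  beta_r <- solve(crossprod(Z) + lam * diag(ncol(Z)),
                  crossprod(Z, s$data$y - fit$beta[1]))
  expect_equal(unname(fit$g), unname(drop(Z %*% beta_r)), tolerance = 1e-6)
})

test_that("pure-noise data yields near-zero heritability estimates", {
  # replicated records anchor Ve, so the null has no flat Vg/Ve ridge
  frac_high <- mean(sapply(1:20, function(s) {
    sim <- sim_gblup_data(n = 300, m = 300, seed = 200 + s, reps = 2)
    d <- dplyr::mutate(sim$data, y = rnorm(dplyr::n()))  # no signal
    fit <- fit_univariate_gblup(d, sim$K, response = "y")
    fit$h2 >= 0.05
  }))
  expect_lte(frac_high, 0.10)
})

test_that("fits are invariant to record order", {
  s <- sim_gblup_data(n = 40, m = 100, seed = 6, reps = 2)
  fit1 <- fit_univariate_gblup(s$data, s$K, response = "y")
  perm <- sample(nrow(s$data))
  fit2 <- fit_univariate_gblup(s$data[perm, ], s$K, response = "y")
  expect_equal(fit1$Vg, fit2$Vg, tolerance = 1e-8)
  expect_equal(fit1$g, fit2$g, tolerance = 1e-8)
})

test_that("singular fixed designs error with the aliased columns named", {
  s <- sim_gblup_data(n = 30, m = 80, seed = 7)
  d <- dplyr::mutate(s$data, x1 = rnorm(dplyr::n()), x2 = x1)
  expect_error(fit_univariate_gblup(d, s$K, fixed = ~ x1 + x2, response = "y"),
               "x2", class = "gxe_design_error")
  expect_message(
    fit_univariate_gblup(d, s$K, fixed = ~ x1 + x2, response = "y",
                         drop_aliased = TRUE),
    "x2")
})

test_that("non-PSD kernels are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2, 2,
                dimnames = list(c("H1", "H2"), c("H1", "H2")))
  Kbad <- structure(list(matrix = bad, kind = "additive",
                         hybrids = c("H1", "H2")), class = "gxe_kernel")
  d <- tibble::tibble(hybrid = c("H1", "H2"), y = c(1, 2))
  expect_error(fit_univariate_gblup(d, Kbad, response = "y"),
               class = "gxe_numeric_error")
})

test_that("predictions project duplicated hybrids onto their training values", {
  s <- sim_gblup_data(n = 40, m = 150, seed = 8)
  fit <- fit_univariate_gblup(s$data, s$K, response = "y")
  # a "new" hybrid with identical markers duplicates a training column of K
  Kx <- rbind(HNEW = s$K$matrix["H0001", ], s$K$matrix)
  tmpl <- tibble::tibble(env_id = "E1", hybrid = c("HNEW", "H0002"))
  pred <- predict_model_a(fit, tmpl, K_cross = Kx)
  expect_equal(pred$yield_mg_ha[1] - fit$beta[1] |> unname(),
               unname(fit$g["H0001"]), tolerance = 1e-6)
  # in-sample template rows reproduce fitted values
  expect_equal(pred$yield_mg_ha[2], unname(fit$beta[1] + fit$g["H0002"]),
               tolerance = 1e-8)
})

test_that("metadata fixed effects predict through unseen levels with fallback", {
  set.seed(9)
  s <- sim_gblup_data(n = 40, m = 100, seed = 9, reps = 2)
  d <- s$data |>
    dplyr::mutate(env_id = rep(c("E1", "E2"), length.out = dplyr::n()),
                  trt = ifelse(.data$env_id == "E1", "standard", "dry"),
                  y = .data$y + ifelse(.data$trt == "dry", -1, 0))
  fit <- fit_univariate_gblup(d, s$K, fixed = ~trt, response = "y")
  meta_new <- tibble::tibble(env_id = c("E3", "E4"), trt = c("dry", "late"))
  tmpl <- tibble::tibble(env_id = rep(c("E3", "E4"), each = 2),
                         hybrid = rep(s$M$hybrids[1:2], 2))
  expect_warning(pred <- predict_model_a(fit, tmpl, meta_new = meta_new),
                 "unseen")
  # E4 ("late", unseen) falls back to the reference level prediction
  ref <- unname(fit$beta[1])
  expect_equal(pred$yield_mg_ha[pred$env_id == "E4"][1],
               ref + unname(fit$g[s$M$hybrids[1]]), tolerance = 1e-8)
  # missing genotypes for a truly new hybrid error
  expect_error(predict_model_a(fit, tibble::tibble(env_id = "E3", hybrid = "HX"),
                               meta_new = meta_new),
               "HX", class = "gxe_format_error")
})

test_that("simulated heritability is recovered on average", {
  h2s <- sapply(1:8, function(s) {
    sim <- sim_gblup_data(n = 250, m = 400, h2 = 0.5, seed = 300 + s)
    fit_univariate_gblup(sim$data, sim$K, response = "y")$h2
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.07)
})
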