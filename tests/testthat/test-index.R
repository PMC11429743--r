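test_that("pair accuracy is 1 for self-prediction and ~0 for unrelated sets", {
  M <- simulate_marker_matrix(sim_config(n_hybrids = 60, n_markers = 1000,
                                         seed = 11))
  K <- arc_cosine_kernel(M)
  setA <- M$hybrids[1:20]
  expect_equal(pair_accuracy(K, setA, setA), 1)
  # on the additive relationship scale, independently simulated genotypes
  # are essentially unrelated (the arc-cosine kernel floors at 1/pi instead)
  Ka <- additive_grm(M)
  expect_equal(pair_accuracy(Ka, setA, setA), 1)
  expect_lt(pair_accuracy(Ka, M$hybrids[21:40], M$hybrids[41:60]), 0.1)
  expect_error(pair_accuracy(K, "nope", setA), class = "gxe_format_error")
  expect_error(pair_accuracy(K, character(0), setA), class = "gxe_format_error")
})

test_that("nested training sets score at least as high as disjoint ones", {
  M <- simulate_marker_matrix(sim_config(n_hybrids = 40, n_markers = 500,
                                         seed = 12))
  K <- arc_cosine_kernel(M)
  target <- M$hybrids[1:10]
  wins <- sapply(1:20, function(s) {
    set.seed(s)
    sup <- c(target, sample(setdiff(M$hybrids, target), 10))
    dis <- sample(setdiff(M$hybrids, target), 20)
    pair_accuracy(K, sup, target) >= pair_accuracy(K, dis, target)
  })
  expect_true(all(wins))
})

test_that("location weights follow accuracy times geography and normalize", {
  meta <- tibble::tibble(
    env_id = c("T", "A1", "A2", "B1", "C1"),
    state = c("ST1", "ST1", "ST1", "ST2", "ST3"),
    station = c("L01", "L01", "L02", "L03", "L04"))
  # single environment gets all the weight
  w1 <- location_weights(tibble::tibble(env_id = "A1", accuracy = 0.3),
                         meta, "T")
  expect_equal(w1$weight, 1)
  # equal accuracies: same-station 1.0 vs three different-state 0.5
  acc <- tibble::tibble(env_id = c("A1", "B1", "C1", "C1x"), accuracy = 1)
  meta2 <- dplyr::bind_rows(meta, tibble::tibble(env_id = "C1x", state = "ST4",
                                                 station = "L05"))
  w2 <- location_weights(acc, meta2, "T")
  expect_equal(w2$weight[w2$env_id == "A1"], 1 / (1 + 3 * 0.5))
  # random inputs normalize to exactly one
  for (s in 1:20) {
    set.seed(s)
    accr <- tibble::tibble(env_id = c("A1", "A2", "B1", "C1"),
                           accuracy = runif(4))
    expect_equal(sum(location_weights(accr, meta, "T")$weight), 1,
                 tolerance = 1e-12)
  }
  # all-zero accuracies fall back to uniform with a warning
  expect_warning(
    w0 <- location_weights(tibble::tibble(env_id = c("A1", "B1"), accuracy = 0),
                           meta, "T"),
    "uniform")
  expect_equal(w0$weight, c(0.5, 0.5))
})

fake_mgblup <- function(G) {
  structure(list(g = G, envs = colnames(G), hybrids = rownames(G),
                 Sigma_g = diag(ncol(G))), class = "gxe_mgblup")
}

test_that("the selection index rescales exactly to sigma_k", {
  set.seed(13)
  G <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(sprintf("H%02d", 1:40), c("E1", "E2", "E3")))
  fit <- fake_mgblup(G)
  w <- tibble::tibble(env_id = c("E1", "E2", "E3"), weight = c(0.5, 0.3, 0.2))
  u <- selection_index(fit, w, sigma_k = 1.3, hybrids_target = rownames(G))
  expect_equal(sd(u$u), 1.3, tolerance = 1e-8)
  expect_equal(mean(u$u), 0, tolerance = 1e-8)

  # weights concentrated on one environment return that environment's
  # genomic values, z-scored and rescaled
  w1 <- tibble::tibble(env_id = c("E1", "E2", "E3"), weight = c(0, 1, 0))
  u1 <- selection_index(fit, w1, sigma_k = 2, hybrids_target = rownames(G))
  expect_equal(u1$u, 2 * as.numeric(scale(G[, "E2"])), tolerance = 1e-8)

  # shifting one environment's genomic values leaves the index unchanged
  G2 <- G; G2[, "E2"] <- G2[, "E2"] + 5
  u2 <- selection_index(fake_mgblup(G2), w, 1.3, rownames(G))
  expect_equal(u2$u, u$u, tolerance = 1e-10)

  # degenerate cases error
  expect_error(selection_index(fit, w, 0, rownames(G)),
               class = "gxe_format_error")
  Gc <- G; Gc[] <- 1
  expect_error(selection_index(fake_mgblup(Gc), w, 1, rownames(Gc)),
               class = "gxe_numeric_error")
})

test_that("Model B predictions decompose into mean plus rescaled merit", {
  set.seed(14)
  G <- matrix(rnorm(30 * 2), 30, 2,
              dimnames = list(sprintf("H%02d", 1:30), c("E1", "E2")))
  fit <- fake_mgblup(G)
  w <- tibble::tibble(env_id = c("E1", "E2"), weight = c(0.6, 0.4))
  template <- tidyr::expand_grid(env_id = c("T1", "T2"),
                                 hybrid = rownames(G))
  idx <- list(T1 = selection_index(fit, w, 1.1, rownames(G)),
              T2 = selection_index(fit, w, 0.7, rownames(G)))
  means <- tibble::tibble(env_id = c("T1", "T2"), env_mean_pred = c(9, 12))
  pred <- model_b_predictions(means, idx, template)
  by_env <- pred |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(m = mean(.data$yield_mg_ha), s = sd(.data$yield_mg_ha))
  expect_equal(by_env$m, c(9, 12), tolerance = 1e-8)
  expect_equal(by_env$s, c(1.1, 0.7), tolerance = 1e-8)
  # missing coverage errors
  expect_error(model_b_predictions(means, idx["T1"], template),
               "T2", class = "gxe_format_error")
  expect_error(
    model_b_predictions(means[1, ], idx, template),
    "T2", class = "gxe_format_error")
})

test_that("ensembles average element-wise and check coverage", {
  set.seed(15)
  p1 <- tibble::tibble(env_id = rep(c("E1", "E2"), each = 5),
                       hybrid = rep(sprintf("H%d", 1:5), 2),
                       yield_mg_ha = rnorm(10, 10))
  expect_equal(ensemble_average(list(p1)), p1, ignore_attr = TRUE)
  expect_equal(ensemble_average(list(p1, p1))$yield_mg_ha, p1$yield_mg_ha)
  p2 <- dplyr::mutate(p1, yield_mg_ha = yield_mg_ha + 2)
  expect_equal(ensemble_average(list(p1, p2))$yield_mg_ha,
               p1$yield_mg_ha + 1)
  expect_error(ensemble_average(list(p1, p1[-1, ])), class = "gxe_format_error")
})

test_that("per-environment ensemble RMSE never exceeds the member mean", {
  set.seed(16)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    truth <- tibble::tibble(env_id = "E", hybrid = sprintf("H%02d", 1:n),
                            yield_mg_ha = rnorm(n, 10, 2))
    members <- lapply(1:3, function(k) {
      dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + rnorm(n, sd = runif(1, 0.5, 3)))
    })
    ens <- ensemble_average(members)
    r_ens <- score_predictions(ens, truth)$summary$rmse_env_avg
    r_mem <- sapply(members, function(p) {
      score_predictions(p, truth)$summary$rmse_env_avg
    })
    expect_lte(r_ens, mean(r_mem) + 1e-12)
  }
})

test_that("submissions are written in the documented format", {
  p <- tibble::tibble(env_id = c("E1", "E2"), hybrid = c("H1", "H2"),
                      yield_mg_ha = c(9.1234567, 10.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_submission(p, path)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(Yield_Mg_ha = readr::col_character()))
  expect_equal(names(out), c("Env", "Hybrid", "Yield_Mg_ha"))
  expect_equal(out$Yield_Mg_ha, c("9.123457", "10.500000"))
})
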