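toy_truth <- function() {
  tibble::tibble(env_id = rep(c("E1", "E2"), each = 4),
                 hybrid = rep(sprintf("H%d", 1:4), 2),
                 yield_mg_ha = c(8, 9, 10, 11, 10, 12, 14, 16))
}

test_that("scoring reproduces hand-computed RMSEs and handles edge cases", {
  truth <- toy_truth()
  expect_equal(score_predictions(truth, truth)$summary$rmse_env_avg, 0)
  expect_equal(score_predictions(truth, truth)$summary$rmse_global, 0)

  # uniform errors of 1 and 3 Mg/ha in the two environments
  pred <- dplyr::mutate(truth,
                        yield_mg_ha = yield_mg_ha + ifelse(env_id == "E1", 1, 3))
  sc <- score_predictions(pred, truth)
  expect_equal(sort(sc$per_env$rmse), c(1, 3))
  expect_equal(sc$summary$rmse_env_avg, 2)

  # constant predictions: Pearson undefined everywhere, RMSE still returned
  const <- dplyr::mutate(truth, yield_mg_ha = 10)
  sc2 <- score_predictions(const, truth)
  expect_true(all(is.na(sc2$per_env$pearson)))
  expect_true(is.na(sc2$summary$pearson_env_avg))
  expect_false(is.na(sc2$summary$rmse_env_avg))

  # pairs absent from the truth are ignored and counted
  pred3 <- dplyr::bind_rows(truth, tibble::tibble(env_id = "E9", hybrid = "H1",
                                                  yield_mg_ha = 5))
  sc3 <- score_predictions(pred3, truth)
  expect_equal(sc3$summary$n_ignored, 1)

  expect_error(score_predictions(
    tibble::tibble(env_id = "X", hybrid = "Y", yield_mg_ha = 1), truth),
    class = "gxe_format_error")
})

test_that("global RMSE^2 is the count-weighted mean of per-environment MSEs", {
  set.seed(20)
  for (i in 1:20) {
    nper <- sample(2:8, 3, replace = TRUE)
    truth <- tibble::tibble(
      env_id = rep(sprintf("E%d", 1:3), nper),
      hybrid = unlist(lapply(nper, function(k) sprintf("H%d", 1:k))),
      yield_mg_ha = rnorm(sum(nper), 10, 2))
    pred <- dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + rnorm(sum(nper)))
    sc <- score_predictions(pred, truth)
    expect_equal(sc$summary$rmse_global^2,
                 sum(sc$per_env$n * sc$per_env$rmse^2) / sum(sc$per_env$n),
                 tolerance = 1e-12)
  }
})

test_that("ranking is invariant to a constant shift of predictions and truth", {
  set.seed(21)
  truth <- toy_truth()
  subs <- list(a = dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + rnorm(8, 0, 0.5)),
               b = dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + rnorm(8, 0, 2)))
  lb1 <- build_leaderboard(subs, truth)
  shift <- function(p) dplyr::mutate(p, yield_mg_ha = yield_mg_ha + 7)
  lb2 <- build_leaderboard(lapply(subs, shift), shift(truth))
  expect_equal(lb1$rmse_env_avg_rank, lb2$rmse_env_avg_rank)
})

test_that("leaderboards rank densely with label-ordered ties", {
  truth <- toy_truth()
  one <- build_leaderboard(list(solo = truth), truth)
  expect_equal(one$rmse_env_avg_rank, 1L)
  same <- dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + 1)
  lb <- build_leaderboard(list(zeta = same, alpha = same), truth)
  expect_equal(lb$team[lb$rmse_env_avg_rank == 1], "alpha")  # tie by label
  expect_true(all(lb$tied))
  # noisier submissions rank strictly worse
  set.seed(22)
  noisy <- lapply(c(t1 = 0.2, t2 = 0.8, t3 = 1.6, t4 = 3, t5 = 6), function(s) {
    dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + rnorm(8, 0, s))
  })
  lbn <- build_leaderboard(noisy, truth)
  expect_equal(lbn$team[order(lbn$rmse_env_avg_rank)],
               paste0("t", 1:5))
})

test_that("top-n spread matches the published leaderboard", {
  t2 <- g2f_table("table2")
  expect_equal(top_n_spread(t2, 10), 0.215, tolerance = 1e-12)
  expect_equal(top_n_spread(t2, 1), 0)
  # non-decreasing in n (order-statistic property)
  set.seed(23)
  for (i in 1:50) {
    lb <- tibble::tibble(rmse_env_avg = rnorm(15, 3, 0.5))
    sp <- sapply(1:15, top_n_spread, lb = lb)
    expect_true(all(diff(sp) >= 0))
  }
  expect_error(top_n_spread(t2, 21), class = "gxe_format_error")
})

test_that("usage percentages reproduce every published footer", {
  expect_equal(
    unname(usage_percentages(g2f_table("table3"))),
    c(63, 52, 33, 7, 52))
  expect_equal(
    unname(usage_percentages(g2f_table("table4"))),
    c(93, 74, 74, 63, 48, 30, 22))
  expect_equal(unname(usage_percentages(tibble::tibble(x = c(FALSE, FALSE)))), 0)
  # ties round up
  expect_equal(unname(usage_percentages(tibble::tibble(x = c(TRUE, FALSE)))), 50)
  expect_equal(unname(usage_percentages(
    tibble::tibble(x = c(rep(TRUE, 1), rep(FALSE, 199)), y = rep(TRUE, 200)))),
    c(1, 100))
})

test_that("Spearman rank correlation matches a brute-force computation", {
  out <- rank_submission_correlation(1:5, c(3, 5, 5, 8, 9))
  # hand computation with average ranks: ranks of counts are 1, 2.5, 2.5, 4, 5
  rho_bf <- 9.5 / sqrt(10 * 9.5)
  expect_equal(out$rho, rho_bf, tolerance = 1e-12)
  t_bf <- rho_bf * sqrt(3 / (1 - rho_bf^2))
  expect_equal(out$p_value, 2 * pt(-abs(t_bf), df = 3), tolerance = 1e-12)

  expect_equal(rank_submission_correlation(1:6, 6:1)$rho, -1)
  expect_error(rank_submission_correlation(1:6, rep(2, 6)),
               class = "gxe_numeric_error")
  expect_error(rank_submission_correlation(1:3, 1:3), class = "gxe_format_error")

  # null behavior: independent vectors give mean rho near zero
  set.seed(24)
  rhos <- replicate(500, rank_submission_correlation(
    sample(30), sample(30, replace = TRUE))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("QC removal counts track the injected artifact rates", {
  cfg <- sim_config(n_hybrids = 150, n_markers = 50, n_locations = 8,
                    n_years = 2, n_states = 4, outlier_rate = 0.01,
                    low_stand_rate = 0.01, disease_trial_rate = 0, seed = 55)
  b <- simulate_g2f_bundle(cfg)
  out <- qc_filter(b$trials, meta = b$meta)
  counts <- qc_removals(out)
  n <- nrow(b$trials)
  flagged_out <- sum(b$truth$artifacts$is_outlier)
  flagged_low <- sum(b$truth$artifacts$is_low_stand)
  # stand removals equal the injected low-stand plots exactly
  expect_equal(counts[["stand"]], flagged_low)
  # SD removals: all injected outliers caught, false positives only from the
  # ~0.3% Gaussian tail beyond 3 SD
  expect_gte(counts[["sd"]], flagged_out)
  expect_lte(counts[["sd"]], flagged_out + qbinom(0.999, n, 0.004))
  # both injected counts sit inside the binomial 99% interval of rate * n
  for (fl in c(flagged_out, flagged_low)) {
    expect_gte(fl, qbinom(0.005, n, 0.01))
    expect_lte(fl, qbinom(0.995, n, 0.01))
  }
})
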