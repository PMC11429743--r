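toy_qc_table <- function() {
  # 20 records in one environment: 18 well-behaved, one gross outlier at
  # +6 clean SD (catchable in one pass at n = 20), one low stand count
  y <- rep(c(9, 10, 11), length.out = 18)
  out <- mean(y) + 6 * sd(y)
  tibble::tibble(
    env_id = "E1",
    hybrid = sprintf("H%02d", 1:20),
    yield_mg_ha = c(y, out, 10),
    stand_count = c(rep(75L, 19), 19L)
  )
}

test_that("QC removes outliers, low stands and disease trials with counts", {
  tr <- toy_qc_table()
  out <- qc_filter(tr)
  expect_equal(nrow(out), 18)
  expect_equal(unname(qc_removals(out)),
               c(0L, 0L, 1L, 1L))  # missing, disease, stand, sd
  expect_named(qc_removals(out), c("missing", "disease", "stand", "sd"))

  # disease environments are dropped wholesale via the metadata treatment
  tr2 <- dplyr::bind_rows(
    dplyr::mutate(tr, env_id = "E1"),
    tibble::tibble(env_id = "E2", hybrid = sprintf("H%02d", 1:5),
                   yield_mg_ha = 9:13, stand_count = 75L))
  meta <- tibble::tibble(env_id = c("E1", "E2"),
                         treatment = c("Standard", "Disease trial"))
  out2 <- qc_filter(tr2, meta = meta)
  expect_equal(qc_removals(out2)[["disease"]], 5L)
  expect_false(any(out2$env_id == "E2"))
  # toggling drop_disease retains them
  out3 <- qc_filter(tr2, meta = meta, drop_disease = FALSE)
  expect_true(any(out3$env_id == "E2"))
})

test_that("QC on an empty table returns an empty table with zero counts", {
  empty <- tibble::tibble(env_id = character(), yield_mg_ha = numeric(),
                          stand_count = integer())
  out <- qc_filter(empty)
  expect_equal(nrow(out), 0)
  expect_true(all(qc_removals(out) == 0))
})

test_that("QC warns when an environment is too small for the SD rule", {
  tr <- tibble::tibble(env_id = "tiny", yield_mg_ha = c(1, 100),
                       stand_count = 75L)
  expect_warning(qc_filter(tr), "SD rule skipped")
})

test_that("QC is monotone in its thresholds", {
  b <- small_bundle()
  tr <- b$trials
  n_loose <- nrow(suppressWarnings(qc_filter(tr, sd_threshold = 4, min_stand = 10,
                                             meta = b$meta)))
  n_base <- nrow(suppressWarnings(qc_filter(tr, meta = b$meta)))
  n_tight <- nrow(suppressWarnings(qc_filter(tr, sd_threshold = 2.5, min_stand = 30,
                                             meta = b$meta)))
  expect_lte(n_tight, n_base)
  expect_lte(n_base, n_loose)
})

test_that("metadata aggregation follows the keyword table", {
  raw <- tibble::tibble(
    env_id = paste0("E", 1:6),
    treatment = c("Standard", "Dryland stress", "LATE planted", "drought plot",
                  "irrigated optimal", "Standard"),
    previous_crop = c("Soybean", "winter Wheat", "corn", "Maize silage",
                      "canola", "Alfalfa")
  )
  agg <- aggregate_metadata(raw)
  expect_equal(agg$previous_crop_class,
               c("legume", "wheat", "corn", "corn", "other", "legume"))
  expect_equal(agg$treatment_class,
               c("standard", "dry", "late", "dry", "standard", "standard"))
  expect_equal(agg$irrigated,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # explicit irrigated column is OR-ed in
  agg2 <- aggregate_metadata(dplyr::mutate(raw, irrigated = TRUE))
  expect_true(all(agg2$irrigated))
})

test_that("standardization removes block effects and is idempotent", {
  set.seed(11)
  tr <- two_block_env(shift = 2)
  std <- standardize_spatial(tr)
  # block-adjusted SD below raw SD
  expect_lt(std$scale$scale, sd(tr$yield_mg_ha))
  expect_equal(mean(std$values$ystar), 0, tolerance = 1e-8)
  expect_equal(sd(std$values$ystar), 1, tolerance = 1e-8)

  # already centered/scaled single-block data passes through
  tr2 <- tibble::tibble(env_id = "E1", hybrid = sprintf("H%02d", 1:12),
                        replicate = 1L, block = "B1",
                        yield_mg_ha = as.numeric(scale(rnorm(12))))
  std2 <- standardize_spatial(tr2)
  expect_equal(std2$values$ystar, tr2$yield_mg_ha, tolerance = 1e-10)

  # invariant to a constant shift of the environment
  std3 <- standardize_spatial(dplyr::mutate(tr, yield_mg_ha = yield_mg_ha + 5))
  expect_equal(std$values$ystar, std3$values$ystar, tolerance = 1e-10)
})

test_that("standardization holds per environment on a simulated bundle", {
  b <- small_bundle()
  std <- suppressWarnings(standardize_spatial(qc_filter(b$trials, meta = b$meta)))
  chk <- std$values |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(m = mean(.data$ystar), s = sd(.data$ystar))
  expect_lt(max(abs(chk$m)), 1e-8)
  expect_lt(max(abs(chk$s - 1)), 1e-8)
})

test_that("zero-variance environments are dropped with a warning", {
  tr <- tibble::tibble(env_id = rep(c("ok", "flat"), each = 4),
                       hybrid = rep(sprintf("H%d", 1:4), 2),
                       replicate = 1L, block = "B1",
                       yield_mg_ha = c(rnorm(4), rep(7, 4)))
  expect_warning(std <- standardize_spatial(tr), "zero-variance")
  expect_false("flat" %in% std$values$env_id)
})

test_that("environment summaries use the sample SD and handle singletons", {
  tr <- tibble::tibble(env_id = c(rep("E1", 3), "E2"),
                       yield_mg_ha = c(8, 10, 12, 9))
  s <- env_summaries(tr)
  expect_equal(s$env_mean[s$env_id == "E1"], 10)
  expect_equal(s$env_sd[s$env_id == "E1"], 2)
  expect_equal(s$env_mean[s$env_id == "E2"], 9)
  expect_true(is.na(s$env_sd[s$env_id == "E2"]))
})

test_that("environment summary means track the simulated truth", {
  b <- small_bundle()
  s <- env_summaries(suppressWarnings(qc_filter(b$trials, meta = b$meta)))
  tm <- b$truth$env$true_env_mean[match(s$env_id, b$truth$env$env_id)]
  expect_gt(cor(s$env_mean, tm), 0.95)
})
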