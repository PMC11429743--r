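#' Score a prediction set with the competition metrics
#'
#' The headline metric is the **averaged RMSE**: the root-mean-squared error
#' is computed within each environment and those per-environment RMSEs are
#' averaged (each environment counts equally regardless of size).  Also
#' reported: the per-environment and averaged Pearson correlation, and the
#' **global** RMSE / Pearson over all pairs jointly.  Predicted pairs absent
#' from the truth are ignored (counted); environments where the correlation
#' is undefined (fewer than 2 pairs, or zero variance) contribute RMSE but
#' are excluded from the Pearson average and recorded as undefined.
#'
#' @param pred Prediction tibble `env_id`, `hybrid`, `yield_mg_ha`.
#' @param truth Observed values in the same format.
#' @return A `gxe_score`: `per_env` tibble (`env_id`, `n`, `rmse`,
#'   `pearson`), `summary` tibble (`rmse_env_avg`, `pearson_env_avg`,
#'   `rmse_global`, `pearson_global`, `n_pairs`, `n_ignored`).
#' @examples
#' truth <- tibble::tibble(env_id = rep(c("E1", "E2"), each = 3),
#'                         hybrid = rep(paste0("H", 1:3), 2),
#'                         yield_mg_ha = c(8, 9, 10, 11, 12, 13))
#' score_predictions(dplyr::mutate(truth, yield_mg_ha = yield_mg_ha + 1), truth)
#' @export
score_predictions <- function(pred, truth) {
  check_columns(pred, c("env_id", "hybrid", "yield_mg_ha"), "predictions")
  check_columns(truth, c("env_id", "hybrid", "yield_mg_ha"), "truth")
  j <- dplyr::inner_join(
    dplyr::rename(pred, yhat = "yield_mg_ha"),
    dplyr::rename(truth, yobs = "yield_mg_ha"),
    by = c("env_id", "hybrid")
  ) |>
    dplyr::filter(!is.na(.data$yobs), !is.na(.data$yhat))
  n_ignored <- nrow(pred) - nrow(j)
  if (nrow(j) == 0) {
    stop_gxe("no scoreable (env, hybrid) pairs shared between predictions and truth",
             class = "gxe_format_error")
  }
  per_env <- j |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmse = sqrt(mean((.data$yhat - .data$yobs)^2)),
      pearson = if (dplyr::n() >= 2 && sd(.data$yhat) > 0 && sd(.data$yobs) > 0) {
        cor(.data$yhat, .data$yobs)
      } else NA_real_
    ) |>
    dplyr::ungroup()
  pe <- per_env$pearson[!is.na(per_env$pearson)]
  summary <- tibble::tibble(
    rmse_env_avg = mean(per_env$rmse),
    pearson_env_avg = if (length(pe) > 0) mean(pe) else NA_real_,
    rmse_global = sqrt(mean((j$yhat - j$yobs)^2)),
    pearson_global = if (nrow(j) >= 2 && sd(j$yhat) > 0 && sd(j$yobs) > 0) {
      cor(j$yhat, j$yobs)
    } else NA_real_,
    n_pairs = nrow(j), n_ignored = n_ignored,
    n_env_pearson_undefined = sum(is.na(per_env$pearson))
  )
  structure(list(per_env = per_env, summary = summary), class = "gxe_score")
}

#' @export
print.gxe_score <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gxe_score> %d pairs in %d environments (%d ignored)\n",
              s$n_pairs, nrow(x$per_env), s$n_ignored))
  cat(sprintf("  averaged RMSE %.3f | averaged r %s | global RMSE %.3f | global r %s\n",
              s$rmse_env_avg,
              ifelse(is.na(s$pearson_env_avg), "undef", sprintf("%.3f", s$pearson_env_avg)),
              s$rmse_global,
              ifelse(is.na(s$pearson_global), "undef", sprintf("%.3f", s$pearson_global))))
  invisible(x)
}

#' @export
tidy.gxe_score <- function(x, ...) x$per_env

#' @export
glance.gxe_score <- function(x, ...) x$summary

#' Per-environment RMSE bar chart of a score report
#'
#' @param object A `gxe_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gxe_score <- function(object, ...) {
  ggplot2::ggplot(object$per_env,
                  ggplot2::aes(stats::reorder(.data$env_id, .data$rmse),
                               .data$rmse)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$summary$rmse_env_avg, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "within-environment RMSE (Mg/ha)") +
    ggplot2::theme_minimal()
}

#' Build a leaderboard from several submissions
#'
#' Scores every submission against the truth, ranks each metric (lower RMSE
#' better, higher Pearson better) with dense ranks and ties broken by team
#' label (documented, deterministic), and flags rank differences between the
#' headline averaged-RMSE ranking and each alternative metric.  Undefined
#' Pearson scores are excluded from that metric's ranking.
#'
#' @param submissions Named list of prediction tibbles.
#' @param truth Observed values tibble.
#' @return A `gxe_leaderboard` tibble: `team`, four score columns, four rank
#'   columns, `tied`, and `rank_differs_*` flags.
#' @export
build_leaderboard <- function(submissions, truth) {
  stopifnot(is.list(submissions), length(submissions) >= 1,
            !is.null(names(submissions)))
  scores <- purrr::imap_dfr(submissions, function(p, team) {
    dplyr::mutate(score_predictions(p, truth)$summary, team = team,
                  .before = 1)
  }) |>
    dplyr::select("team", "rmse_env_avg", "pearson_env_avg",
                  "rmse_global", "pearson_global")
  rank_metric <- function(x, lower_better) {
    o <- if (lower_better) x else -x
    r <- rep(NA_integer_, length(o))
    ok <- !is.na(o)
    # ties broken by team label: order by (score, team), sequential ranks
    ord <- order(o[ok], scores$team[ok])
    r[which(ok)[ord]] <- seq_len(sum(ok))
    r
  }
  lb <- scores |>
    dplyr::mutate(
      rmse_env_avg_rank = rank_metric(.data$rmse_env_avg, TRUE),
      pearson_env_avg_rank = rank_metric(.data$pearson_env_avg, FALSE),
      rmse_global_rank = rank_metric(.data$rmse_global, TRUE),
      pearson_global_rank = rank_metric(.data$pearson_global, FALSE),
      tied = duplicated(.data$rmse_env_avg) |
        duplicated(.data$rmse_env_avg, fromLast = TRUE),
      rank_differs_pearson_env = .data$pearson_env_avg_rank != .data$rmse_env_avg_rank,
      rank_differs_rmse_global = .data$rmse_global_rank != .data$rmse_env_avg_rank,
      rank_differs_pearson_global = .data$pearson_global_rank != .data$rmse_env_avg_rank
    ) |>
    dplyr::arrange(.data$rmse_env_avg_rank)
  class(lb) <- c("gxe_leaderboard", class(lb))
  lb
}

#' Spread of the top-n averaged-RMSE scores
#'
#' The difference between the n-th best and the best averaged RMSE — how
#' tightly packed the top of the leaderboard is (Mg/ha).
#'
#' @param lb A `gxe_leaderboard` or any tibble with the score column.
#' @param n Number of top teams (>= 1).
#' @param score_col Score column name (default `"rmse_env_avg"`).
#' @return A single number (Mg/ha).
#' @examples
#' top_n_spread(g2f_table("table2"), 10)
#' @export
top_n_spread <- function(lb, n, score_col = "rmse_env_avg") {
  check_columns(lb, score_col, "leaderboard")
  s <- sort(lb[[score_col]])
  if (n < 1 || n > length(s)) {
    stop_gxe(sprintf("`n` must be between 1 and the number of teams (%d)",
                     length(s)), "gxe_format_error")
  }
  s[n] - s[1]
}

#' Percentage of teams using each strategy or data factor
#'
#' `100 * (count of TRUE flags) / (row count)` per logical column, rounded to
#' the nearest integer percent with ties rounded up — the convention that
#' reproduces the printed footers of the competition's strategy and factor
#' survey tables.
#'
#' @param t Tibble with one row per team and logical flag columns.
#' @return Named numeric vector of integer percentages, one per flag column.
#' @examples
#' usage_percentages(g2f_table("table4"))
#' @export
usage_percentages <- function(t) {
  stopifnot(nrow(t) >= 1)
  flags <- t[, vapply(t, is.logical, logical(1)), drop = FALSE]
  vapply(flags, function(col) floor(100 * mean(col) + 0.5), numeric(1))
}

#' Spearman correlation between final ranks and submission counts
#'
#' Spearman's rho with average ranks for ties and a two-sided p-value from
#' the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param ranks Final team ranks.
#' @param submission_counts Number of submissions per team.
#' @return Tibble `rho`, `p_value`, `n`.
#' @export
rank_submission_correlation <- function(ranks, submission_counts) {
  if (length(ranks) != length(submission_counts)) {
    stop_gxe("`ranks` and `submission_counts` must have equal length",
             "gxe_format_error")
  }
  n <- length(ranks)
  if (n < 4) stop_gxe("need at least 4 teams", "gxe_format_error")
  if (sd(ranks) == 0 || sd(submission_counts) == 0) {
    stop_gxe("Spearman correlation undefined for a constant vector",
             "gxe_numeric_error")
  }
  rho <- cor(rank(ranks), rank(submission_counts))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  tibble::tibble(rho = rho, p_value = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Transcribed competition summary tables
#'
#' Plain-CSV transcriptions of three summary tables released with the 2022
#' Genomes-to-Fields maize yield prediction competition, shipped so the
#' package's summary statistics can be recomputed from them:
#' `"table2"` — the top-20 leaderboard (averaged and global RMSE / Pearson r
#' with published ranks; one averaged-Pearson entry is `NaN` in the source
#' and is preserved as such); `"table3"` — modeling strategies used by the
#' 27 survey-respondent teams; `"table4"` — data factors included by team.
#'
#' @param which `"table2"`, `"table3"` or `"table4"`.
#' @return A tibble.
#' @examples
#' g2f_table("table3")
#' @export
g2f_table <- function(which = c("table2", "table3", "table4")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".csv"), package = "gxeyield",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, na = "NA")
}
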