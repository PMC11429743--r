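#' Quality-control filter for plot-level trial records
#'
#' Applies the three field-trial QC rules in one pass, each record removed
#' under the first rule that catches it:
#'
#' 1. **disease** — every record of an environment whose treatment string
#'    contains "disease" (case-insensitive) is dropped (when `drop_disease`);
#' 2. **stand** — records with `stand_count < min_stand` are dropped;
#' 3. **sd** — records farther than `sd_threshold` within-environment standard
#'    deviations from the environment mean are dropped, with mean and SD
#'    computed once from the environment's records *before any removal* (the
#'    rule is not iterated).
#'
#' Missing yields are dropped up front and reported separately.  Environments
#' with fewer than 3 records skip the SD rule with a warning.
#'
#' @param trials Plot-level tibble with at least `env_id`, `yield_mg_ha`,
#'   `stand_count`, `treatment` joined in or absent (when absent the disease
#'   rule needs `meta`).
#' @param sd_threshold Outlier rule width in SD units (default 3).
#' @param min_stand Minimum plants per plot (default 20).
#' @param drop_disease Drop disease-trial environments? Default `TRUE`.
#' @param meta Optional environment metadata supplying `treatment` per
#'   `env_id` when `trials` has no treatment column.
#' @return The filtered tibble, with attributes `removed` (named counts per
#'   rule) and `removed_by_env` (tibble of per-environment counts per rule).
#'   Retrieve them with [qc_removals()].
#' @examples
#' tr <- tibble::tibble(env_id = "E1", yield_mg_ha = c(8, 9, 10, 11, 50),
#'                      stand_count = c(75, 75, 12, 75, 75))
#' qc_removals(qc_filter(tr))
#' @export
qc_filter <- function(trials, sd_threshold = 3, min_stand = 20,
                      drop_disease = TRUE, meta = NULL) {
  check_columns(trials, c("env_id", "yield_mg_ha"), "trials")
  n0 <- nrow(trials)
  if (n0 == 0) {
    out <- trials
    attr(out, "removed") <- c(missing = 0L, disease = 0L, stand = 0L, sd = 0L)
    attr(out, "removed_by_env") <- tibble::tibble(
      env_id = character(), missing = integer(), disease = integer(),
      stand = integer(), sd = integer())
    return(out)
  }
  treatment <- trials[["treatment"]]
  if (is.null(treatment) && !is.null(meta)) {
    check_columns(meta, c("env_id", "treatment"), "meta")
    treatment <- meta$treatment[match(trials$env_id, meta$env_id)]
  }
  if (is.null(treatment)) treatment <- rep("", n0)

  is_missing <- is.na(trials$yield_mg_ha)
  is_disease <- drop_disease & grepl("disease", treatment, ignore.case = TRUE)

  stand <- trials[["stand_count"]] %||% rep(NA_integer_, n0)
  is_stand <- !is.na(stand) & stand < min_stand

  # SD rule: per-environment mean/SD from all non-missing records, pre-removal.
  st <- trials |>
    dplyr::filter(!is.na(.data$yield_mg_ha)) |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(.m = mean(.data$yield_mg_ha),
                     .s = sd(.data$yield_mg_ha), .n = dplyr::n())
  small <- st$env_id[st$.n < 3]
  if (length(small) > 0) {
    warn_gxe(sprintf(
      "SD rule skipped for environment(s) with < 3 records: %s",
      paste(small, collapse = ", ")))
  }
  idx <- match(trials$env_id, st$env_id)
  dev <- abs(trials$yield_mg_ha - st$.m[idx])
  is_sd <- !is_missing & st$.n[idx] >= 3 & !is.na(st$.s[idx]) & st$.s[idx] > 0 &
    dev > sd_threshold * st$.s[idx]
  is_sd[is.na(is_sd)] <- FALSE

  # precedence: missing > disease > stand > sd — each record counted once
  rule <- dplyr::case_when(
    is_missing ~ "missing",
    is_disease ~ "disease",
    is_stand ~ "stand",
    is_sd ~ "sd",
    .default = "keep"
  )
  out <- trials[rule == "keep", , drop = FALSE]
  counts <- vapply(c("missing", "disease", "stand", "sd"),
                   function(r) sum(rule == r), integer(1))
  by_env <- tibble::tibble(env_id = trials$env_id, rule = rule) |>
    dplyr::filter(.data$rule != "keep") |>
    dplyr::count(.data$env_id, .data$rule) |>
    tidyr::pivot_wider(names_from = "rule", values_from = "n", values_fill = 0L)
  attr(out, "removed") <- counts
  attr(out, "removed_by_env") <- by_env
  out
}

#' Removal counts recorded by [qc_filter()]
#'
#' @param filtered The tibble returned by [qc_filter()].
#' @return Named integer vector with counts for `missing`, `disease`, `stand`
#'   and `sd` removals.
#' @export
qc_removals <- function(filtered) attr(filtered, "removed")

#' Write the per-environment QC report as JSON
#'
#' @param filtered Result of [qc_filter()].
#' @param path Output path (`qc_report.json` convention).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(filtered, path) {
  rep <- list(total_removed = as.list(qc_removals(filtered)),
              by_environment = attr(filtered, "removed_by_env"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Aggregate messy environment metadata into modeling classes
#'
#' Previous crops collapse to four levels — wheat, legume, corn, other — and
#' treatments to three — standard, dry, late — through a documented keyword
#' table; irrigation is pulled out of the treatment string into its own
#' boolean (combined with an explicit `irrigated` column when present).
#' Unmatched strings fall through to `other` / `standard`.
#'
#' Keyword table (case-insensitive substring match, first hit wins):
#' * previous crop: "soy"/"bean"/"pea"/"legume"/"alfalfa"/"clover" -> legume;
#'   "maize"/"corn" -> corn; "wheat" -> wheat; anything else -> other
#' * treatment: "dry"/"drought" -> dry; "late" -> late; else -> standard
#' * irrigation: "irrig" in treatment (without a "non"/"not" prefix) -> TRUE
#'
#' @param meta_raw Tibble with `env_id`, `treatment`, `previous_crop` and
#'   optionally `irrigated`, `state`, `station`, coordinates.
#' @return Tibble with `treatment_class`, `previous_crop_class`, `irrigated`
#'   plus the pass-through identification columns.
#' @examples
#' aggregate_metadata(tibble::tibble(env_id = "E1", treatment = "Dryland",
#'                                   previous_crop = "Soybean"))
#' @export
aggregate_metadata <- function(meta_raw) {
  check_columns(meta_raw, c("env_id", "treatment", "previous_crop"), "metadata")
  treat <- tolower(meta_raw$treatment %||% "")
  crop <- tolower(meta_raw$previous_crop %||% "")
  treat[is.na(treat)] <- ""
  crop[is.na(crop)] <- ""
  crop_class <- dplyr::case_when(
    grepl("soy|bean|pea|legume|alfalfa|clover", crop) ~ "legume",
    grepl("maize|corn", crop) ~ "corn",
    grepl("wheat", crop) ~ "wheat",
    .default = "other"
  )
  treat_class <- dplyr::case_when(
    grepl("dry|drought", treat) ~ "dry",
    grepl("late", treat) ~ "late",
    .default = "standard"
  )
  irr_from_treat <- grepl("irrig", treat) & !grepl("non[- ]?irrig|not irrig", treat)
  irrigated <- meta_raw[["irrigated"]] %||% FALSE
  irrigated <- as.logical(irrigated) | irr_from_treat
  keep <- intersect(c("env_id", "state", "station", "latitude", "longitude"),
                    names(meta_raw))
  dplyr::bind_cols(
    meta_raw[, keep, drop = FALSE],
    tibble::tibble(irrigated = irrigated, treatment_class = treat_class,
                   previous_crop_class = crop_class)
  )
}

#' Standardize phenotypes within environment after block adjustment
#'
#' Two stages, applied per environment to QC-filtered records:
#'
#' 1. **block adjustment** — least-squares block (replicate) means are
#'    subtracted, removing additive block effects (the only design columns
#'    guaranteed in the bundle; row-column or spline field-trend adjustment
#'    is a documented extension point);
#' 2. **standardization** — the block-adjusted residuals are centered and
#'    scaled to mean 0, SD 1 within the environment.
#'
#' Environments with zero variance or all-missing yields are dropped with a
#' warning.  The per-environment means and SDs used for the transform are
#' kept so predictions can be mapped back to Mg/ha.
#'
#' @param trials QC-filtered plot tibble with `env_id`, `hybrid`,
#'   `yield_mg_ha` and optionally `block` (or `replicate`).
#' @return A list of class `gxe_std_pheno`: `values` (tibble `env_id`,
#'   `hybrid`, `replicate`, `ystar`) and `scale` (tibble `env_id`, `center`,
#'   `scale` of the post-adjustment transform).
#' @export
standardize_spatial <- function(trials) {
  check_columns(trials, c("env_id", "hybrid", "yield_mg_ha"), "trials")
  blk <- trials[["block"]] %||% as.character(trials[["replicate"]] %||% "1")
  df <- tibble::tibble(env_id = trials$env_id, hybrid = trials$hybrid,
                       replicate = trials[["replicate"]] %||% 1L,
                       block = as.character(blk), y = trials$yield_mg_ha) |>
    dplyr::filter(!is.na(.data$y))
  dropped <- setdiff(unique(trials$env_id), unique(df$env_id))
  out <- df |>
    dplyr::group_by(.data$env_id) |>
    dplyr::group_modify(function(d, key) {
      # stage 1: subtract least-squares block means, restore the env mean
      bm <- tapply(d$y, d$block, mean)
      adj <- d$y - as.numeric(bm[d$block]) + mean(d$y)
      s <- sd(adj)
      if (is.na(s) || s < 1e-12) {
        return(dplyr::mutate(d, ystar = NA_real_, .center = NA_real_,
                             .scale = NA_real_))
      }
      dplyr::mutate(d, ystar = (adj - mean(adj)) / s, .center = mean(adj),
                    .scale = s)
    }) |>
    dplyr::ungroup()
  degenerate <- unique(out$env_id[is.na(out$ystar)])
  if (length(c(dropped, degenerate)) > 0) {
    warn_gxe(sprintf("dropped zero-variance or empty environment(s): %s",
                     paste(unique(c(dropped, degenerate)), collapse = ", ")))
    out <- dplyr::filter(out, !is.na(.data$ystar))
  }
  scale_tbl <- out |>
    dplyr::distinct(.data$env_id, center = .data$.center, scale = .data$.scale)
  structure(list(
    values = dplyr::select(out, "env_id", "hybrid", "replicate", "ystar"),
    scale = scale_tbl
  ), class = "gxe_std_pheno")
}

#' @export
print.gxe_std_pheno <- function(x, ...) {
  cat(sprintf("<gxe_std_pheno> %d records, %d environments\n",
              nrow(x$values), nrow(x$scale)))
  invisible(x)
}

#' Per-environment mean and standard deviation of plot yields
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of `yield_mg_ha` per
#' environment; the SD is reported missing for single-record environments.
#'
#' @param trials QC-filtered plot tibble.
#' @return Tibble `env_id`, `env_mean`, `env_sd`, `n_plots` (Mg/ha).
#' @examples
#' env_summaries(tibble::tibble(env_id = "E1", yield_mg_ha = c(8, 10, 12)))
#' @export
env_summaries <- function(trials) {
  check_columns(trials, c("env_id", "yield_mg_ha"), "trials")
  trials |>
    dplyr::filter(!is.na(.data$yield_mg_ha)) |>
    dplyr::group_by(.data$env_id) |>
    dplyr::summarise(env_mean = mean(.data$yield_mg_ha),
                     env_sd = sd(.data$yield_mg_ha),
                     n_plots = dplyr::n()) |>
    dplyr::ungroup()
}
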