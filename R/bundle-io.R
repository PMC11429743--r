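#' Write / read a competition-shaped data bundle as CSV files
#'
#' The bundle mirrors the file roster of the Genomes-to-Fields prediction
#' competition as plain UTF-8 CSV with a header row:
#'
#' * `trait.csv` — plot-level records: `env_id, year, location_code, hybrid,
#'   yield_mg_ha, stand_count, replicate, block, discarded_flag`
#' * `meta.csv` — environment metadata: `env_id, state, station, latitude,
#'   longitude, irrigated, treatment, previous_crop`
#' * `ec.csv` — `env_id` plus numeric environmental covariate columns
#' * `geno.csv` — `hybrid` plus one dosage (0/1/2) column per variant
#' * `template.csv` — submission template: `env_id, hybrid, yield_mg_ha`
#'   (empty yield column), one row per requested pair
#'
#' `read_bundle(write_bundle(x))` restores every table field-for-field.
#' Ground truth from the simulator is not part of the file roster (the real
#' competition never shipped it); keep the in-memory `gxe_bundle` if truth is
#' needed downstream.
#'
#' @param bundle A `gxe_bundle` (or a plain list with elements `trials`,
#'   `meta`, `ec`, `markers`, `template`).
#' @param dir Directory to write to (created if missing).
#' @return `write_bundle()` returns `dir` invisibly; `read_bundle()` a
#'   `gxe_bundle` (without truth).
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(bundle$trials, file.path(dir, "trait.csv"))
  readr::write_csv(bundle$meta, file.path(dir, "meta.csv"))
  readr::write_csv(bundle$ec, file.path(dir, "ec.csv"))
  geno <- tibble::as_tibble(bundle$markers$dosage, rownames = "hybrid")
  readr::write_csv(geno, file.path(dir, "geno.csv"))
  readr::write_csv(bundle$template, file.path(dir, "template.csv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("trait.csv", "meta.csv", "ec.csv", "geno.csv", "template.csv")) {
    if (!file.exists(p(f))) {
      stop_gxe(sprintf("bundle file `%s` not found in %s", f, dir),
               "gxe_format_error")
    }
  }
  trials <- readr::read_csv(p("trait.csv"), show_col_types = FALSE,
                            col_types = readr::cols(
                              replicate = readr::col_integer(),
                              stand_count = readr::col_integer(),
                              year = readr::col_integer()
                            ))
  check_columns(trials, c("env_id", "year", "location_code", "hybrid",
                          "yield_mg_ha", "stand_count", "replicate", "block",
                          "discarded_flag"), "trait.csv")
  meta <- readr::read_csv(p("meta.csv"), show_col_types = FALSE)
  check_columns(meta, c("env_id", "state", "station", "latitude", "longitude",
                        "irrigated", "treatment", "previous_crop"), "meta.csv")
  ec <- readr::read_csv(p("ec.csv"), show_col_types = FALSE)
  check_columns(ec, "env_id", "ec.csv")
  geno <- readr::read_csv(p("geno.csv"), show_col_types = FALSE)
  check_columns(geno, "hybrid", "geno.csv")
  dosage <- as.matrix(geno[, -1])
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- geno$hybrid
  template <- readr::read_csv(p("template.csv"), show_col_types = FALSE,
                              col_types = readr::cols(
                                yield_mg_ha = readr::col_double()
                              ))
  check_columns(template, c("env_id", "hybrid", "yield_mg_ha"), "template.csv")
  structure(list(trials = trials, meta = meta, ec = ec,
                 markers = new_marker_matrix(dosage), template = template),
            class = "gxe_bundle")
}

#' Import hybrid dosages from a VCF file
#'
#' Maps diploid GT fields to 0/1/2 alternate-allele dosages.  Multiallelic
#' records and records with missing genotypes are rejected: the modeling code
#' assumes a complete dosage matrix (impute upstream).
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return A `gxe_marker_matrix` with samples as hybrids.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_gxe("package `vcfR` is required for VCF import", "gxe_format_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) {
    stop_gxe("multiallelic VCF records are not supported", "gxe_format_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  if (anyNA(dos)) {
    stop_gxe("VCF contains missing genotypes; impute before import",
             "gxe_format_error")
  }
  dos <- t(dos)  # samples (hybrids) in rows
  new_marker_matrix(dos)
}
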