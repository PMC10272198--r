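#' Read a wide-format spectral CSV
#'
#' The on-disk dialect is a UTF-8 comma-separated file with header
#' `sample_id,replicate_id,class_label,<wn1>,<wn2>,...` where the remaining
#' header fields are numeric wavenumbers in cm^-1, and one spectrum per row.
#' An ascending grid is accepted and reordered to the canonical descending
#' order on read; round-trips with [write_spectra()] are bit-identical for
#' finite values.
#'
#' @param path Path to a CSV file.
#' @return A spectral tibble (see [spectra_grid()] for the layout).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  # absorbances come in as text and through base R's strtod: unlike the
  # vroom fast-float path it rounds correctly, so 17-digit output from
  # write_spectra() parses back bit-identically
  ds <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  prob <- readr::problems(ds)
  if (nrow(prob)) {
    abort(sprintf("parse error at row %d, column %d of %s",
                  prob$row[1], prob$col[1], path))
  }
  for (col in setdiff(names(ds), .meta_cols)) {
    v <- suppressWarnings(as.numeric(ds[[col]]))
    if (anyNA(v) && !all(is.na(v) == is.na(ds[[col]]))) {
      bad <- which(is.na(v) & !is.na(ds[[col]]))[1]
      abort(sprintf("parse error at data row %d, column '%s' of %s",
                    bad, col, path))
    }
    ds[[col]] <- v
  }
  attr(ds, "spec") <- NULL
  attr(ds, "problems") <- NULL
  class(ds) <- c("tbl_df", "tbl", "data.frame")
  .check_spectra(ds)
  ds <- .canonical_order(ds)
  .warn_unbalanced(ds)
  ds
}

#' Write a spectral tibble to wide CSV
#'
#' Absorbances are written with 17 significant digits, enough for any double
#' to parse back bit-identically, so [read_spectra()] recovers the dataset
#' exactly. A dataset with zero rows produces a header-only file.
#'
#' @param ds A spectral tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  .check_spectra(ds)
  out <- ds
  for (col in setdiff(names(out), .meta_cols)) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Validation warning (not an error): ragged replicate counts are legal but
# usually indicate an upstream bookkeeping problem.
.warn_unbalanced <- function(ds) {
  if (!nrow(ds)) return(invisible(ds))
  counts <- table(ds$sample_id)
  if (length(unique(as.integer(counts))) > 1L) {
    warn("samples have unequal replicate counts")
  }
  invisible(ds)
}

#' Write a simulated cohort with its reproducibility sidecar
#'
#' Writes the spectra via [write_spectra()] plus a JSON sidecar
#' (`<path>.json`) recording the generator configuration and seed, which is
#' enough to regenerate the cohort bit-identically.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_spectra(cohort$spectra, path)
  cfg <- cohort$config
  sidecar <- list(
    generator = "serafir::simulate_cohort",
    seed = cohort$seed,
    config = list(
      n_control = cfg$n_control, n_case = cfg$n_case,
      n_replicates = cfg$n_replicates,
      wn_start = cfg$wn_start, wn_end = cfg$wn_end, wn_step = cfg$wn_step,
      base_bands = as.data.frame(cfg$base_bands),
      effect_bands = as.data.frame(cfg$effect_bands),
      baseline_coeffs_sd = cfg$baseline_coeffs_sd,
      noise_sd = cfg$noise_sd
    )
  )
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("writing the sidecar requires the jsonlite package")
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
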