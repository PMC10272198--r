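#' Gaussian absorption band
#'
#' Band shape used by the synthetic-cohort generator:
#' `amplitude * exp(-(grid - center)^2 / (2 * width^2))`. Real mid-infrared
#' bands are closer to Voigt profiles, but a Gaussian is the simplest shape
#' with effectively local support and is sufficient for planting known
#' structure in simulated spectra.
#'
#' @param grid Numeric wavenumber vector (cm^-1).
#' @param center Band center (cm^-1).
#' @param width Gaussian standard deviation (cm^-1); must be positive.
#' @param amplitude Peak absorbance (a.u.).
#' @return Numeric absorbance vector, same length as `grid`.
#' @examples
#' gaussian_band(seq(1800, 900, by = -2), center = 1650, width = 25,
#'               amplitude = 0.5)
#' @export
gaussian_band <- function(grid, center, width, amplitude) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    abort("`width` must be a single positive number")
  }
  amplitude * exp(-(grid - center)^2 / (2 * width^2))
}

#' Synthetic serum cohort configuration
#'
#' Bundles every knob of the two-class synthetic ATR-FTIR cohort generator.
#' The defaults describe the cohort the package's own validation studies use:
#' 32 control and 30 case samples measured in triplicate on a 1800 -> 900
#' cm^-1 grid at 2 cm^-1 spacing (the biofingerprint region; a full
#' 4000 -> 600 acquisition grid is available by changing `wn_start`/`wn_end`),
#' a serum-like set of base absorption bands, and nine case-specific
#' amplitude shifts at 1711, 1661, 1574, 1510, 1398, 1273, 1225, 1107 and
#' 906.5 cm^-1. Case-minus-control signs follow the direction of the class
#' differences reported for those bands in serum studies of musculoskeletal
#' disease: protein/nucleic-acid bands (1661, 1574, 1510, 1107) lower in
#' cases, lipid/phosphate bands (1398, 1273, 1225, 906.5) higher.
#'
#' Band tables are tibbles with columns `center`, `width`, `amplitude`
#' (all a.u. / cm^-1). Baseline drift is a random polynomial of order
#' `length(baseline_coeffs_sd) - 1` (at most 3) on the scaled coordinate
#' t in [-1, 1], drawn once per sample and shared across that sample's
#' replicates; Gaussian noise of sd `noise_sd` is drawn per replicate point.
#'
#' @param n_control,n_case Samples per class (each >= 2).
#' @param n_replicates Replicate spectra per sample (>= 1).
#' @param wn_start,wn_end,wn_step Grid limits and spacing (cm^-1);
#'   `wn_start > wn_end > 0`, `wn_step > 0`; the grid is stored descending.
#' @param base_bands Tibble of class-shared bands.
#' @param effect_bands Tibble of case-only amplitude deltas (may have zero
#'   rows for a null cohort).
#' @param baseline_coeffs_sd Per-order standard deviations of the random
#'   polynomial baseline coefficients (length <= 4, i.e. order <= 3).
#' @param noise_sd Per-point replicate noise sd (a.u., >= 0).
#' @param seed Default integer seed used by [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_control = 32L,
                          n_case = 30L,
                          n_replicates = 3L,
                          wn_start = 1800,
                          wn_end = 900,
                          wn_step = 2,
                          base_bands = serum_base_bands(),
                          effect_bands = osteo_effect_bands(),
                          baseline_coeffs_sd = c(0.02, 0.01, 0.004, 0.002),
                          noise_sd = 0.003,
                          seed = 1L) {
  cfg <- list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    n_replicates = as.integer(n_replicates),
    wn_start = wn_start, wn_end = wn_end, wn_step = wn_step,
    base_bands = tibble::as_tibble(base_bands),
    effect_bands = tibble::as_tibble(effect_bands),
    baseline_coeffs_sd = baseline_coeffs_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_control < 2L || cfg$n_case < 2L) {
    abort("need at least 2 samples per class")
  }
  if (cfg$n_replicates < 1L) abort("`n_replicates` must be >= 1")
  if (!(cfg$wn_start > cfg$wn_end && cfg$wn_end > 0)) {
    abort("require wn_start > wn_end > 0")
  }
  if (cfg$wn_step <= 0) abort("`wn_step` must be positive")
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (length(cfg$baseline_coeffs_sd) > 4L) {
    abort("baseline polynomial order is capped at 3 (4 coefficients)")
  }
  for (tab in list(cfg$base_bands, cfg$effect_bands)) {
    if (nrow(tab)) {
      stopifnot(all(c("center", "width", "amplitude") %in% names(tab)))
      if (any(tab$width <= 0)) abort("all band widths must be positive")
      if (any(tab$center > cfg$wn_start | tab$center < cfg$wn_end)) {
        abort("all band centers must lie inside [wn_end, wn_start]")
      }
    }
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  samples: %d control + %d case, %d replicate(s) each\n",
              x$n_control, x$n_case, x$n_replicates))
  cat(sprintf("  grid: %g -> %g cm^-1, step %g (%d points)\n",
              x$wn_start, x$wn_end, x$wn_step,
              length(seq(x$wn_start, x$wn_end, by = -x$wn_step))))
  cat(sprintf("  bands: %d base, %d effect; noise_sd = %g a.u.\n",
              nrow(x$base_bands), nrow(x$effect_bands), x$noise_sd))
  invisible(x)
}

#' Serum-like base absorption bands
#'
#' Amide I/II, CH deformation, amide III/phosphate and carbohydrate bands at
#' positions and relative intensities typical of deproteinised blood serum in
#' the biofingerprint region.
#'
#' @return Tibble with columns `center`, `width`, `amplitude`.
#' @export
serum_base_bands <- function() {
  tibble::tribble(
    ~center, ~width, ~amplitude,
    1652,    28,     0.55,   # amide I
    1545,    24,     0.38,   # amide II
    1454,    14,     0.14,   # CH2 scissoring
    1400,    12,     0.12,   # COO- symmetric stretch
    1310,    18,     0.06,
    1244,    16,     0.10,   # amide III / PO2- asymmetric
    1170,    10,     0.05,
    1080,    22,     0.16,   # PO2- symmetric / carbohydrates
    1030,    12,     0.08,   # glycogen
    935,     10,     0.03
  )
}

#' Default case-effect bands
#'
#' Nine case-minus-control amplitude shifts centred at 1711, 1661, 1574,
#' 1510, 1398, 1273, 1225, 1107 and 906.5 cm^-1. With the default
#' `noise_sd = 0.003`, the smallest |amplitude| is 5x the noise sd.
#'
#' @param scale Multiplier applied to every amplitude delta; `scale = 0`
#'   gives a null (exchangeable-classes) cohort.
#' @return Tibble with columns `center`, `width`, `amplitude`.
#' @export
osteo_effect_bands <- function(scale = 1) {
  b <- tibble::tribble(
    ~center, ~width, ~amplitude,
    1711,    10,      0.020,
    1661,    12,     -0.030,
    1574,     9,     -0.018,
    1510,     9,     -0.020,
    1398,     9,      0.022,
    1273,     8,      0.018,
    1225,    10,      0.025,
    1107,    10,     -0.020,
    906.5,    8,      0.015
  )
  b$amplitude <- b$amplitude * scale
  b
}

#' Simulate a two-class ATR-FTIR cohort
#'
#' Generates one replicate spectrum per row as
#' sum of base bands + (case only) sum of effect bands + a per-sample random
#' polynomial baseline + i.i.d. Gaussian noise per point. The random stream
#' is hierarchical: each sample derives its own seed from `seed` and its
#' sample index, and each replicate from the sample stream, so enlarging the
#' cohort never perturbs the draws of earlier samples. Identical `seed` and
#' config give a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `synthetic_cohort` with elements
#'   `spectra` (the wide spectral tibble, one replicate per row),
#'   `truth` (tibble `sample_id`, `class_label`),
#'   `planted_effect_centers` (numeric, cm^-1), `config`, and `seed`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_control = 3, n_case = 3), seed = 7)
#' dim(cohort$spectra)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- seq(config$wn_start, config$wn_end, by = -config$wn_step)
  tt <- 2 * (grid - config$wn_end) / (config$wn_start - config$wn_end) - 1
  poly_basis <- outer(tt, seq_along(config$baseline_coeffs_sd) - 1, `^`)

  band_sum <- function(tab) {
    if (!nrow(tab)) return(numeric(length(grid)))
    Reduce(`+`, purrr::pmap(tab, function(center, width, amplitude, ...) {
      gaussian_band(grid, center, width, amplitude)
    }))
  }
  base_sig <- band_sum(config$base_bands)
  effect_sig <- band_sum(config$effect_bands)

  n_samples <- config$n_control + config$n_case
  classes <- rep(c("control", "case"), c(config$n_control, config$n_case))
  ids <- sprintf("%s_%02d", ifelse(classes == "control", "ctrl", "case"),
                 c(seq_len(config$n_control), seq_len(config$n_case)))

  rows <- purrr::map(seq_len(n_samples), function(i) {
    s_seed <- child_seed(seed, i)
    set.seed(s_seed)
    coefs <- rnorm(length(config$baseline_coeffs_sd)) * config$baseline_coeffs_sd
    baseline <- drop(poly_basis %*% coefs)
    clean <- base_sig + if (classes[i] == "case") effect_sig else 0
    purrr::map(seq_len(config$n_replicates), function(r) {
      set.seed(child_seed(s_seed, r))
      clean + baseline + rnorm(length(grid), sd = config$noise_sd)
    })
  })
  mat <- do.call(rbind, purrr::flatten(rows))

  meta <- tibble::tibble(
    sample_id = rep(ids, each = config$n_replicates),
    replicate_id = sprintf("r%d", rep(seq_len(config$n_replicates), n_samples)),
    class_label = rep(classes, each = config$n_replicates)
  )
  spectra <- .spectra_tibble(meta, mat, grid)
  structure(
    list(
      spectra = spectra,
      truth = tibble::tibble(sample_id = ids, class_label = classes),
      planted_effect_centers = config$effect_bands$center,
      config = config,
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat(sprintf("  %d spectra (%d samples x %d replicates), %d wavenumbers\n",
              nrow(x$spectra), nrow(x$truth), x$config$n_replicates,
              length(spectra_grid(x$spectra))))
  cat(sprintf("  planted effect centers: %s cm^-1\n",
              paste(x$planted_effect_centers, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' @export
autoplot.synthetic_cohort <- function(object, ...) {
  plot_spectra(object$spectra) +
    ggplot2::ggtitle("Synthetic cohort: class-mean spectra")
}

#' Plot class-mean spectra
#'
#' @param ds A spectral tibble.
#' @return A ggplot: mean absorbance per class against wavenumber, with the
#'   x axis reversed (high wavenumbers left, the FTIR convention).
#' @export
plot_spectra <- function(ds) {
  .check_spectra(ds)
  long <- tidyr::pivot_longer(ds, cols = -dplyr::all_of(.meta_cols),
                              names_to = "wavenumber",
                              values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$class_label, .data$wavenumber),
    absorbance = mean(.data$absorbance), .groups = "drop"
  )
  ggplot2::ggplot(means,
                  ggplot2::aes(.data$wavenumber, .data$absorbance,
                               colour = .data$class_label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)),
                  y = "Absorbance (a.u.)", colour = "Class") +
    ggplot2::theme_minimal()
}
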