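#' Preprocessing configuration
#'
#' Settings for the fixed preprocessing chain applied to every replicate
#' spectrum: Savitzky-Golay smoothing, automatic-weighted least squares
#' (AWLS) baseline correction, truncation to the biofingerprint region,
#' then replicate averaging; mean-centering is fitted separately on the
#' training partition (see [fit_centering()]).
#'
#' @param sg_window Savitzky-Golay window length in points (odd,
#'   `> sg_polyorder`); default 5.
#' @param sg_polyorder Savitzky-Golay polynomial order; default 2.
#' @param awls_order Baseline polynomial order; default 2.
#' @param awls_tol Relative l2 change of the baseline coefficient vector at
#'   which iteration stops; default 1e-6.
#' @param awls_max_iter Iteration cap; default 100.
#' @param awls_weight `"binary"` (points above the fit get weight 0, the
#'   default) or `"soft"` (exponential down-weighting of positive residuals).
#' @param region `c(high, low)` truncation window in cm^-1, inclusive on
#'   both ends; default `c(1800, 900)`, the biofingerprint region.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 5L, sg_polyorder = 2L,
                              awls_order = 2L, awls_tol = 1e-6,
                              awls_max_iter = 100L,
                              awls_weight = c("binary", "soft"),
                              region = c(1800, 900)) {
  awls_weight <- match.arg(awls_weight)
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L) abort("`sg_window` must be odd")
  if (sg_window <= sg_polyorder) abort("`sg_window` must exceed `sg_polyorder`")
  if (awls_max_iter < 1L) abort("`awls_max_iter` must be >= 1")
  if (length(region) != 2L || region[1] <= region[2]) {
    abort("`region` must be c(high, low) with high > low")
  }
  structure(list(sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 awls_order = as.integer(awls_order),
                 awls_tol = awls_tol,
                 awls_max_iter = as.integer(awls_max_iter),
                 awls_weight = awls_weight,
                 region = as.numeric(region)),
            class = "preprocess_config")
}

#' Savitzky-Golay smoothing
#'
#' Replaces each point by the value at that point of the least-squares
#' polynomial of order `sg_polyorder` fitted over the surrounding
#' `sg_window` points. At the edges the polynomial is fitted on the nearest
#' full window and evaluated at the edge offsets, so the output has the same
#' length as the input with no padding. A polynomial of degree
#' `<= sg_polyorder` is reproduced exactly.
#'
#' @param x Numeric absorbance vector (length `>= sg_window`).
#' @param config A [preprocess_config()].
#' @return Smoothed numeric vector, same length as `x`.
#' @export
sg_smooth <- function(x, config = preprocess_config()) {
  if (length(x) < config$sg_window) {
    abort(sprintf("input length %d is shorter than the %d-point window",
                  length(x), config$sg_window))
  }
  as.numeric(signal::sgolayfilt(x, p = config$sg_polyorder,
                                n = config$sg_window))
}

#' Automatic-weighted least squares baseline correction
#'
#' Iteratively reweighted polynomial baseline estimation. An
#' order-`awls_order` polynomial is fitted to the spectrum by least squares
#' (all points weighted 1 initially); points lying above the fit are then
#' screened from pulling the baseline upward and the fit is repeated until
#' the coefficient vector changes by less than `awls_tol` in relative l2
#' norm or `awls_max_iter` is reached. The default `"binary"` screen
#' removes the influence of above-baseline points by clipping their fit
#' target to the current baseline (a damped form of zero-weighting: a raw
#' 0/1 weight scheme lets the surviving point set oscillate, and with it
#' the fit). The `"soft"` variant instead down-weights positive residuals
#' by `exp(-r/s)`, `s` being the mean positive residual. Either way the
#' baseline settles under the absorption peaks while tracking the smooth
#' drift, the screened set only accumulates on clean peak-plus-polynomial
#' input, and a pure polynomial is reproduced exactly (corrected spectrum
#' identically ~0). Non-convergence is reported through the `converged`
#' flag, never as an error.
#'
#' @param x Numeric absorbance vector.
#' @param grid Matching wavenumber vector (used only to scale the polynomial
#'   coordinate; any strictly monotonic vector works).
#' @param config A [preprocess_config()].
#' @return A list: `corrected` (`x - baseline`), `baseline`, `converged`
#'   (logical), `iterations`, and `screened_trace` (list of logical masks of
#'   above-baseline points, one per iteration).
#' @export
awls_baseline <- function(x, grid, config = preprocess_config()) {
  if (length(x) != length(grid)) abort("`x` and `grid` lengths differ")
  n <- length(x)
  tt <- if (diff(range(grid)) > 0) {
    2 * (grid - min(grid)) / diff(range(grid)) - 1
  } else {
    rep(0, n)
  }
  basis <- outer(tt, 0:config$awls_order, `^`)
  # the binary screen refits the same design every iteration: factor once
  ls_op <- if (config$awls_weight == "binary") {
    qr_b <- qr(basis)
    function(target, w) qr.coef(qr_b, target)
  } else {
    function(target, w) stats::lm.wfit(basis, target, w)$coefficients
  }
  target <- x
  w <- rep(1, n)
  coef_old <- rep(Inf, ncol(basis))
  converged <- FALSE
  iter <- 0L
  screened <- vector("list", config$awls_max_iter)
  for (iter in seq_len(config$awls_max_iter)) {
    coefs <- ls_op(target, w)
    coefs <- ifelse(is.na(coefs), 0, coefs)
    baseline <- drop(basis %*% coefs)
    screened[[iter]] <- x > baseline
    denom <- sqrt(sum(coefs^2))
    delta <- sqrt(sum((coefs - coef_old)^2))
    if (is.finite(delta) && delta <= config$awls_tol * max(denom, 1e-300)) {
      converged <- TRUE
      break
    }
    coef_old <- coefs
    if (config$awls_weight == "binary") {
      target <- pmin(x, baseline)
    } else {
      r <- x - baseline
      s <- mean(r[r > 0])
      w <- ifelse(r > 0, exp(-r / max(s, 1e-300)), 1)
    }
  }
  list(corrected = x - baseline, baseline = baseline,
       converged = converged, iterations = iter,
       screened_trace = screened[seq_len(iter)])
}

#' Truncate a spectral tibble to a wavenumber window
#'
#' Keeps the columns with `low <= wavenumber <= high`, inclusive on both
#' ends, preserving the existing column order.
#'
#' @param ds A spectral tibble.
#' @param region `c(high, low)` in cm^-1.
#' @return The truncated spectral tibble.
#' @export
truncate_region <- function(ds, region = c(1800, 900)) {
  .check_spectra(ds)
  wn <- spectra_grid(ds)
  keep <- wn <= max(region) & wn >= min(region)
  if (!any(keep)) {
    abort(sprintf("region (%g, %g) contains no grid points",
                  max(region), min(region)))
  }
  ds[c(.meta_cols, format_wn(wn[keep]))]
}

#' Average replicate spectra per sample
#'
#' Collapses the dataset to one row per `sample_id`, the arithmetic mean of
#' its replicate rows, taken after per-replicate preprocessing so that
#' uncorrelated replicate noise shrinks by `1/n_replicates` in variance.
#' The class label is inherited; replicates of one sample disagreeing on
#' class is an integrity error.
#'
#' @param ds A spectral tibble.
#' @return A spectral tibble with `replicate_id = "mean"` and one row per
#'   sample, in first-appearance order.
#' @export
average_replicates <- function(ds) {
  .check_spectra(ds)
  n_class <- dplyr::summarise(dplyr::group_by(ds, .data$sample_id),
                              k = dplyr::n_distinct(.data$class_label),
                              .groups = "drop")
  if (any(n_class$k > 1L)) {
    abort(paste0("conflicting class labels within sample(s): ",
                 paste(n_class$sample_id[n_class$k > 1L], collapse = ", ")))
  }
  wn_cols <- setdiff(names(ds), .meta_cols)
  out <- dplyr::summarise(
    dplyr::group_by(ds, .data$sample_id),
    class_label = dplyr::first(.data$class_label),
    dplyr::across(dplyr::all_of(wn_cols), mean),
    .groups = "drop"
  )
  out <- out[match(unique(ds$sample_id), out$sample_id), ]
  out <- dplyr::mutate(out, replicate_id = "mean",
                       .after = "sample_id")
  tibble::as_tibble(out)
}

#' Fit / apply training-mean centering
#'
#' `fit_centering()` records the per-wavenumber mean over the training rows;
#' `apply_centering()` subtracts those means from any dataset on the same
#' grid. Fitting on the training partition only (and applying the same means
#' to the test partition) avoids leaking test information into the model.
#'
#' @param train,ds Spectral tibbles on a shared grid.
#' @param model A `centering_model`.
#' @return `fit_centering()`: a `centering_model` (list with `grid` and
#'   `column_means`); `apply_centering()`: the centered spectral tibble.
#' @export
fit_centering <- function(train) {
  .check_spectra(train)
  if (!nrow(train)) abort("cannot fit centering on an empty dataset")
  X <- spectra_matrix(train)
  structure(list(grid = spectra_grid(train), column_means = colMeans(X)),
            class = "centering_model")
}

#' @rdname fit_centering
#' @export
apply_centering <- function(ds, model) {
  stopifnot(inherits(model, "centering_model"))
  .check_spectra(ds)
  if (!isTRUE(all.equal(spectra_grid(ds), model$grid))) {
    abort("dataset grid does not match the centering model's grid")
  }
  X <- sweep(spectra_matrix(ds), 2, model$column_means)
  .spectra_tibble(ds[.meta_cols], X, model$grid)
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: Savitzky-Golay smoothing (per replicate), AWLS
#' baseline correction (per replicate, on the full supplied grid so the
#' baseline fit has the widest support), truncation to `config$region`, and
#' replicate averaging. Centering is deliberately not part of this chain —
#' it must be fitted on the training partition after splitting.
#'
#' @param ds A spectral tibble of replicate spectra.
#' @param config A [preprocess_config()].
#' @return A list of class `preprocessed_spectra`: `spectra` (one averaged
#'   row per sample), `awls_converged` (logical, all replicates converged),
#'   `config`.
#' @export
preprocess_spectra <- function(ds, config = preprocess_config()) {
  .check_spectra(ds)
  grid <- spectra_grid(ds)
  X <- spectra_matrix(ds)
  converged <- TRUE
  for (i in seq_len(nrow(X))) {
    sm <- sg_smooth(X[i, ], config)
    bl <- awls_baseline(sm, grid, config)
    converged <- converged && bl$converged
    X[i, ] <- bl$corrected
  }
  out <- .spectra_tibble(ds[.meta_cols], X, grid)
  out <- truncate_region(out, config$region)
  out <- average_replicates(out)
  structure(list(spectra = out, awls_converged = converged, config = config),
            class = "preprocessed_spectra")
}

#' @export
print.preprocessed_spectra <- function(x, ...) {
  cat("<preprocessed_spectra>\n")
  cat(sprintf("  %d samples x %d wavenumbers (%g -> %g cm^-1)\n",
              nrow(x$spectra), length(spectra_grid(x$spectra)),
              max(x$config$region), min(x$config$region)))
  if (!x$awls_converged) cat("  note: AWLS hit the iteration cap on >= 1 spectrum\n")
  invisible(x)
}
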