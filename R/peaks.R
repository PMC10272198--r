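#' Pick prominent peaks of a loading vector
#'
#' Finds the local maxima of `|loading|` and keeps those whose topographic
#' prominence is at least `min_prominence * max(|loading|)`. Prominence of a
#' peak is its height minus the highest of the two "saddle" minima reached
#' before a higher point (or the series end) on each side — the standard
#' definition, which suppresses ripples riding on larger features. Plateau
#' maxima report their first grid point. A constant vector has no peaks.
#'
#' @param loading Numeric per-wavenumber vector (e.g. a PCA loading).
#' @param grid Matching wavenumber vector (cm^-1).
#' @param min_prominence Fraction of `max(|loading|)` in `(0, 1]`;
#'   default 0.1.
#' @return Tibble with columns `wavenumber`, `height` (`|loading|`),
#'   `prominence`, sorted by descending wavenumber.
#' @export
peak_pick <- function(loading, grid, min_prominence = 0.1) {
  if (length(loading) != length(grid)) {
    abort("`loading` and `grid` lengths differ")
  }
  if (!(min_prominence > 0 && min_prominence <= 1)) {
    abort("`min_prominence` must be in (0, 1]")
  }
  v <- abs(loading)
  n <- length(v)
  if (n < 3L || diff(range(v)) == 0) {
    return(tibble::tibble(wavenumber = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  # local maxima, plateaus collapsed to their first point
  is_peak <- logical(n)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) is_peak[i] <- TRUE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks <- which(is_peak)
  if (!length(peaks)) {
    return(tibble::tibble(wavenumber = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  prominence <- vapply(peaks, function(p) {
    h <- v[p]
    left_min <- h
    for (t in seq(p - 1L, 1L)) {
      if (v[t] > h) break
      left_min <- min(left_min, v[t])
      if (t == 1L) left_min <- min(left_min, v[1L])
    }
    right_min <- h
    for (t in seq(p + 1L, n)) {
      if (v[t] > h) break
      right_min <- min(right_min, v[t])
    }
    h - max(left_min, right_min)
  }, numeric(1))
  keep <- prominence >= min_prominence * max(v)
  out <- tibble::tibble(wavenumber = grid[peaks[keep]],
                        height = v[peaks[keep]],
                        prominence = prominence[keep])
  dplyr::arrange(out, dplyr::desc(.data$wavenumber))
}

#' Match picked peaks to reference positions
#'
#' Counts how many reference wavenumbers have at least one picked peak
#' within `tolerance`. Used to quantify recovery of planted effect-band
#' centers from a loading vector.
#'
#' @param peaks Tibble from [peak_pick()] (or a numeric vector of peak
#'   positions).
#' @param reference Numeric vector of reference wavenumbers (cm^-1).
#' @param tolerance Matching half-window (cm^-1); default 8.
#' @return Tibble with columns `reference`, `matched` (logical),
#'   `nearest_peak`, `offset`.
#' @export
match_peaks <- function(peaks, reference, tolerance = 8) {
  pos <- if (is.data.frame(peaks)) peaks$wavenumber else as.numeric(peaks)
  purrr::map_dfr(reference, function(r) {
    if (!length(pos)) {
      return(tibble::tibble(reference = r, matched = FALSE,
                            nearest_peak = NA_real_, offset = NA_real_))
    }
    d <- abs(pos - r)
    i <- which.min(d)
    tibble::tibble(reference = r, matched = d[i] <= tolerance,
                   nearest_peak = pos[i], offset = pos[i] - r)
  })
}
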