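#' Confusion counts for a two-class prediction
#'
#' Standard 2x2 tally against a declared positive class. In this package
#' the positive class is the disease class (`"case"`), so sensitivity is
#' the case-detection rate, matching clinical usage.
#'
#' @param truth,estimate Vectors of class labels, equal length, each value
#'   in `{control, case}` (or any two labels when `positive` names one of
#'   them).
#' @param positive The positive class; default `"case"`.
#' @return Tibble of class `confusion_counts` with columns `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
confusion_counts <- function(truth, estimate, positive = "case") {
  if (length(truth) != length(estimate) || !length(truth)) {
    abort("`truth` and `estimate` must be non-empty and of equal length")
  }
  labels <- unique(c(truth, estimate))
  allowed <- if (positive == "case") c("control", "case") else labels
  bad <- setdiff(labels, allowed)
  if (length(bad)) {
    abort(paste0("label(s) outside {", paste(allowed, collapse = ", "),
                 "}: ", paste(bad, collapse = ", ")))
  }
  t_pos <- truth == positive
  e_pos <- estimate == positive
  out <- tibble::tibble(
    tp = sum(t_pos & e_pos), tn = sum(!t_pos & !e_pos),
    fp = sum(!t_pos & e_pos), fn = sum(t_pos & !e_pos)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

#' F-score and G-score of a sensitivity/specificity pair
#'
#' `FS = 2 * SENS * SPEC / (SENS + SPEC)` (harmonic mean) and
#' `GS = sqrt(SENS * SPEC)` (geometric mean), on the percentage scale.
#' By the classical mean inequalities `FS <= GS <= (SENS + SPEC)/2`, with
#' equality exactly when `SENS == SPEC`. The degenerate `SENS = SPEC = 0`
#' pair returns `FS = 0`.
#'
#' @param sens,spec Percentages in `[0, 100]`.
#' @return Named numeric vector `c(fs = ..., gs = ...)`, unrounded.
#' @examples
#' fscore_gscore(67, 78)   # c(fs = 72.08..., gs = 72.29...)
#' @export
fscore_gscore <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 100, spec >= 0, spec <= 100)
  fs <- if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
  c(fs = fs, gs = sqrt(sens * spec))
}

#' Figures of merit from confusion counts
#'
#' Computes, on the percentage scale:
#' accuracy `AC = (TP + TN) / n * 100`, sensitivity
#' `SENS = TP / (TP + FN) * 100`, specificity `SPEC = TN / (TN + FP) * 100`,
#' and the F-score / G-score of the unrounded SENS/SPEC pair
#' (see [fscore_gscore()]). Values are reported unrounded; rounding to
#' integer percent for display is the job of [comparison_table()].
#'
#' @param counts A `confusion_counts` tibble (or anything with `tp`, `tn`,
#'   `fp`, `fn`).
#' @return One-row tibble of class `fom`: `tp`, `tn`, `fp`, `fn`, `ac`,
#'   `sens`, `spec`, `fs`, `gs`.
#' @export
figures_of_merit <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + fn == 0) abort("no positive samples evaluated (TP + FN = 0)")
  if (tn + fp == 0) abort("no negative samples evaluated (TN + FP = 0)")
  sens <- tp / (tp + fn) * 100
  spec <- tn / (tn + fp) * 100
  fg <- fscore_gscore(sens, spec)
  out <- tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    ac = (tp + tn) / (tp + tn + fp + fn) * 100,
    sens = sens, spec = spec, fs = unname(fg["fs"]), gs = unname(fg["gs"])
  )
  class(out) <- c("fom", class(out))
  out
}

# Round half away from zero to integer percent (what printed FOM tables use;
# base round() rounds half to even).
round_percent <- function(x) floor(abs(x) + 0.5) * sign(x)

#' Model comparison table
#'
#' Assembles per-model figures of merit into the conventional model-by-merit
#' display grid, with percentages rounded half away from zero to integers,
#' and flags the best model: maximal accuracy, ties broken by maximal
#' G-score (both compared unrounded), then by table order.
#'
#' @param results Named list of `fom` rows (names = model labels, e.g.
#'   `"pca-svm"`).
#' @return Tibble with columns `model`, `ac`, `sens`, `spec`, `fs`, `gs`
#'   (integer percents) and logical `best`.
#' @export
comparison_table <- function(results) {
  if (!length(results)) abort("`results` must contain at least one model")
  if (is.null(names(results))) {
    names(results) <- paste0("model_", seq_along(results))
  }
  raw <- dplyr::bind_rows(results, .id = "model")
  best_i <- order(-raw$ac, -raw$gs, seq_len(nrow(raw)))[1]
  out <- dplyr::transmute(
    raw, model = .data$model,
    ac = round_percent(.data$ac), sens = round_percent(.data$sens),
    spec = round_percent(.data$spec), fs = round_percent(.data$fs),
    gs = round_percent(.data$gs)
  )
  out$best <- seq_len(nrow(out)) == best_i
  out
}
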