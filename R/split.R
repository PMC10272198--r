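#' Kennard-Stone train/test split
#'
#' Deterministic uniform sample selection: the two samples at maximal
#' Euclidean distance seed the training set, then the sample whose minimal
#' distance to the already-selected set is maximal is added (max-min rule)
#' until `round(fraction * n)` samples are selected (rounding half away from
#' zero); the remainder form the test set. All ties are broken by the lowest
#' row index, so the split is a pure function of the data. Duplicate rows
#' are legal.
#'
#' @param x A spectral tibble (the distance is computed on the absorbance
#'   block) or a numeric sample-by-feature matrix.
#' @param fraction Training fraction, strictly between 0 and 1; default 0.7.
#' @return A list of class `ks_split`: `train_indices` and `test_indices`
#'   (row indices; training in selection order), plus `sample_id`s when the
#'   input carries them.
#' @examples
#' kennard_stone(matrix(c(0, 1, 10), ncol = 1), fraction = 2/3)
#' @export
kennard_stone <- function(x, fraction = 0.7) {
  X <- if (is.data.frame(x)) spectra_matrix(x) else as.matrix(x)
  n <- nrow(X)
  if (n < 2L) abort("need at least 2 samples to split")
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must be in (0, 1)")
  n_train <- floor(fraction * n + 0.5)  # round half away from zero (n > 0)
  if (n_train < 2L) abort("training fraction selects fewer than 2 samples")
  if (n_train >= n) abort("training fraction leaves an empty test set")

  D <- as.matrix(stats::dist(X))
  # seed pair: maximal distance, ties -> smallest (i, j)
  upper <- which(upper.tri(D), arr.ind = TRUE)
  dvals <- D[upper]
  best <- upper[which(dvals == max(dvals)), , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  selected <- as.integer(best[1, ])

  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(D[, selected[1]], D[, selected[2]])
  while (length(selected) < n_train) {
    cand <- remaining[min_d[remaining] == max(min_d[remaining])]
    nxt <- min(cand)
    selected <- c(selected, nxt)
    remaining <- setdiff(remaining, nxt)
    min_d <- pmin(min_d, D[, nxt])
  }
  out <- list(train_indices = selected,
              test_indices = setdiff(seq_len(n), selected))
  if (is.data.frame(x) && "sample_id" %in% names(x)) {
    out$train_ids <- x$sample_id[out$train_indices]
    out$test_ids <- x$sample_id[out$test_indices]
  }
  structure(out, class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d train / %d test\n",
              length(x$train_indices), length(x$test_indices)))
  invisible(x)
}

#' @export
tidy.ks_split <- function(x, ...) {
  n <- length(x$train_indices) + length(x$test_indices)
  part <- character(n)
  part[x$train_indices] <- "train"
  part[x$test_indices] <- "test"
  out <- tibble::tibble(index = seq_len(n), partition = part)
  if (!is.null(x$train_ids)) {
    ids <- character(n)
    ids[x$train_indices] <- x$train_ids
    ids[x$test_indices] <- x$test_ids
    out <- dplyr::mutate(out, sample_id = ids, .before = 1)
  }
  out
}

#' Venetian-blinds cross-validation folds
#'
#' Assigns sample `i` (in dataset row order) to fold `((i - 1) mod k) + 1` —
#' the interleaved "venetian blinds" scheme standard in chemometrics. Fold
#' sizes differ by at most one; the assignment is a pure function of
#' `(n, k)`.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of folds (`k >= 2`); default 10.
#' @return Integer vector of fold ids in `1..k`, length `n`.
#' @examples
#' table(venetian_blinds(43, 10))
#' @export
venetian_blinds <- function(n, k = 10L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) abort("`k` must be >= 2")
  if (n < k) abort(sprintf("cannot assign %d samples to %d folds", n, k))
  ((seq_len(n) - 1L) %% k) + 1L
}
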