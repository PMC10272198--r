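#' Radial basis function kernel
#'
#' `K(x, z) = exp(-gamma * ||x - z||^2)`, so `K(x, x) = 1` for any `gamma`.
#'
#' @param X,Z Feature matrices (rows = samples); `Z` defaults to `X`.
#' @param gamma Positive width parameter.
#' @return Kernel matrix, `nrow(X)` x `nrow(Z)`.
#' @export
rbf_kernel <- function(X, Z = X, gamma) {
  if (gamma <= 0) abort("`gamma` must be positive")
  X <- as.matrix(X); Z <- as.matrix(Z)
  d2 <- outer(rowSums(X^2), rowSums(Z^2), `+`) - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a soft-margin RBF support vector machine
#'
#' Solves the standard soft-margin dual
#' maximise `sum(a) - 1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j)` subject to
#' `0 <= a_i <= C`, `sum(a_i y_i) = 0`, by deterministic SMO (maximal
#' violating pair, ties by lowest index) to KKT tolerance `tol`. The bias
#' `b` is the average of `y_i - f(x_i)` over unbounded support vectors
#' (`0 < a_i < C`); when none exist it is the midpoint of the KKT bounds.
#' Support vectors are the samples with `a_i > 1e-8`.
#'
#' @param x Feature matrix.
#' @param y Labels: +/-1, or a factor/character with exactly two levels, in
#'   which case the positive class must be named via `positive`.
#' @param cost Box constraint C (> 0).
#' @param gamma RBF width (> 0).
#' @param positive Class mapped to +1 when `y` is not numeric; default
#'   `"case"`.
#' @param tol KKT tolerance; default 1e-5.
#' @param max_iter SMO iteration cap; non-convergence is an error carrying
#'   the final gap and iteration count.
#' @return An object of class `rbf_svm`: `support_vectors`, `alphas`
#'   (for support vectors), `sv_labels` (+/-1), `b`, `gamma`, `cost`,
#'   `classes` (named map to +/-1), plus solver diagnostics.
#' @export
fit_svm <- function(x, y, cost = 1, gamma = 1, positive = "case",
                    tol = 1e-5, max_iter = 20000000L) {
  X <- as.matrix(x)
  classes <- NULL
  if (!is.numeric(y)) {
    y <- as.character(y)
    lv <- sort(unique(y))
    if (length(lv) != 2L) abort("`y` must have exactly 2 classes")
    if (!positive %in% lv) {
      abort(sprintf("positive class '%s' not present in `y`", positive))
    }
    classes <- stats::setNames(ifelse(lv == positive, 1, -1), lv)
    y <- unname(classes[y])
  }
  if (!all(y %in% c(-1, 1))) abort("numeric `y` must be +/-1")
  if (length(unique(y)) < 2L) abort("both labels must be present")
  if (cost <= 0) abort("`cost` must be positive")

  K <- rbf_kernel(X, gamma = gamma)
  sol <- .smo_solve(K, as.numeric(y), cost, tol, as.integer(max_iter))
  if (!sol$converged) {
    abort(sprintf(
      "SMO did not converge: KKT gap %.3g after %d iterations (tol %.1g)",
      sol$gap, sol$iterations, tol))
  }
  alpha <- sol$alpha
  sv <- which(alpha > 1e-8)
  unbounded <- which(alpha > 1e-8 & alpha < cost - 1e-8)
  b <- if (length(unbounded)) {
    mean(y[unbounded] - sol$f[unbounded])
  } else {
    # midpoint of the KKT interval; with gap < tol any value inside is valid
    mean(range((y - sol$f)[sv]))
  }
  structure(list(
    support_vectors = X[sv, , drop = FALSE],
    alphas = alpha[sv],
    sv_labels = y[sv],
    b = b, gamma = gamma, cost = cost,
    classes = classes,
    n_sv = length(sv),
    kkt_gap = sol$gap,
    iterations = sol$iterations,
    alpha_full = alpha
  ), class = "rbf_svm")
}

#' SVM decision values and predictions
#'
#' `decision_values()` returns `f(z) = sum_i a_i y_i K(x_i, z) + b` over the
#' support vectors; `predict()` returns `sign(f)`, with the tie
#' `f = 0 -> +1` by convention, mapped back to the original class labels
#' when the model was fitted on labelled data.
#'
#' @param model,object An `rbf_svm`.
#' @param x,newdata Feature matrix of points to classify.
#' @param ... Unused.
#' @return `decision_values()`: numeric vector; `predict()`: labels.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "rbf_svm"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != ncol(model$support_vectors)) {
    abort(sprintf("expected %d features, got %d",
                  ncol(model$support_vectors), ncol(X)))
  }
  Kz <- rbf_kernel(X, model$support_vectors, gamma = model$gamma)
  drop(Kz %*% (model$alphas * model$sv_labels)) + model$b
}

#' @rdname decision_values
#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata)
  num <- ifelse(f >= 0, 1, -1)
  if (is.null(object$classes)) return(num)
  names(object$classes)[match(num, object$classes)]
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat(sprintf("<rbf_svm> C = %g, gamma = %g, %d support vector(s), b = %.4g\n",
              x$cost, x$gamma, x$n_sv, x$b))
  invisible(x)
}

#' @export
tidy.rbf_svm <- function(x, ...) {
  tibble::tibble(sv = seq_len(x$n_sv), alpha = x$alphas, label = x$sv_labels)
}

#' @export
glance.rbf_svm <- function(x, ...) {
  tibble::tibble(cost = x$cost, gamma = x$gamma, n_sv = x$n_sv, b = x$b,
                 kkt_gap = x$kkt_gap, iterations = x$iterations)
}

#' Default SVM hyperparameter lattice
#'
#' `C` in `2^-5 .. 2^15` and `gamma` in `2^-15 .. 2^3`, each stepping by a
#' factor of 4 — the usual coarse log-scale grid for RBF SVMs.
#'
#' @return Tibble with columns `cost`, `gamma` (one row per lattice point).
#' @export
svm_default_grid <- function() {
  tidyr::expand_grid(cost = 2^seq(-5, 15, by = 2),
                     gamma = 2^seq(-15, 3, by = 2))
}

#' Tune an RBF SVM over a (C, gamma) lattice by cross-validation
#'
#' For every lattice point, fits the SVM on each training fold complement
#' and measures accuracy on the held-out fold; returns the point maximising
#' mean CV accuracy (ties: smallest `cost`, then smallest `gamma`). A fold
#' whose training complement contains a single class cannot be fitted and
#' is skipped with a warning.
#'
#' @param x Feature matrix.
#' @param y Labels (see [fit_svm()]).
#' @param folds Integer fold ids, e.g. from [venetian_blinds()].
#' @param grid Tibble with columns `cost`, `gamma`; default
#'   [svm_default_grid()].
#' @param positive Positive class name for non-numeric labels.
#' @param tol Dual tolerance for the sweep fits; default 1e-3 (the usual
#'   model-selection tolerance — extreme lattice corners are expensive to
#'   solve tightly and fold accuracies are insensitive to the last digits
#'   of the dual). Refit the winner with [fit_svm()] for a tight solution.
#' @return A list of class `svm_tuning`: `best_cost`, `best_gamma`,
#'   `cv_accuracy` (of the winner), `results` (per-point tibble).
#' @export
tune_svm <- function(x, y, folds, grid = svm_default_grid(),
                     positive = "case", tol = 1e-3) {
  X <- as.matrix(x)
  if (!nrow(grid)) abort("`grid` must be non-empty")
  if (length(folds) != nrow(X)) abort("`folds` length must match rows of `x`")
  fold_ids <- sort(unique(folds))
  acc <- purrr::pmap_dbl(grid, function(cost, gamma) {
    fold_acc <- vapply(fold_ids, function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        warn(sprintf("fold %d leaves a single-class training set; skipped", f))
        return(NA_real_)
      }
      m <- fit_svm(X[tr, , drop = FALSE], y[tr], cost = cost, gamma = gamma,
                   positive = positive, tol = tol)
      mean(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  })
  res <- dplyr::mutate(grid, cv_accuracy = acc)
  ord <- order(-res$cv_accuracy, res$cost, res$gamma)
  best <- res[ord[1], ]
  structure(list(best_cost = best$cost, best_gamma = best$gamma,
                 cv_accuracy = best$cv_accuracy, results = res),
            class = "svm_tuning")
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat(sprintf("<svm_tuning> best C = %g, gamma = %g (CV accuracy %.3f)\n",
              x$best_cost, x$best_gamma, x$cv_accuracy))
  invisible(x)
}
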