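#' Fit a non-Bayesian Mahalanobis discriminant model
#'
#' Linear (LDA) and quadratic (QDA) discriminant classifiers in the
#' distance form used throughout chemometrics: a sample is assigned to the
#' class whose mean is nearest in squared Mahalanobis distance,
#' `L_ik = (x_i - xbar_k)' C_pooled^-1 (x_i - xbar_k)` for LDA and the
#' per-class-covariance analogue `Q_ik = (x_i - xbar_k)' C_k^-1 (x_i - xbar_k)`
#' for QDA. No prior or log-determinant terms enter the scores (this is the
#' non-Bayesian form, which differs from textbook Gaussian-posterior QDA).
#' Covariances use divisor `n_k - 1`; the pooled covariance is
#' `sum_k (n_k - 1) C_k / (n - K)`. Ill-conditioned covariances are ridged
#' (`C + lambda I`, `lambda = 1e-8 tr(C)/p`) and the lambda actually applied
#' is recorded.
#'
#' @param x Feature matrix (samples x features), e.g. PCA scores or
#'   SPA-selected absorbances.
#' @param y Class labels; every class needs >= 2 samples.
#' @param kind `"lda"` (pooled covariance) or `"qda"` (per-class).
#' @return An object of class `mahal_da`.
#' @export
fit_discriminant <- function(x, y, kind = c("lda", "qda")) {
  kind <- match.arg(kind)
  X <- as.matrix(x)
  y <- as.character(y)
  if (nrow(X) != length(y)) abort("`x` and `y` lengths differ")
  classes <- sort(unique(y))
  if (length(classes) < 2L) abort("need >= 2 classes")
  counts <- table(y)
  if (any(counts < 2L)) {
    abort(paste0("class(es) with < 2 samples (covariance undefined): ",
                 paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  p <- ncol(X)
  means <- t(matrix(vapply(classes,
                           function(k) colMeans(X[y == k, , drop = FALSE]),
                           numeric(p)),
                    nrow = p, dimnames = list(NULL, classes)))
  cov_k <- lapply(classes, function(k) stats::cov(X[y == k, , drop = FALSE]))
  names(cov_k) <- classes
  ridge <- 0
  if (kind == "lda") {
    Cp <- Reduce(`+`, purrr::map2(cov_k, as.integer(counts[classes]),
                                  ~ .x * (.y - 1L))) /
      (nrow(X) - length(classes))
    rr <- ridge_covariance(Cp)
    ridge <- rr$lambda
    cov_inv <- list(pooled = solve(rr$C))
    C_pooled <- rr$C
  } else {
    rr <- lapply(cov_k, ridge_covariance)
    ridge <- max(vapply(rr, `[[`, numeric(1), "lambda"))
    cov_inv <- lapply(rr, function(r) solve(r$C))
    cov_k <- lapply(rr, `[[`, "C")
    C_pooled <- NULL
  }
  structure(list(kind = kind, classes = classes, class_means = means,
                 C_pooled = C_pooled, C_k = if (kind == "qda") cov_k,
                 cov_inv = cov_inv, ridge_lambda = ridge, p = p),
            class = "mahal_da")
}

#' Discriminant scores
#'
#' Squared Mahalanobis distance of each sample to each class mean, under
#' the pooled (LDA) or per-class (QDA) covariance. The score at a class's
#' own mean is exactly 0; with an identity covariance it reduces to the
#' squared Euclidean distance.
#'
#' @param model A `mahal_da`.
#' @param x Feature matrix or single feature vector.
#' @return Matrix of scores, rows = samples, columns = classes.
#' @export
discriminant_score <- function(model, x) {
  stopifnot(inherits(model, "mahal_da"))
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != model$p) {
    abort(sprintf("expected %d features, got %d", model$p, ncol(X)))
  }
  out <- matrix(0, nrow(X), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (j in seq_along(model$classes)) {
    k <- model$classes[j]
    Ci <- if (model$kind == "lda") model$cov_inv$pooled else model$cov_inv[[k]]
    d <- sweep(X, 2, model$class_means[j, ])
    out[, j] <- rowSums((d %*% Ci) * d)
  }
  out
}

#' @rdname discriminant_score
#' @param object A `mahal_da`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return `predict()`: character vector of class labels (ties go to the
#'   first class in alphabetical order — deterministic, and in practice a
#'   measure-zero event).
#' @export
predict.mahal_da <- function(object, newdata, ...) {
  sc <- discriminant_score(object, newdata)
  object$classes[apply(sc, 1, which.min)]
}

#' @export
print.mahal_da <- function(x, ...) {
  cat(sprintf("<mahal_da> %s, %d features, classes: %s\n",
              toupper(x$kind), x$p, paste(x$classes, collapse = ", ")))
  if (x$ridge_lambda > 0) {
    cat(sprintf("  ridge lambda = %.3g\n", x$ridge_lambda))
  }
  invisible(x)
}

#' @export
tidy.mahal_da <- function(x, ...) {
  m <- x$class_means
  tibble::tibble(
    class = rep(x$classes, each = ncol(m)),
    feature = rep(seq_len(ncol(m)), length(x$classes)),
    mean = as.vector(t(m))
  )
}

#' @export
glance.mahal_da <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_features = x$p,
                 n_classes = length(x$classes),
                 ridge_lambda = x$ridge_lambda)
}
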