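#' Principal component analysis of a centered spectral matrix
#'
#' Decomposes the centered training matrix as `X = T P' + E` via the
#' singular value decomposition (numerically stabler than an eigendecomposition
#' of the covariance): `P` holds the leading right singular vectors
#' (orthonormal loadings), `T = X P` the scores, and the explained-variance
#' fraction of component j is `sigma_j^2 / sum(sigma_i^2)` over all singular
#' values. The sign of each loading column is fixed so its
#' largest-magnitude element is positive, making the decomposition unique.
#'
#' @param x Centered spectral tibble (training rows) or centered numeric
#'   matrix; column means must be ~0 (center with [apply_centering()]).
#' @param n_components Number of components to retain
#'   (`1 <= n_components <= rank(x)`).
#' @return An object of class `ftir_pca`: `loadings` (p x k), `scores`
#'   (n x k), `explained_variance_fraction`, `n_components`, `training_grid`
#'   (NULL for plain matrices).
#' @seealso [project_scores()], [tidy.ftir_pca()]
#' @export
fit_pca <- function(x, n_components) {
  grid <- NULL
  if (is.data.frame(x)) {
    grid <- spectra_grid(x)
    X <- spectra_matrix(x)
  } else {
    X <- as.matrix(x)
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L) abort("`n_components` must be >= 1")
  sv <- svd(X)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1))
  if (n_components > rank) {
    abort(sprintf("n_components = %d exceeds the achievable rank %d",
                  n_components, rank))
  }
  P <- sv$v[, seq_len(n_components), drop = FALSE]
  flip <- apply(P, 2, function(col) sign(col[which.max(abs(col))]))
  flip[flip == 0] <- 1
  P <- sweep(P, 2, flip, `*`)
  structure(list(
    loadings = P,
    scores = X %*% P,
    explained_variance_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
    singular_values = sv$d,
    n_components = n_components,
    training_grid = grid
  ), class = "ftir_pca")
}

#' Project new centered data onto fitted loadings
#'
#' Returns `X_new P`. Projecting the training matrix reproduces the stored
#' scores. New data must be centered with the training column means and
#' share the training grid.
#'
#' @param model An `ftir_pca`.
#' @param x Centered spectral tibble or matrix.
#' @return Score matrix, one row per input row.
#' @export
project_scores <- function(model, x) {
  stopifnot(inherits(model, "ftir_pca"))
  if (is.data.frame(x)) {
    if (!is.null(model$training_grid) &&
        !isTRUE(all.equal(spectra_grid(x), model$training_grid))) {
      abort("dataset grid does not match the PCA training grid")
    }
    x <- spectra_matrix(x)
  }
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$loadings)) {
    abort(sprintf("expected %d features, got %d",
                  nrow(model$loadings), ncol(x)))
  }
  x %*% model$loadings
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d component(s), %d features\n",
              x$n_components, nrow(x$loadings)))
  cat("  explained variance: ",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a PCA fit into a long loadings table
#'
#' @param x An `ftir_pca`.
#' @param ... Unused.
#' @return Tibble with columns `component`, `wavenumber` (or `feature` index
#'   when no grid is attached), `loading`.
#' @export
tidy.ftir_pca <- function(x, ...) {
  p <- nrow(x$loadings)
  key <- if (is.null(x$training_grid)) {
    tibble::tibble(feature = seq_len(p))
  } else {
    tibble::tibble(wavenumber = x$training_grid)
  }
  out <- tidyr::expand_grid(component = seq_len(x$n_components), key)
  out$loading <- as.vector(x$loadings)[
    (out$component - 1L) * p + rep(seq_len(p), x$n_components)]
  out
}

#' @export
glance.ftir_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    explained_variance_fraction = sum(x$explained_variance_fraction),
    pc1_variance_fraction = x$explained_variance_fraction[1]
  )
}

#' @export
autoplot.ftir_pca <- function(object, component = 1L, ...) {
  td <- dplyr::filter(tidy(object), .data$component == !!component)
  xvar <- if ("wavenumber" %in% names(td)) "wavenumber" else "feature"
  p <- ggplot2::ggplot(td, ggplot2::aes(.data[[xvar]], .data$loading)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (xvar == "wavenumber") expression(Wavenumber ~ (cm^-1)) else "Feature",
      y = sprintf("PC%d loading (%.1f%% variance)", component,
                  100 * object$explained_variance_fraction[component])
    ) +
    ggplot2::theme_minimal()
  if (xvar == "wavenumber") p <- p + ggplot2::scale_x_reverse()
  p
}
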