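#' Mahalanobis separation cost G
#'
#' Scores a candidate variable subset by how well it separates the classes
#' on a held-out validation set: for each validation sample n,
#' `g_n = r2(x_n, m_true) / min over wrong classes of r2(x_n, m_wrong)`,
#' where `r2` is the squared Mahalanobis distance under the pooled training
#' covariance, and `G = mean(g_n)` over all validation samples. Samples
#' close to their own class center and far from the others give small
#' `g_n`; `G = 0` means every validation sample sits exactly on its class
#' mean, and `g_n = 1` marks a sample equidistant from its own and the
#' nearest wrong class.
#'
#' @param x_val Validation feature matrix (rows = samples) restricted to the
#'   candidate variables.
#' @param y_val Validation class labels; every label must also appear in
#'   `y_train`.
#' @param x_train,y_train Training data on the same variables, used for the
#'   class means and pooled covariance (ridged when ill-conditioned, see
#'   details in the package vignette).
#' @return The scalar cost `G` (dimensionless, >= 0).
#' @export
spa_cost_g <- function(x_val, y_val, x_train, y_train) {
  x_val <- as.matrix(x_val); x_train <- as.matrix(x_train)
  classes <- sort(unique(as.character(y_train)))
  if (length(classes) < 2L) abort("training data must contain >= 2 classes")
  if (!all(y_val %in% classes)) {
    abort("validation labels include a class absent from training")
  }
  stats <- .pooled_stats(x_train, y_train, classes)
  r2 <- .mahal_sq(x_val, stats$means, stats$C_inv)  # n_val x n_class
  own <- match(as.character(y_val), classes)
  g <- vapply(seq_len(nrow(r2)), function(i) {
    num <- r2[i, own[i]]
    den <- min(r2[i, -own[i]])
    if (den == 0) {
      if (num == 0) return(1)  # on both centers at once: no separation signal
      return(Inf)
    }
    num / den
  }, numeric(1))
  mean(g)
}

# Class means + pooled covariance (divisor n - K), ridged if ill-conditioned.
.pooled_stats <- function(X, y, classes) {
  y <- as.character(y)
  p <- ncol(X)
  means <- t(matrix(vapply(classes,
                           function(k) colMeans(X[y == k, , drop = FALSE]),
                           numeric(p)),
                    nrow = p, dimnames = list(NULL, classes)))
  n <- nrow(X); K <- length(classes)
  Cp <- matrix(0, p, p)
  for (k in classes) {
    Xk <- X[y == k, , drop = FALSE]
    if (nrow(Xk) >= 2L) {
      Cp <- Cp + (nrow(Xk) - 1L) * stats::cov(Xk)
    }
  }
  Cp <- Cp / max(n - K, 1L)
  rr <- ridge_covariance(Cp)
  list(means = means, C = rr$C, C_inv = solve(rr$C), lambda = rr$lambda)
}

# Squared Mahalanobis distances of rows of X to each mean (rows of M).
.mahal_sq <- function(X, M, C_inv) {
  out <- matrix(0, nrow(X), nrow(M))
  for (k in seq_len(nrow(M))) {
    d <- sweep(X, 2, M[k, ])
    out[, k] <- rowSums((d %*% C_inv) * d)
  }
  out
}

# Classical successive-projections chain from one starting column: repeatedly
# append the column with maximal norm after projection onto the orthogonal
# complement of the span of the chosen columns. Ties -> lowest index.
.spa_chain <- function(X, start, max_vars) {
  p <- ncol(X)
  P <- X
  chain <- integer(0)
  current <- start
  for (step in seq_len(max_vars)) {
    chain <- c(chain, current)
    if (length(chain) == max_vars) break
    v <- P[, current]
    nv2 <- sum(v^2)
    if (nv2 <= 1e-300) break
    P <- P - v %*% (crossprod(v, P) / nv2)
    norms <- colSums(P^2)
    norms[chain] <- -Inf
    nxt <- which.max(norms)          # which.max takes the lowest index on ties
    if (norms[nxt] <= 1e-12 * max(colSums(X^2))) break  # only collinear left
    current <- nxt
  }
  chain
}

#' Successive projections algorithm variable selection
#'
#' Two-phase deterministic selection. Phase 1 (projection phase, on the
#' training matrix): from every starting variable, build a chain of length
#' up to `max_vars` by repeatedly appending the variable whose column has
#' maximal norm after orthogonal projection off the span of the variables
#' already in the chain — each chain is a minimally collinear variable set.
#' Phase 2 (scoring): every prefix of every chain is a candidate subset and
#' is scored by the Mahalanobis cost [spa_cost_g()] on the validation set;
#' the subset with minimal G wins (ties: fewer variables, then the earlier
#' candidate in enumeration order).
#'
#' @param x_train,y_train Training feature matrix (samples x variables) and
#'   class labels.
#' @param x_val,y_val Validation data for the cost (same variables).
#' @param max_vars Maximum subset size (`>= 1`, at most
#'   `min(n_train - 1, p)`).
#' @return An object of class `spa_selection`: `selected_indices` (ordered
#'   as chosen), `cost_g` (G of the winner), `candidates` (tibble of every
#'   scored subset: `start`, `size`, `g`, `indices` list-column), and
#'   `by_size` (per-size best candidate).
#' @export
spa_select <- function(x_train, y_train, x_val, y_val, max_vars) {
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  p <- ncol(x_train)
  max_vars <- as.integer(max_vars)
  if (max_vars < 1L) abort("`max_vars` must be >= 1")
  max_vars <- min(max_vars, nrow(x_train) - 1L, p)

  chains <- purrr::map(seq_len(p), ~ .spa_chain(x_train, .x, max_vars))
  cand <- purrr::map_dfr(seq_len(p), function(s) {
    ch <- chains[[s]]
    tibble::tibble(start = s, size = seq_along(ch),
                   indices = purrr::map(seq_along(ch), ~ ch[seq_len(.x)]))
  })
  # score each distinct subset once (prefixes repeat heavily across starts)
  keysig <- vapply(cand$indices, paste, character(1), collapse = ",")
  uniq <- !duplicated(keysig)
  g_of <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    idx <- cand$indices[[i]]
    g <- spa_cost_g(x_val[, idx, drop = FALSE], y_val,
                    x_train[, idx, drop = FALSE], y_train)
    assign(keysig[i], g, envir = g_of)
  }
  cand$g <- vapply(keysig, function(k) get(k, envir = g_of), numeric(1),
                   USE.NAMES = FALSE)

  ord <- order(cand$g, cand$size, seq_len(nrow(cand)))
  winner <- cand[ord[1], ]
  by_size <- dplyr::slice_min(dplyr::group_by(cand, .data$size),
                              order_by = .data$g, n = 1, with_ties = FALSE)
  structure(list(
    selected_indices = winner$indices[[1]],
    cost_g = winner$g,
    n_selected = length(winner$indices[[1]]),
    candidates = cand,
    by_size = dplyr::ungroup(by_size)
  ), class = "spa_selection")
}

#' @export
print.spa_selection <- function(x, ...) {
  cat(sprintf("<spa_selection> %d variable(s), G = %.4g\n",
              x$n_selected, x$cost_g))
  cat("  indices:", paste(x$selected_indices, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.spa_selection <- function(x, ...) {
  tibble::tibble(rank = seq_along(x$selected_indices),
                 index = x$selected_indices)
}
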