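# Independent brute-force oracles used to cross-check the implementations.
# Each is written directly from the defining rule, with plain loops, and
# shares no code with the package internals it checks.

# Savitzky-Golay by explicit per-window polynomial regression. Interior
# points use the centred window; edge points reuse the nearest full window
# and evaluate the fitted polynomial at their offset inside it.
oracle_savgol <- function(x, window, polyorder) {
  n <- length(x)
  half <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1, i - half), n - window + 1)
    idx <- lo:(lo + window - 1)
    fit <- stats::lm(y ~ poly(t, polyorder, raw = TRUE),
                     data = data.frame(t = idx - i, y = x[idx]))
    out[i] <- stats::predict(fit, newdata = data.frame(t = 0))
  }
  out
}

# Kennard-Stone max-min selection by direct simulation of the rule.
oracle_kennard_stone <- function(X, n_train) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); best_d <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > best_d) { best_d <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_train) {
    rem <- setdiff(1:n, sel)
    score <- sapply(rem, function(r) min(D[r, sel]))
    sel <- c(sel, rem[which.max(score)])
  }
  sel
}

# Exhaustive SPA: enumerate every projection chain from every start by the
# defining recursion, score every prefix on the validation set, return the
# minimal-G subset (ties: smaller, then enumeration order).
oracle_spa <- function(x_train, y_train, x_val, y_val, max_vars) {
  p <- ncol(x_train)
  chains <- list()
  for (s in 1:p) {
    chain <- s
    P <- x_train
    while (length(chain) < max_vars) {
      v <- P[, chain[length(chain)]]
      if (sum(v^2) < 1e-300) break
      P <- P - outer(v, as.vector(crossprod(v, P)) / sum(v^2))
      norms <- apply(P, 2, function(col) sum(col^2))
      norms[chain] <- -Inf
      nxt <- which.max(norms)
      if (norms[nxt] <= 1e-12 * max(apply(x_train, 2, function(c) sum(c^2)))) break
      chain <- c(chain, nxt)
    }
    chains[[s]] <- chain
  }
  best <- NULL; best_g <- Inf; best_size <- Inf
  for (ch in chains) for (k in seq_along(ch)) {
    idx <- ch[1:k]
    g <- spa_cost_g(x_val[, idx, drop = FALSE], y_val,
                    x_train[, idx, drop = FALSE], y_train)
    if (g < best_g || (g == best_g && k < best_size)) {
      best <- idx; best_g <- g; best_size <- k
    }
  }
  list(indices = best, g = best_g)
}

# KKT feasibility check of an SVM dual solution, straight from the
# stationarity/complementarity conditions of the soft-margin dual.
check_svm_kkt <- function(model, X, y_num, tol = 1e-4) {
  a <- model$alpha_full
  C <- model$cost
  K <- exp(-model$gamma * as.matrix(dist(X))^2)
  f <- drop(K %*% (a * y_num)) + model$b
  ok_box <- all(a >= -1e-10) && all(a <= C + 1e-10)
  ok_eq <- abs(sum(a * y_num)) <= 1e-6 * max(1, C)
  margin <- y_num * f
  viol <- c(
    1 - margin[a < 1e-8],                     # alpha = 0  ->  y f >= 1
    margin[a > C - 1e-8] - 1,                 # alpha = C  ->  y f <= 1
    abs(margin[a > 1e-8 & a < C - 1e-8] - 1)  # interior   -> y f  = 1
  )
  max_viol <- if (length(viol)) max(viol) else 0
  list(ok = ok_box && ok_eq && max_viol < tol,
       box = ok_box, eq = ok_eq, max_violation = max_viol)
}

# Small cohort for fast structural tests.
tiny_cohort_config <- function(...) {
  cohort_config(n_control = 5, n_case = 5, n_replicates = 2, ...)
}
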