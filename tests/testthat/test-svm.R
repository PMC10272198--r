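test_that("the RBF kernel is 1 at zero distance for any gamma", {
  X <- matrix(rnorm(10), ncol = 2)
  for (g in c(1e-4, 1, 50)) {
    expect_equal(unname(diag(rbf_kernel(X, gamma = g))), rep(1, 5))
  }
  expect_error(rbf_kernel(X, gamma = 0), "gamma")
})

test_that("the two-point instance has its boundary at the midpoint", {
  # one sample per class: closed-form dual gives alpha1 = alpha2 and a
  # decision that changes sign exactly at the midpoint
  X <- rbind(c(0, 0), c(2, 0))
  m <- fit_svm(X, c(-1, 1), cost = 10, gamma = 0.5)
  expect_equal(m$n_sv, 2L)
  expect_equal(m$alphas[1], m$alphas[2], tolerance = 1e-8)
  expect_equal(sum(m$alphas * m$sv_labels), 0, tolerance = 1e-6)
  # closed form: alpha = 1 / (1 - K12), b = 0
  k12 <- exp(-0.5 * 4)
  expect_equal(m$alphas[1], 1 / (1 - k12), tolerance = 1e-4)
  expect_equal(m$b, 0, tolerance = 1e-6)

  expect_equal(predict(m, X), c(-1, 1))                  # interpolation
  expect_lt(abs(decision_values(m, c(1, 0))), 1e-6)      # boundary at midpoint
  expect_equal(predict(m, rbind(c(0.9, 0), c(1.1, 0))), c(-1, 1))

  # the documented sign(0) -> +1 tie rule, on an exactly symmetric model
  sym <- structure(list(support_vectors = X, alphas = c(1, 1),
                        sv_labels = c(-1, 1), b = 0, gamma = 0.5,
                        cost = 10, classes = NULL, n_sv = 2L),
                   class = "rbf_svm")
  expect_equal(decision_values(sym, c(1, 0)), 0)
  expect_equal(predict(sym, rbind(c(1, 0))), 1)
})

test_that("a large-gamma SVM separates the XOR pattern", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c(1, 1, -1, -1)
  m <- fit_svm(X, y, cost = 1000, gamma = 10)
  expect_equal(predict(m, X), y)
})

test_that("dual feasibility holds at the returned solution", {
  set.seed(31)
  X <- matrix(rnorm(24), ncol = 2)
  y <- rep(c(1, -1), 6)
  for (C in c(0.5, 8)) {
    m <- fit_svm(X, y, cost = C, gamma = 1)
    expect_true(all(m$alpha_full >= 0 & m$alpha_full <= C + 1e-10))
    expect_lt(abs(sum(m$alpha_full * y)), 1e-6 * max(1, C))
  }
})

test_that("the solution is KKT-feasible and agrees with libsvm", {
  skip_if_not_installed("e1071")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 2), ncol = 2) +
      rep(c(0, 1.5), length.out = n)      # loose structure, both labels
    y <- rep(c(1, -1), length.out = n)
    C <- sample(c(1, 10), 1)
    g <- sample(c(0.5, 2), 1)
    m <- fit_svm(X, y, cost = C, gamma = g)

    kkt <- check_svm_kkt(m, X, y, tol = 1e-3)
    expect_true(kkt$ok, info = sprintf("rep %d max viol %.2g", rep,
                                       kkt$max_violation))

    ref <- e1071::svm(X, factor(y), scale = FALSE, kernel = "radial",
                      cost = C, gamma = g, tolerance = 1e-6)
    Z <- matrix(rnorm(40), ncol = 2)
    expect_equal(predict(m, Z),
                 as.numeric(as.character(predict(ref, Z))),
                 info = sprintf("rep %d", rep))
  }
})

test_that("labelled factors map through the declared positive class", {
  set.seed(2)
  X <- rbind(matrix(rnorm(12, 0), ncol = 2), matrix(rnorm(12, 4), ncol = 2))
  y <- rep(c("control", "case"), each = 6)
  m <- fit_svm(X, y, cost = 10, gamma = 0.5, positive = "case")
  expect_setequal(unique(predict(m, X)), c("control", "case"))
  expect_equal(predict(m, X), y)
  expect_error(fit_svm(X, y, positive = "tumour"), "positive class")
  expect_error(fit_svm(X, rep("case", 12)), "2 classes")
})

test_that("tuning returns the accuracy-maximal lattice point", {
  set.seed(8)
  X <- rbind(matrix(rnorm(20, 0, 0.5), ncol = 2),
             matrix(rnorm(20, 3, 0.5), ncol = 2))
  y <- rep(c(-1, 1), each = 10)
  folds <- venetian_blinds(20, 5)

  one <- tune_svm(X, y, folds, grid = tibble::tibble(cost = 2, gamma = 0.1))
  expect_equal(one$best_cost, 2)
  expect_equal(one$best_gamma, 0.1)

  tuned <- tune_svm(X, y, folds)
  expect_true(all(tuned$results$cv_accuracy <= tuned$cv_accuracy))
  # ties resolve to the smallest cost, then gamma
  top <- tuned$results[tuned$results$cv_accuracy == tuned$cv_accuracy, ]
  expect_equal(tuned$best_cost, min(top$cost))
})

test_that("a single-class fold is skipped with a warning", {
  set.seed(1)
  X <- matrix(rnorm(6), ncol = 1)
  y <- c(1, -1, 1, -1, 1, 1)
  folds <- c(2, 2, 2, 2, 1, 1)   # fold 2's training complement is one class
  expect_warning(
    res <- tune_svm(X, y, folds, grid = tibble::tibble(cost = 1, gamma = 1)),
    "single-class"
  )
  expect_true(is.finite(res$cv_accuracy))
})
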