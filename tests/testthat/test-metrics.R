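test_that("confusion counts follow the declared positive class", {
  y <- c("case", "case", "control", "control")
  expect_equal(as.list(confusion_counts(y, y))[c("fp", "fn")],
               list(fp = 0L, fn = 0L))
  flipped <- rev(y)
  expect_equal(as.list(confusion_counts(y, flipped))[c("tp", "tn")],
               list(tp = 0L, tn = 0L))

  truth <- c("case", "case", "case", "control", "control",
             "control", "case", "control", "case", "control")
  pred <- c("case", "control", "case", "control", "case",
            "control", "case", "control", "control", "case")
  cc <- confusion_counts(truth, pred)
  expect_equal(as.list(cc), list(tp = 3L, tn = 3L, fp = 2L, fn = 2L))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 10L)

  expect_error(confusion_counts(c("case", "healthy"), c("case", "case")),
               "healthy")
  expect_error(confusion_counts(character(0), character(0)), "non-empty")
})

test_that("F-score and G-score arithmetic on benchmark integer pairs", {
  # equal sensitivity/specificity pairs are fixed points
  expect_equal(unname(fscore_gscore(56, 56)), c(56, 56))
  expect_equal(unname(fscore_gscore(89, 89)), c(89, 89))

  # (67, 78): harmonic 72.08 -> 72, geometric 72.29 -> 72
  fg <- fscore_gscore(67, 78)
  expect_equal(floor(fg + 0.5), c(fs = 72, gs = 72))
  expect_equal(unname(fg["fs"]), 2 * 67 * 78 / 145, tolerance = 1e-12)

  # (33, 89): harmonic 48.15 -> 48
  expect_equal(floor(fscore_gscore(33, 89)["fs"] + 0.5), c(fs = 48))

  # zero sensitivity annihilates both means
  expect_equal(unname(fscore_gscore(0, 100)), c(0, 0))

  # direct-formula check away from the benchmark pairs
  fg2 <- fscore_gscore(22, 44)
  expect_equal(unname(fg2["fs"]), 2 * 22 * 44 / 66, tolerance = 1e-12)
  expect_equal(unname(fg2["gs"]), sqrt(22 * 44), tolerance = 1e-12)
})

test_that("figures of merit satisfy their exact identities", {
  cc <- tibble::tibble(tp = 5L, tn = 5L, fp = 0L, fn = 0L)
  fom <- figures_of_merit(cc)
  expect_equal(unlist(fom[c("ac", "sens", "spec", "fs", "gs")]),
               c(ac = 100, sens = 100, spec = 100, fs = 100, gs = 100))

  set.seed(99)
  for (i in 1:50) {
    counts <- tibble::tibble(tp = sample(0:20, 1), tn = sample(0:20, 1),
                             fp = sample(0:20, 1), fn = sample(0:20, 1))
    if (counts$tp + counts$fn == 0 || counts$tn + counts$fp == 0) next
    f <- figures_of_merit(counts)
    n <- counts$tp + counts$tn + counts$fp + counts$fn
    # accuracy is the class-size-weighted mean of SENS and SPEC
    expect_equal(f$ac,
                 (f$sens * (counts$tp + counts$fn) +
                  f$spec * (counts$tn + counts$fp)) / n,
                 tolerance = 1e-12)
  }

  expect_error(figures_of_merit(tibble::tibble(tp = 0, tn = 3, fp = 2,
                                               fn = 0)), "positive")
  expect_error(figures_of_merit(tibble::tibble(tp = 3, tn = 0, fp = 0,
                                               fn = 2)), "negative")
})

test_that("harmonic <= geometric <= arithmetic on random confusion tables", {
  set.seed(123)
  for (i in 1:1000) {
    sens <- stats::runif(1, 0, 100)
    spec <- stats::runif(1, 0, 100)
    fg <- fscore_gscore(sens, spec)
    expect_lte(fg[["fs"]], fg[["gs"]] + 1e-12)
    expect_lte(fg[["gs"]], (sens + spec) / 2 + 1e-12)
  }
  # equality exactly when SENS = SPEC
  fg_eq <- fscore_gscore(37.5, 37.5)
  expect_equal(fg_eq[["fs"]], fg_eq[["gs"]])
  expect_equal(fg_eq[["gs"]], 37.5)
})

test_that("the comparison table rounds and flags the best model", {
  good <- figures_of_merit(tibble::tibble(tp = 8, tn = 9, fp = 1, fn = 1))
  poor <- figures_of_merit(tibble::tibble(tp = 5, tn = 5, fp = 5, fn = 4))
  single <- comparison_table(list("pca-svm" = good))
  expect_equal(nrow(single), 1L)
  expect_true(single$best)

  tab <- comparison_table(list("pca-svm" = good, "pca-lda" = poor))
  expect_equal(tab$best, c(TRUE, FALSE))
  expect_equal(tab$ac[1], 89)      # 17/19 = 89.47 -> 89

  # an accuracy tie is broken by the (unrounded) G-score
  a <- figures_of_merit(tibble::tibble(tp = 4, tn = 6, fp = 0, fn = 2))
  b <- figures_of_merit(tibble::tibble(tp = 5, tn = 5, fp = 1, fn = 1))
  expect_equal(a$ac, b$ac)
  tie <- comparison_table(list(m1 = a, m2 = b))
  expect_equal(tie$best, c(a$gs > b$gs, b$gs >= a$gs))
})

test_that("display rounding goes half away from zero", {
  half <- figures_of_merit(tibble::tibble(tp = 1, tn = 1, fp = 1, fn = 1))
  # sens = spec = 50 exactly; ac = 50
  tab <- comparison_table(list(m = half))
  expect_equal(tab$ac, 50)
  expect_equal(serafir:::round_percent(72.5), 73)
  expect_equal(serafir:::round_percent(71.5), 72)   # not banker's rounding
})
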