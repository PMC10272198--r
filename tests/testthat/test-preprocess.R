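test_that("Savitzky-Golay reproduces low-degree polynomials exactly", {
  t <- seq(0, 5, length.out = 41)
  quad <- 1.5 - 0.7 * t + 0.3 * t^2
  expect_equal(sg_smooth(quad), quad, tolerance = 1e-10)
  expect_equal(sg_smooth(rep(2.5, 20)), rep(2.5, 20), tolerance = 1e-12)
})

test_that("Savitzky-Golay equals the per-window regression oracle", {
  set.seed(42)
  x <- cumsum(rnorm(51))
  cfg <- preprocess_config()
  expect_equal(sg_smooth(x, cfg), oracle_savgol(x, 5, 2), tolerance = 1e-9)

  cfg7 <- preprocess_config(sg_window = 7, sg_polyorder = 3)
  expect_equal(sg_smooth(x, cfg7), oracle_savgol(x, 7, 3), tolerance = 1e-9)

  expect_error(sg_smooth(x[1:3]), "shorter")
  expect_error(preprocess_config(sg_window = 4), "odd")
  expect_error(preprocess_config(sg_window = 1), "exceed")
})

test_that("AWLS reproduces a pure polynomial baseline exactly", {
  grid <- seq(1800, 900, by = -2)
  t <- (grid - 900) / 900
  poly <- 0.4 + 0.2 * t - 0.15 * t^2
  res <- awls_baseline(poly, grid)
  expect_true(res$converged)
  expect_lt(max(abs(res$corrected)), 1e-8 * max(abs(poly)))
  expect_equal(res$baseline, poly, tolerance = 1e-8)

  zero <- awls_baseline(rep(0, length(grid)), grid)
  expect_equal(zero$baseline, rep(0, length(grid)))
  expect_equal(zero$corrected, rep(0, length(grid)))
})

test_that("AWLS recovers a tall peak on a polynomial drift", {
  grid <- seq(1800, 900, by = -2)
  t <- (grid - 900) / 900
  baseline <- 0.3 - 0.1 * t + 0.05 * t^2
  peak <- gaussian_band(grid, 1400, 15, 1.0)
  cfg <- preprocess_config(awls_max_iter = 500)
  res <- awls_baseline(baseline + peak, grid, cfg)
  apex <- res$corrected[grid == 1400]
  expect_lt(abs(apex - 1.0), 0.02)

  # the screened (above-baseline) set only accumulates after iteration 1:
  # a point once above the settling baseline never drops back below it
  tr <- res$screened_trace
  if (length(tr) > 2) {
    for (k in 3:length(tr)) {
      expect_true(all(!tr[[k - 1]] | tr[[k]]))
    }
  }
})

test_that("the soft AWLS variant also settles under a peak", {
  grid <- seq(1800, 900, by = -2)
  t <- (grid - 900) / 900
  baseline <- 0.2 + 0.1 * t
  peak <- gaussian_band(grid, 1300, 20, 0.8)
  cfg <- preprocess_config(awls_weight = "soft", awls_max_iter = 500)
  res <- awls_baseline(baseline + peak, grid, cfg)
  expect_lt(abs(res$corrected[grid == 1300] - 0.8), 0.05)
})

test_that("region truncation is inclusive and order-preserving", {
  co <- simulate_cohort(
    cohort_config(n_control = 2, n_case = 2, n_replicates = 1,
                  wn_start = 4000, wn_end = 600, wn_step = 2),
    seed = 1
  )
  tr <- truncate_region(co$spectra, c(1800, 900))
  expect_length(spectra_grid(tr), 451L)
  expect_equal(range(spectra_grid(tr)), c(900, 1800))

  full <- truncate_region(co$spectra, c(4000, 600))
  expect_identical(full, co$spectra)

  one <- truncate_region(co$spectra, c(1000, 1000))
  expect_length(spectra_grid(one), 1L)
  expect_equal(spectra_grid(one), 1000)

  expect_error(truncate_region(co$spectra, c(401, 400)), "no grid points")
})

test_that("replicate averaging is the arithmetic mean with inherited labels", {
  ds <- tibble::tibble(
    sample_id = c("a", "a", "b"),
    replicate_id = c("r1", "r2", "r1"),
    class_label = c("control", "control", "case"),
    `1800` = c(0, 2, 9), `1798` = c(0, 4, 9), `1796` = c(0, 6, 9)
  )
  avg <- average_replicates(ds)
  expect_equal(nrow(avg), 2L)
  expect_equal(unname(spectra_matrix(avg)[1, ]), c(1, 2, 3))
  expect_equal(avg$class_label, c("control", "case"))

  # idempotence: identical replicates average to themselves
  same <- ds
  same$`1800` <- 5; same$`1798` <- 5; same$`1796` <- 5
  expect_equal(unname(spectra_matrix(average_replicates(same))[1, ]),
               c(5, 5, 5))

  bad <- ds
  bad$class_label[2] <- "case"
  expect_error(average_replicates(bad), "conflicting")
})

test_that("replicate averaging shrinks noise variance by 1/n_replicates", {
  # pure-noise cohorts across seeds: per-point variance of the averaged
  # spectra should match noise_sd^2 / n_replicates
  cfg <- cohort_config(n_control = 2, n_case = 2, n_replicates = 3,
                       base_bands = serum_base_bands()[1, ],
                       effect_bands = osteo_effect_bands(scale = 0),
                       baseline_coeffs_sd = rep(0, 4), noise_sd = 0.01)
  # the deterministic band signal is identical across samples and seeds, so
  # the spread of these values is purely averaged noise
  vals <- unlist(lapply(1:40, function(s) {
    co <- simulate_cohort(cfg, seed = s)
    spectra_matrix(average_replicates(co$spectra))[, 100]
  }))
  expect_equal(stats::var(vals), 0.01^2 / 3, tolerance = 0.35)
})

test_that("centering is fitted on training rows and applied elsewhere", {
  co <- simulate_cohort(tiny_cohort_config(), seed = 2)
  ds <- average_replicates(co$spectra)
  train <- ds[1:6, ]
  test <- ds[7:10, ]
  model <- fit_centering(train)
  centred <- apply_centering(train, model)
  expect_lt(max(abs(colMeans(spectra_matrix(centred)))), 1e-12)

  single <- fit_centering(train[1, ])
  expect_equal(max(abs(spectra_matrix(apply_centering(train[1, ], single)))), 0)

  centred_test <- apply_centering(test, model)
  expect_equal(colMeans(spectra_matrix(centred_test)),
               colMeans(spectra_matrix(test)) - model$column_means)

  shifted <- test
  names(shifted)[4] <- "123.5"
  expect_error(apply_centering(shifted, model), "grid")
})

test_that("the full preprocessing chain is deterministic and ordered", {
  co <- simulate_cohort(tiny_cohort_config(), seed = 6)
  a <- preprocess_spectra(co$spectra)
  b <- preprocess_spectra(co$spectra)
  expect_identical(a$spectra, b$spectra)
  expect_equal(nrow(a$spectra), 10L)       # one row per sample
  expect_equal(range(spectra_grid(a$spectra)), c(900, 1800))
  expect_true(all(a$spectra$replicate_id == "mean"))
})
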