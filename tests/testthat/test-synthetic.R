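test_that("gaussian_band has the stated shape, peak and integral", {
  grid <- seq(1800, 900, by = -2)

  expect_equal(gaussian_band(grid, 1650, 20, 0), rep(0, length(grid)))

  band <- gaussian_band(grid, 1650, 20, 1)
  expect_equal(band[grid == 1650], 1)
  expect_equal(max(band), 1)

  # integral against numerical quadrature of the same analytic density
  quad <- stats::integrate(function(w) gaussian_band(w, 1650, 20, 0.7),
                           900, 1800)$value
  expect_equal(quad, 0.7 * 20 * sqrt(2 * pi), tolerance = 1e-6)

  expect_error(gaussian_band(grid, 1650, 0, 1), "width")
  expect_error(gaussian_band(grid, 1650, -3, 1), "width")
})

test_that("cohort config enforces its invariants", {
  expect_error(cohort_config(n_control = 1), "2 samples")
  expect_error(cohort_config(n_replicates = 0), "n_replicates")
  expect_error(cohort_config(wn_start = 900, wn_end = 1800), "wn_start")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(
    cohort_config(effect_bands = tibble::tibble(center = 250, width = 5,
                                                amplitude = 0.1)),
    "inside"
  )
  expect_error(
    cohort_config(base_bands = tibble::tibble(center = 1650, width = 0,
                                              amplitude = 0.1)),
    "width"
  )
})

test_that("noise-free cohorts are exact band sums", {
  cfg <- cohort_config(n_control = 3, n_case = 3, n_replicates = 3,
                       baseline_coeffs_sd = rep(0, 4), noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 5)
  X <- spectra_matrix(co$spectra)
  grid <- spectra_grid(co$spectra)

  # replicates of one sample are identical
  for (id in unique(co$spectra$sample_id)) {
    rows <- X[co$spectra$sample_id == id, , drop = FALSE]
    expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
  }

  # any case spectrum minus any control spectrum = sum of effect bands
  effect <- Reduce(`+`, purrr::pmap(cfg$effect_bands,
    function(center, width, amplitude)
      gaussian_band(grid, center, width, amplitude)))
  ctrl <- X[co$spectra$class_label == "control", ][1, ]
  case <- X[co$spectra$class_label == "case", ][1, ]
  expect_equal(unname(case - ctrl), effect, tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- tiny_cohort_config()
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  c <- simulate_cohort(cfg, seed = 12)
  expect_identical(a$spectra, b$spectra)
  expect_false(isTRUE(all.equal(a$spectra, c$spectra)))
})

test_that("enlarging the cohort leaves earlier samples' draws untouched", {
  small <- simulate_cohort(cohort_config(n_control = 4, n_case = 4,
                                         n_replicates = 2), seed = 3)
  big <- simulate_cohort(cohort_config(n_control = 4, n_case = 6,
                                       n_replicates = 2), seed = 3)
  shared <- small$spectra$sample_id
  expect_identical(small$spectra,
                   big$spectra[big$spectra$sample_id %in% shared, ])
})

test_that("class-mean difference recovers the planted effect as noise -> 0", {
  cfg <- cohort_config(n_control = 6, n_case = 6, n_replicates = 1,
                       baseline_coeffs_sd = rep(0, 4), noise_sd = 1e-9)
  co <- simulate_cohort(cfg, seed = 21)
  X <- spectra_matrix(co$spectra)
  grid <- spectra_grid(co$spectra)
  diff_mean <- colMeans(X[co$spectra$class_label == "case", ]) -
    colMeans(X[co$spectra$class_label == "control", ])
  effect <- Reduce(`+`, purrr::pmap(cfg$effect_bands,
    function(center, width, amplitude)
      gaussian_band(grid, center, width, amplitude)))
  expect_equal(unname(diff_mean), effect, tolerance = 1e-6)
})

test_that("exchangeable null cohorts carry no class signal in the mean", {
  cfg <- cohort_config(n_control = 8, n_case = 8, n_replicates = 2,
                       effect_bands = osteo_effect_bands(scale = 0))
  co <- simulate_cohort(cfg, seed = 9)
  X <- spectra_matrix(co$spectra)
  d <- colMeans(X[co$spectra$class_label == "case", ]) -
    colMeans(X[co$spectra$class_label == "control", ])
  # class-mean difference is pure noise + baseline: far below effect scale
  expect_lt(stats::median(abs(d)), 0.01)
  expect_identical(co$planted_effect_centers,
                   osteo_effect_bands()$center)
})
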