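#' Run the full spectral classification pipeline
#'
#' Executes the fixed analysis chain on a replicate-level spectral tibble:
#' preprocessing (Savitzky-Golay smoothing, AWLS baseline correction,
#' biofingerprint truncation, replicate averaging), Kennard-Stone 70/30
#' train/test splitting on the preprocessed per-sample spectra, training-mean
#' centering, feature reduction (PCA) or discrete variable selection (SPA),
#' classification (non-Bayesian LDA/QDA or RBF-SVM) with venetian-blinds
#' cross-validated model selection, and test-set figures of merit. Every
#' stage after simulation is deterministic, so identical input gives an
#' identical report; test-partition rows are touched only in the final
#' evaluation.
#'
#' Model-complexity choices are cross-validated on the training partition:
#' the number of principal components over `pc_range` and the SPA variable
#' count over the per-size best SPA candidates (both: ties go to the
#' smaller model), and the SVM `(C, gamma)` pair over `svm_grid`. The SPA
#' cost G is evaluated on an inner Kennard-Stone 70/30 split of the
#' training partition, so the test set never informs selection.
#'
#' @param ds Replicate-level spectral tibble with known class labels
#'   (`control`/`case`), e.g. `simulate_cohort(...)$spectra` or
#'   [read_spectra()] output.
#' @param methods Subset of
#'   `c("pca-lda", "pca-qda", "pca-svm", "spa-lda", "spa-qda", "spa-svm")`.
#' @param preprocess A [preprocess_config()].
#' @param split_fraction Kennard-Stone training fraction; default 0.7.
#' @param cv_folds Venetian-blinds fold count; default 10.
#' @param pc_range Candidate numbers of principal components; default
#'   `1:10`.
#' @param spa_max_vars Maximum SPA subset size; default 15.
#' @param svm_grid `(cost, gamma)` lattice for [tune_svm()]; default
#'   [svm_default_grid()].
#' @param positive Positive class; default `"case"`.
#' @return An object of class `ftir_run`; see [tidy.ftir_run()],
#'   [glance.ftir_run()] and `autoplot()`.
#' @export
run_pipeline <- function(ds,
                         methods = c("pca-lda", "pca-qda", "pca-svm",
                                     "spa-lda", "spa-qda", "spa-svm"),
                         preprocess = preprocess_config(),
                         split_fraction = 0.7,
                         cv_folds = 10L,
                         pc_range = 1:10,
                         spa_max_vars = 15L,
                         svm_grid = svm_default_grid(),
                         positive = "case") {
  methods <- match.arg(methods, several.ok = TRUE)
  .check_spectra(ds, require_class = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- numeric(0)
  tic <- function() proc.time()[["elapsed"]]
  lap <- function(name, since) {
    timings[[name]] <<- tic() - since
  }

  # --- preprocess -----------------------------------------------------------
  t_stage <- tic()
  pp <- preprocess_spectra(ds, preprocess)
  samples <- pp$spectra
  grid <- spectra_grid(samples)
  y_all <- samples$class_label
  lap("preprocess", t_stage)

  # --- split (on preprocessed, replicate-averaged, uncentered spectra) ------
  t_stage <- tic()
  split <- kennard_stone(samples, fraction = split_fraction)
  train_rows <- sort(split$train_indices)   # dataset row order for CV folds
  test_rows <- sort(split$test_indices)
  train_ds <- samples[train_rows, ]
  test_ds <- samples[test_rows, ]
  y_train <- y_all[train_rows]
  y_test <- y_all[test_rows]
  folds <- venetian_blinds(length(train_rows), cv_folds)
  lap("split", t_stage)

  # --- center with training means -------------------------------------------
  centering <- fit_centering(train_ds)
  Xtr <- spectra_matrix(apply_centering(train_ds, centering))
  Xte <- spectra_matrix(apply_centering(test_ds, centering))

  models <- list()
  foms <- list()
  pca_model <- NULL
  spa_sel <- NULL

  # --- PCA branch -----------------------------------------------------------
  if (any(startsWith(methods, "pca"))) {
    t_stage <- tic()
    rank_max <- qr(Xtr)$rank
    pc_range <- pc_range[pc_range <= min(rank_max, ncol(Xtr), nrow(Xtr) - 1L)]
    if (!length(pc_range)) abort("`pc_range` exceeds the achievable rank")
    pca_model <- fit_pca(Xtr, max(pc_range))
    pca_model$training_grid <- grid
    scores_tr <- pca_model$scores
    scores_te <- project_scores(pca_model, Xte)
    lap("pca", t_stage)

    for (m in intersect(methods, c("pca-lda", "pca-qda", "pca-svm"))) {
      t_stage <- tic()
      kind <- sub("pca-", "", m)
      sel <- .select_width(scores_tr, y_train, folds, pc_range, kind,
                           svm_grid, positive)
      Ztr <- scores_tr[, seq_len(sel$width), drop = FALSE]
      Zte <- scores_te[, seq_len(sel$width), drop = FALSE]
      fit <- .fit_final(Ztr, y_train, kind, sel, positive)
      pred <- predict(fit$model, Zte)
      foms[[m]] <- figures_of_merit(confusion_counts(y_test, pred, positive))
      models[[m]] <- c(fit, list(n_components = sel$width,
                                 cv_accuracy = sel$cv_accuracy))
      lap(m, t_stage)
    }
  }

  # --- SPA branch -----------------------------------------------------------
  if (any(startsWith(methods, "spa"))) {
    t_stage <- tic()
    inner <- kennard_stone(Xtr, fraction = 0.7)
    spa_sel <- spa_select(Xtr[inner$train_indices, , drop = FALSE],
                          y_train[inner$train_indices],
                          Xtr[inner$test_indices, , drop = FALSE],
                          y_train[inner$test_indices],
                          max_vars = spa_max_vars)
    lap("spa", t_stage)

    for (m in intersect(methods, c("spa-lda", "spa-qda", "spa-svm"))) {
      t_stage <- tic()
      kind <- sub("spa-", "", m)
      cand_sets <- spa_sel$by_size$indices
      sel <- .select_subset(Xtr, y_train, folds, cand_sets, kind,
                            svm_grid, positive)
      idx <- cand_sets[[sel$which]]
      fit <- .fit_final(Xtr[, idx, drop = FALSE], y_train, kind, sel, positive)
      pred <- predict(fit$model, Xte[, idx, drop = FALSE])
      foms[[m]] <- figures_of_merit(confusion_counts(y_test, pred, positive))
      models[[m]] <- c(fit, list(selected_indices = idx,
                                 selected_wavenumbers = grid[idx],
                                 cv_accuracy = sel$cv_accuracy))
      lap(m, t_stage)
    }
  }

  # --- loading peaks (PC1) --------------------------------------------------
  peaks <- NULL
  if (!is.null(pca_model)) {
    peaks <- peak_pick(pca_model$loadings[, 1], grid)
  }

  table <- comparison_table(foms[methods[methods %in% names(foms)]])
  structure(list(
    fom_table = table,
    foms = foms,
    models = models,
    pca = pca_model,
    spa = spa_sel,
    peaks = peaks,
    split = split,
    centering = centering,
    preprocess = pp$config,
    awls_converged = pp$awls_converged,
    provenance = list(
      package_version = as.character(utils::packageVersion("serafir")),
      n_samples = nrow(samples), n_train = length(train_rows),
      n_test = length(test_rows), n_wavenumbers = length(grid),
      split_fraction = split_fraction, cv_folds = cv_folds,
      methods = methods, positive = positive,
      test_ids = samples$sample_id[test_rows],
      timings_s = timings, total_s = tic() - t0
    )
  ), class = "ftir_run")
}

# CV-accuracy selection of the number of leading score columns (PCA width).
.select_width <- function(scores, y, folds, widths, kind, svm_grid, positive) {
  acc <- vapply(widths, function(w) {
    Z <- scores[, seq_len(w), drop = FALSE]
    if (kind == "svm") {
      .quiet_tune(Z, y, folds, svm_grid, positive)$cv_accuracy
    } else {
      .cv_discriminant(Z, y, folds, kind)
    }
  }, numeric(1))
  best <- widths[order(-acc, widths)[1]]  # ties -> fewest components
  out <- list(width = best, cv_accuracy = max(acc))
  if (kind == "svm") {
    tuned <- .quiet_tune(scores[, seq_len(best), drop = FALSE], y, folds,
                         svm_grid, positive)
    out$cost <- tuned$best_cost
    out$gamma <- tuned$best_gamma
  }
  out
}

# CV-accuracy selection among candidate SPA variable subsets (one per size).
.select_subset <- function(X, y, folds, cand_sets, kind, svm_grid, positive) {
  acc <- vapply(seq_along(cand_sets), function(i) {
    Z <- X[, cand_sets[[i]], drop = FALSE]
    if (kind == "svm") {
      .quiet_tune(Z, y, folds, svm_grid, positive)$cv_accuracy
    } else {
      .cv_discriminant(Z, y, folds, kind)
    }
  }, numeric(1))
  sizes <- lengths(cand_sets)
  best <- order(-acc, sizes)[1]            # ties -> fewest variables
  out <- list(which = best, cv_accuracy = max(acc))
  if (kind == "svm") {
    tuned <- .quiet_tune(X[, cand_sets[[best]], drop = FALSE], y, folds,
                         svm_grid, positive)
    out$cost <- tuned$best_cost
    out$gamma <- tuned$best_gamma
  }
  out
}

.cv_discriminant <- function(Z, y, folds, kind) {
  fold_acc <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- tryCatch(
      fit_discriminant(Z[tr, , drop = FALSE], y[tr], kind),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NA_real_)
    mean(predict(fit, Z[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  mean(fold_acc, na.rm = TRUE)
}

# tune_svm warns on degenerate folds; during the selection sweep those
# warnings would repeat per lattice point, so collect them once.
.quiet_tune <- function(Z, y, folds, grid, positive) {
  withCallingHandlers(
    tune_svm(Z, y, folds, grid, positive),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

.fit_final <- function(Z, y, kind, sel, positive) {
  if (kind == "svm") {
    list(model = fit_svm(Z, y, cost = sel$cost, gamma = sel$gamma,
                         positive = positive),
         cost = sel$cost, gamma = sel$gamma)
  } else {
    list(model = fit_discriminant(Z, y, kind))
  }
}

#' @export
print.ftir_run <- function(x, ...) {
  cat("<ftir_run>\n")
  cat(sprintf("  %d samples (%d train / %d test), %d wavenumbers\n",
              x$provenance$n_samples, x$provenance$n_train,
              x$provenance$n_test, x$provenance$n_wavenumbers))
  print(x$fom_table)
  if (!is.null(x$peaks) && nrow(x$peaks)) {
    cat("  PC1 loading peaks (cm^-1):",
        paste(x$peaks$wavenumber, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy / summarise a pipeline run
#'
#' `tidy()` returns the figures of merit in long form (one row per model and
#' merit); `glance()` returns the best model's row.
#'
#' @param x An `ftir_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ftir_run <- function(x, ...) {
  tidyr::pivot_longer(x$fom_table, cols = c("ac", "sens", "spec", "fs", "gs"),
                      names_to = "merit", values_to = "value")
}

#' @rdname tidy.ftir_run
#' @export
glance.ftir_run <- function(x, ...) {
  best <- x$fom_table[x$fom_table$best, ]
  tibble::tibble(best_model = best$model, ac = best$ac, sens = best$sens,
                 spec = best$spec, fs = best$fs, gs = best$gs,
                 n_train = x$provenance$n_train,
                 n_test = x$provenance$n_test)
}

#' @export
autoplot.ftir_run <- function(object, ...) {
  td <- tidy(object)
  td$merit <- factor(toupper(td$merit),
                     levels = c("AC", "SENS", "SPEC", "FS", "GS"))
  ggplot2::ggplot(td, ggplot2::aes(.data$model, .data$value,
                                   fill = .data$merit)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Percent", fill = "Merit") +
    ggplot2::theme_minimal()
}
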