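# Repeated stratified cross-validation, hold-out splits, the {T, k, R}
# grid search, and SMOTE augmentation.

# Stratified fold assignment: within each class, shuffled rows receive fold
# ids cyclically, bounding per-fold class imbalance to +/-1.
stratified_folds <- function(label, folds) {
  assignment <- integer(length(label))
  for (g in unique(label)) {
    idx <- sample(which(label == g))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

#' Repeated stratified cross-validation of a classifier
#'
#' Runs `repeats` independent stratified `folds`-fold cross-validations (one
#' derived seed per repeat). Confusion metrics are computed per held-out
#' fold; AUC and AUP are computed on the pooled held-out scores of each
#' repeat. The summary reports the mean and standard deviation of every
#' metric across folds x repeats (across repeats for the pooled areas).
#'
#' @param table Feature table with labels.
#' @param spec Classifier spec, see [classifier_specs()].
#' @param folds,repeats Cross-validation layout (default fivefold, 10
#'   repeats).
#' @param seed Integer seed driving all fold assignments.
#' @param ... Passed to [fit_classifier()] (`k`, `ridge`, `threshold`, ...).
#' @return A `cv_summary` tibble (`metric`, `mean`, `sd`) with the per-fold
#'   results in the `folds` attribute.
#' @export
#' @examples
#' tbl <- toy_feature_table(seed = 1)
#' repeated_stratified_cv(tbl, "knn", folds = 5, repeats = 2, seed = 1)
repeated_stratified_cv <- function(table, spec = "lwl-lr", folds = 5,
                                   repeats = 10, seed = 1, ...) {
  label <- check_labels(table$label)
  if (min(table(label)) < folds) {
    abort("each class must have at least `folds` rows",
          class = "tidybreathe_config")
  }
  fold_rows <- list()
  area_rows <- list()
  for (r in seq_len(repeats)) {
    assignment <- withr::with_seed(derive_seed(seed, r),
                                   stratified_folds(label, folds))
    scores <- numeric(nrow(table))
    for (f in seq_len(folds)) {
      test_idx <- which(assignment == f)
      fit <- fit_classifier(table[-test_idx, ], spec, ...)
      pr <- predict(fit, table[test_idx, ], type = "prob")
      scores[test_idx] <- pr
      pred <- as.integer(pr >= fit$threshold)
      cm <- confusion_metrics(label[test_idx], pred)
      fold_rows[[length(fold_rows) + 1]] <-
        dplyr::mutate(cm, repeat_idx = r, fold = f, .before = 1)
    }
    area_rows[[r]] <- rank_curve_areas(label, scores)
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  per_repeat <- dplyr::bind_rows(area_rows)

  long <- tidyr::pivot_longer(
    per_fold[, c("acc", "tpr", "tnr", "f", "kappa")],
    dplyr::everything(), names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  areas <- tibble::tibble(
    metric = c("auc", "aup"),
    mean = c(mean(per_repeat$auc), mean(per_repeat$aup)),
    sd = c(sd(per_repeat$auc), sd(per_repeat$aup)))
  out <- dplyr::bind_rows(summary, areas)
  out <- out[match(c("acc", "tpr", "tnr", "f", "kappa", "auc", "aup"),
                   out$metric), ]
  tibble::new_tibble(out, class = "cv_summary", spec = spec,
                     folds_detail = per_fold, repeats = repeats,
                     n = nrow(table))
}

#' Hold-out test-set size under the nearest-integer rule
#'
#' The test set holds `1/t` of the `n` instances, rounded to the nearest
#' integer with halves rounded up: for n = 60 and t = 2..7 this yields
#' 30, 20, 15, 12, 10, 9.
#'
#' @param n Total instance count.
#' @param t Reciprocal of the test fraction.
#' @return Integer test-set size.
#' @export
holdout_test_size <- function(n, t) as.integer(floor(n / t + 0.5))

#' Single stratified hold-out evaluation
#'
#' Splits off `1/t` of the rows ([holdout_test_size()]) as a stratified test
#' set, trains the classifier on the rest and returns the hold-out accuracy.
#'
#' @inheritParams repeated_stratified_cv
#' @param t Reciprocal of the test fraction (t >= 2).
#' @return Accuracy percentage on the held-out rows.
#' @export
holdout_eval <- function(table, spec = "lwl-lr", t = 5, seed = 1, ...) {
  label <- check_labels(table$label)
  n <- nrow(table)
  m <- holdout_test_size(n, t)
  if (t < 2 || m < 1 || m >= n) {
    abort("hold-out split leaves an empty test or training set",
          class = "tidybreathe_config")
  }
  n1 <- sum(label == 1)
  m1 <- min(max(as.integer(floor(m * n1 / n + 0.5)), 0L), m)
  m0 <- m - m1
  test_idx <- withr::with_seed(derive_seed(seed, t), {
    c(sample(which(label == 1), m1), sample(which(label == 0), m0))
  })
  if (length(unique(label[-test_idx])) < 2) {
    abort("training split lost a class", class = "tidybreathe_config")
  }
  fit <- fit_classifier(table[-test_idx, ], spec, ...)
  pred <- predict(fit, table[test_idx, ], type = "class")
  confusion_metrics(label[test_idx], pred)$acc
}

#' Grid search over test fraction, neighborhood size and ridge exponent
#'
#' Evaluates the locally weighted ridge-logistic classifier over the triplet
#' grid `{T, k, R} = (1/t, k, 10^-r)` by one stratified hold-out evaluation
#' per cell, all driven by a common base seed so cells with equal `t` share
#' their split.
#'
#' @param table Feature table with labels.
#' @param t_range,k_range,r_range Integer grids (defaults 2:7, 5:10, 3:8).
#' @param seed Base seed.
#' @return A `grid_result` tibble `t, k, r, accuracy_pct` with the argmax
#'   triplets in the `best` attribute.
#' @export
grid_search <- function(table, t_range = 2:7, k_range = 5:10, r_range = 3:8,
                        seed = 1) {
  grid <- tidyr::expand_grid(t = t_range, k = k_range, r = r_range)
  grid$accuracy_pct <- purrr::pmap_dbl(grid, function(t, k, r) {
    holdout_eval(table, "lwl-lr", t = t, seed = seed, k = k, ridge = 10^(-r))
  })
  best <- grid[grid$accuracy_pct == max(grid$accuracy_pct), ]
  tibble::new_tibble(grid, class = "grid_result", best = best, seed = seed)
}

#' SMOTE augmentation of a feature table
#'
#' For each class independently, repeats `n_new_per_class` times: draw a
#' random class row, draw one of its `k_smote` same-class nearest neighbors
#' (Euclidean on raw features), and emit the convex combination
#' `x + u (x_nb - x)` with `u ~ Uniform(0, 1)`. Output is the original rows
#' followed by the synthetic rows, flagged `synthetic = 1`.
#'
#' @param table Feature table with labels.
#' @param n_new_per_class Synthetic rows to add per class.
#' @param k_smote Neighbor pool size (each class needs `k_smote + 1` rows).
#' @param seed Integer seed.
#' @return Augmented feature table with a `synthetic` column.
#' @export
smote_augment <- function(table, n_new_per_class, k_smote = 5, seed = 1) {
  label <- check_labels(table$label)
  X <- feature_matrix(table)
  out <- dplyr::mutate(table, synthetic = 0L)
  if (n_new_per_class == 0) return(out)
  new_rows <- withr::with_seed(derive_seed(seed, 17L), {
    purrr::map(c(0L, 1L), function(g) {
      idx <- which(label == g)
      if (length(idx) < k_smote + 1) {
        abort(sprintf("class %d has %d rows; SMOTE needs k_smote + 1 = %d",
                      g, length(idx), k_smote + 1),
              class = "tidybreathe_config")
      }
      Xg <- X[idx, , drop = FALSE]
      purrr::map(seq_len(n_new_per_class), function(j) {
        i <- sample(length(idx), 1)
        d <- sqrt(colSums((t(Xg) - Xg[i, ])^2))
        d[i] <- Inf
        nb_pool <- order(d)[seq_len(k_smote)]
        nb <- nb_pool[sample(k_smote, 1)]
        u <- runif(1)
        synth <- Xg[i, ] + u * (Xg[nb, ] - Xg[i, ])
        row <- tibble::as_tibble(as.list(synth))
        dplyr::mutate(row,
                      subject_id = sprintf("syn%d_%03d", g, j),
                      trial = NA_integer_, label = g, synthetic = 1L,
                      .before = 1)
      })
    })
  })
  dplyr::bind_rows(out, dplyr::bind_rows(purrr::flatten(new_rows)))
}
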