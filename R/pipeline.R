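# End-to-end orchestration: simulate -> extract -> evaluate, with every
# output determined by a single top-level seed. Stages hand off via files so
# the command-line interface (inst/scripts/tidalbreathe.R) can drive them
# independently.

#' Default run configuration
#'
#' @return Nested list with `seed` and `simulate`/`preprocess`/`classifier`/
#'   `evaluate` blocks, each validated by the owning stage.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_per_class = 10, trials = 3, duration_s = 60, fs = 100,
                    separation = 1),
    preprocess = list(smooth_window_s = 0.05, hysteresis_frac = 0.05,
                      min_phase_s = 0.25),
    classifier = list(spec = "lwl-lr", k = 5, ridge = 1e-3, threshold = 0.5),
    evaluate = list(folds = 5, repeats = 10, confidence = 0.99,
                    grid = FALSE, smote = 0, friedman = FALSE)
  )
}

# Merge a partial user config (e.g. from YAML) over the defaults.
merge_config <- function(config = list()) {
  base <- default_config()
  for (blk in names(base)) {
    if (blk %in% names(config)) {
      if (is.list(base[[blk]])) {
        base[[blk]][names(config[[blk]])] <- config[[blk]]
      } else {
        base[[blk]] <- config[[blk]]
      }
    }
  }
  base
}

#' Simulate a cohort and write it to disk
#'
#' @param config Run configuration (see [default_config()]); partial lists
#'   are merged over the defaults.
#' @param out_dir Output directory for the flow CSVs and manifest.
#' @return Invisibly, the manifest path.
#' @export
cmd_simulate <- function(config = list(), out_dir = ".") {
  cfg <- merge_config(config)
  s <- cfg$simulate
  cohort <- synth_cohort(n_per_class = s$n_per_class, trials = s$trials,
                         duration_s = s$duration_s, fs = s$fs,
                         separation = s$separation, seed = cfg$seed)
  path <- write_cohort(cohort, out_dir)
  message(sprintf("simulate: wrote %d flow records (seed %d) to %s",
                  nrow(cohort), cfg$seed, out_dir))
  invisible(path)
}

#' Extract the feature table from a cohort on disk
#'
#' @param manifest_path Manifest CSV written by [cmd_simulate()] /
#'   [write_cohort()].
#' @param config Run configuration.
#' @param out_file Output feature CSV path.
#' @return Invisibly, the feature table.
#' @export
cmd_extract <- function(manifest_path, config = list(),
                        out_file = "features.csv") {
  cfg <- merge_config(config)
  cohort <- read_cohort(manifest_path)
  pp <- cfg$preprocess
  table <- build_feature_table(cohort, smooth_window_s = pp$smooth_window_s,
                               hysteresis_frac = pp$hysteresis_frac,
                               min_phase_s = pp$min_phase_s)
  write.csv(table, out_file, row.names = FALSE)
  dropped <- attr(table, "dropped")
  message(sprintf("extract: %d feature rows -> %s (%d record(s) dropped)",
                  nrow(table), out_file, length(dropped)))
  invisible(table)
}

#' Evaluate the classifier family on a feature table
#'
#' Runs repeated stratified cross-validation for every classifier spec,
#' optionally the `{T, k, R}` grid search, a SMOTE-augmented rerun of the
#' tuned classifier, and the Friedman rank comparison over per-subject
#' accuracies.
#'
#' @param features Feature table, or path to a feature CSV.
#' @param config Run configuration.
#' @param out_dir Directory for result CSV/JSON files (`NULL` = don't write).
#' @return List with `cv` (per-spec metric summaries), and optionally
#'   `grid`, `smote_cv`, `friedman`, `fld`.
#' @export
cmd_evaluate <- function(features, config = list(), out_dir = NULL) {
  cfg <- merge_config(config)
  ev <- cfg$evaluate
  cl <- cfg$classifier
  table <- if (is.character(features)) {
    tibble::as_tibble(read.csv(features))
  } else features

  cv <- purrr::map(rlang::set_names(classifier_specs()), function(spec) {
    repeated_stratified_cv(table, spec, folds = ev$folds,
                           repeats = ev$repeats, seed = cfg$seed,
                           k = cl$k, threshold = cl$threshold)
  })
  out <- list(cv = cv, config = cfg,
              version = as.character(utils::packageVersion("tidybreathe")))

  if (isTRUE(ev$grid)) {
    out$grid <- grid_search(table, seed = cfg$seed)
  }
  if (ev$smote > 0) {
    aug <- smote_augment(table, n_new_per_class = ev$smote, seed = cfg$seed)
    out$smote_cv <- repeated_stratified_cv(
      aug[, setdiff(names(aug), "synthetic")], cl$spec, folds = ev$folds,
      repeats = ev$repeats, seed = cfg$seed, k = cl$k, ridge = cl$ridge)
  }
  if (isTRUE(ev$friedman)) {
    out$friedman <- friedman_compare(table, folds = ev$folds,
                                     seed = cfg$seed, k = cl$k,
                                     ridge = cl$ridge,
                                     confidence = ev$confidence)
  }
  out$fld <- fld_project(table)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (spec in names(cv)) {
      write.csv(cv[[spec]],
                file.path(out_dir, paste0("cv_", gsub("-", "_", spec), ".csv")),
                row.names = FALSE)
    }
    if (!is.null(out$grid)) {
      write.csv(out$grid, file.path(out_dir, "grid.csv"), row.names = FALSE)
    }
    if (!is.null(out$friedman)) {
      fr <- out$friedman
      writeLines(sprintf(
        '{"chi2_f": %.6f, "df": %d, "critical": %.4f, "reject": %s, "mean_ranks": [%s]}',
        fr$chi2_f, fr$df, fr$critical, tolower(fr$reject),
        paste(sprintf("%.4f", fr$mean_ranks), collapse = ", ")),
        file.path(out_dir, "friedman.json"))
    }
    message(sprintf("evaluate: results written to %s", out_dir))
  }
  invisible(out)
}

#' Rank the classifier family per subject and run the Friedman test
#'
#' Builds the N x d accuracy matrix the Friedman comparison needs: for each
#' subject, its trials are held out, each classifier is trained on the
#' remaining rows, and the subject's hold-out accuracy is recorded; the
#' classifiers are then compared by [friedman_test()] over subjects.
#'
#' @param table Feature table with `subject_id` and labels.
#' @param specs Classifier specs to compare (default all five).
#' @param folds Unused placeholder for config symmetry.
#' @param seed Integer seed (classifiers here are deterministic given data).
#' @param k,ridge Classifier settings.
#' @param confidence Confidence level for the critical value.
#' @return A `friedman_rank_test` with the accuracy matrix in attribute
#'   `accuracy_matrix`.
#' @export
friedman_compare <- function(table, specs = classifier_specs(), folds = 5,
                             seed = 1, k = 5, ridge = 1e-3,
                             confidence = 0.99) {
  subjects <- unique(table$subject_id)
  acc <- matrix(NA_real_, length(subjects), length(specs),
                dimnames = list(subjects, specs))
  for (i in seq_along(subjects)) {
    test_idx <- which(table$subject_id == subjects[i])
    train <- table[-test_idx, ]
    for (j in seq_along(specs)) {
      fit <- fit_classifier(train, specs[j], k = k, ridge = ridge)
      pred <- predict(fit, table[test_idx, ], type = "class")
      acc[i, j] <- mean(pred == table$label[test_idx]) * 100
    }
  }
  res <- friedman_test(acc, confidence = confidence)
  attr(res, "accuracy_matrix") <- acc
  res
}

#' Run the whole pipeline under one seed
#'
#' simulate -> extract -> evaluate, writing all intermediate and final files
#' under `out_dir`.
#'
#' @param config Run configuration (partial lists merged over
#'   [default_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the evaluation result list.
#' @export
run_pipeline <- function(config = list(), out_dir = "tidybreathe_run") {
  cfg <- merge_config(config)
  cohort_dir <- file.path(out_dir, "cohort")
  manifest <- cmd_simulate(cfg, cohort_dir)
  features <- cmd_extract(manifest, cfg, file.path(out_dir, "features.csv"))
  invisible(cmd_evaluate(features, cfg, file.path(out_dir, "results")))
}
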