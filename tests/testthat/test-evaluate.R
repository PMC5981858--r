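# Metrics, ranking areas, resampling, SMOTE, Friedman test, FLD.

test_that("confusion metrics match hand-evaluated formulas", {
  y_true <- c(rep(1, 50), rep(0, 50))
  y_pred <- c(rep(1, 40), rep(0, 10), rep(1, 5), rep(0, 45))
  m <- confusion_metrics(y_true, y_pred)
  expect_equal(m$acc, 85.0)
  expect_equal(m$tpr, 0.80)
  expect_equal(m$tnr, 0.90)
  expect_equal(m$kappa, 0.70)
  expect_identical(c(m$tp, m$fn, m$fp, m$tn), c(40L, 10L, 5L, 45L))
  # identities recomputed from the stored counts
  expect_equal(m$acc, 100 * (m$tp + m$tn) / m$n)
  expect_equal(m$tpr, m$tp / (m$tp + m$fn))
  expect_equal(m$tnr, m$tn / (m$tn + m$fp))

  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$f, 1)

  constant <- confusion_metrics(c(1, 0, 1, 0), c(1, 1, 1, 1))
  expect_equal(constant$kappa, 0)
  expect_error(confusion_metrics(integer(0), integer(0)),
               class = "tidybreathe_domain")
})

test_that("AUC equals pairwise concordance; AUP behaves at the extremes", {
  r <- rank_curve_areas(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$auc, 0.75)   # 3 of 4 pairs concordant

  sep <- rank_curve_areas(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1.0)
  expect_equal(sep$aup, 1.0)

  ties <- rank_curve_areas(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(ties$auc, 0.5)

  expect_error(rank_curve_areas(c(1, 1), c(0.2, 0.4)),
               class = "tidybreathe_domain")

  # brute-force pairwise oracle on random score vectors
  set.seed(31)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)    # rounding forces ties
    pos <- s[y == 1]; neg <- s[y == 0]
    conc <- 0
    for (a in pos) for (b in neg) conc <- conc + (a > b) + 0.5 * (a == b)
    expect_equal(rank_curve_areas(y, s)$auc, conc / (length(pos) * length(neg)))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(40)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(rank_curve_areas(y, s)$auc, ref, tolerance = 1e-12)
})

test_that("stratified CV partitions rows correctly and is deterministic", {
  tbl <- cached_toy_table()    # 20 rows, 10 per class
  cv1 <- repeated_stratified_cv(tbl, "knn", folds = 5, repeats = 3, seed = 2)
  cv2 <- repeated_stratified_cv(tbl, "knn", folds = 5, repeats = 3, seed = 2)
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))

  detail <- attr(cv1, "folds_detail")
  per_fold_n <- tapply(detail$n, list(detail$repeat_idx, detail$fold), sum)
  expect_true(all(detail$n == 4))                   # 20 rows / 5 folds
  expect_true(all(detail$tp + detail$fn == 2))      # 2 positives per fold
  # every row tested exactly once per repeat
  expect_true(all(rowSums(per_fold_n, na.rm = TRUE) == 20))

  expect_error(repeated_stratified_cv(tbl, "knn", folds = 11),
               class = "tidybreathe_config")
})

test_that("a chance-level classifier scores near 50% on a balanced table", {
  set.seed(44)
  n <- 30
  junk <- tibble::as_tibble(matrix(rnorm(n * 12), n,
                                   dimnames = list(NULL, feature_names())))
  junk$label <- rep(c(0, 1), each = n / 2)
  junk$subject_id <- sprintf("J%02d", seq_len(n))
  junk$trial <- 1L
  cv <- repeated_stratified_cv(junk, "knn", folds = 5, repeats = 4, seed = 3)
  acc <- cv$mean[cv$metric == "acc"]
  expect_gt(acc, 25)
  expect_lt(acc, 75)
})

test_that("hold-out sizing reproduces the printed test-set sequence", {
  expect_identical(sapply(2:7, function(t) holdout_test_size(60, t)),
                   c(30L, 20L, 15L, 12L, 10L, 9L))
  acc <- holdout_eval(cached_toy_table(), "lwl-lr", t = 2, seed = 1)
  expect_gte(acc, 90)   # separable synthetic classes
})

test_that("grid search covers the full triplet grid and finds separable optima", {
  tbl <- cached_toy_table()
  g <- grid_search(tbl, t_range = 2:3, k_range = 5:6, r_range = 3:4, seed = 1)
  expect_identical(nrow(g), 8L)
  expect_identical(nrow(unique(g[, c("t", "k", "r")])), 8L)
  expect_gte(max(g$accuracy_pct), 90)
  best <- attr(g, "best")
  expect_true(all(best$accuracy_pct == max(g$accuracy_pct)))
})

test_that("SMOTE grows classes as requested with convex synthetic rows", {
  tbl <- cached_toy_table()
  aug <- smote_augment(tbl, n_new_per_class = 7, seed = 5)
  expect_identical(nrow(aug), nrow(tbl) + 14L)
  expect_identical(sum(aug$synthetic), 14L)
  expect_identical(as.integer(table(aug$label)), c(17L, 17L))

  X <- as.matrix(tbl[feature_names()])
  for (i in which(aug$synthetic == 1)) {
    s <- as.numeric(aug[i, feature_names()])
    g <- aug$label[i]
    Xg <- X[tbl$label == g, , drop = FALSE]
    ok <- FALSE
    for (a in seq_len(nrow(Xg))) {
      for (b in seq_len(nrow(Xg))) {
        if (a == b) next
        dir <- Xg[b, ] - Xg[a, ]
        j <- which.max(abs(dir))
        if (dir[j] == 0) next
        u <- (s[j] - Xg[a, j]) / dir[j]
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(Xg[a, ] + u * dir - s)) < 1e-8) {
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    expect_true(ok)
  }

  expect_identical(smote_augment(tbl, 0)$synthetic, rep(0L, nrow(tbl)))
  # class 0 keeps only 3 rows: fewer than the k_smote + 1 SMOTE needs
  expect_error(smote_augment(tbl[c(1:3, 11:20), ], 3),
               class = "tidybreathe_config")
})

test_that("Friedman statistic matches hand evaluation and stats::friedman.test", {
  # identical ordering on every dataset: mean ranks 1, 2, 3
  m <- rbind(c(3, 2, 1), c(30, 20, 10), c(0.9, 0.5, 0.1))
  fr <- friedman_test(m)
  expect_equal(fr$chi2_f, 6.0)
  expect_equal(unname(fr$mean_ranks), c(1, 2, 3))

  # identical accuracies: all ranks tie at (d+1)/2
  fr0 <- friedman_test(matrix(5, 4, 3))
  expect_equal(fr0$chi2_f, 0)
  expect_false(fr0$reject)

  # rank-only: any monotone transformation leaves the statistic unchanged
  set.seed(9)
  a <- matrix(runif(60), 12, 5)
  expect_equal(friedman_test(exp(3 * a))$chi2_f, friedman_test(a)$chi2_f)

  # independent implementation (tie-free by construction)
  ref <- friedman.test(a)
  expect_equal(friedman_test(a)$chi2_f, unname(ref$statistic),
               tolerance = 1e-12)
  expect_identical(friedman_test(a)$df, as.integer(ref$parameter))
})

test_that("the critical value is the chi-square quantile at the configured confidence", {
  fr <- friedman_test(matrix(runif(80), 20, 4), confidence = 0.99)
  expect_equal(fr$critical, qchisq(0.99, 3))
  expect_equal(round(fr$critical, 2), 11.34)
})

test_that("FLD recovers the closed-form direction for isotropic classes", {
  # exactly isotropic 2-D scatter: S_W proportional to I, means (0,0)/(1,0),
  # so the discriminant direction is exactly (1, 0)
  pts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  X <- rbind(pts, sweep(pts, 2, c(1, 0), "+"))
  n <- 4
  tbl <- tibble::as_tibble(matrix(0, 2 * n, 12,
                                  dimnames = list(NULL, feature_names())))
  tbl$ti_s <- X[, 1]; tbl$te_s <- X[, 2]
  tbl$label <- rep(c(0, 1), each = n)
  f <- fld_project(tbl)
  expect_equal(f$direction[["ti_s"]], 1, tolerance = 1e-6)
  expect_equal(f$direction[["te_s"]], 0, tolerance = 1e-6)
  # sign convention: smokers project higher
  expect_gt(mean(f$projections$projection[tbl$label == 1]),
            mean(f$projections$projection[tbl$label == 0]))
  # and under noisy isotropic sampling the direction is still dominated by
  # the mean-difference axis
  set.seed(14)
  m <- 200
  tbl2 <- tibble::as_tibble(matrix(0, 2 * m, 12,
                                   dimnames = list(NULL, feature_names())))
  tbl2$ti_s <- c(rnorm(m), 1 + rnorm(m)); tbl2$te_s <- rnorm(2 * m)
  tbl2$label <- rep(c(0, 1), each = m)
  f2 <- fld_project(tbl2)
  expect_gt(abs(f2$direction[["ti_s"]]), 0.95)

  # well-separated clusters separate perfectly
  tbl$ti_s <- tbl$ti_s + 20 * tbl$label
  g <- fld_project(tbl)
  expect_gt(min(g$projections$projection[tbl$label == 1]),
            max(g$projections$projection[tbl$label == 0]))

  # identical class means: regularized direction, near-zero separation
  set.seed(15)
  tbl$ti_s <- rep(rnorm(n), 2)[seq_len(2 * n)]
  tbl$te_s <- 2 * tbl$ti_s          # singular within-class scatter
  h <- fld_project(tbl)
  expect_true(all(is.finite(h$direction)))
  expect_error(fld_project(tbl[tbl$label == 1, ]),
               class = "tidybreathe_domain")
})

test_that("autoplot methods return ggplot objects", {
  tbl <- cached_toy_table()
  expect_s3_class(autoplot(fld_project(tbl)), "ggplot")
  g <- grid_search(tbl, 2:3, 5:5, 3:3, seed = 1)
  expect_s3_class(autoplot(g), "ggplot")
  cv <- repeated_stratified_cv(tbl, "knn", folds = 5, repeats = 2, seed = 1)
  expect_s3_class(autoplot(cv), "ggplot")
  seg <- segment_record(sine_flow(duration = 12), 100)
  expect_s3_class(plot_flow(seg$flow, seg$cycles, 100), "ggplot")
})

test_that("tidy and glance methods give tibble views of fits", {
  tbl <- cached_toy_table()
  fit <- fit_weighted_logistic_ridge(as.matrix(tbl[feature_names()]),
                                     tbl$label, R = 1e-3)
  td <- tidy(fit)
  expect_identical(nrow(td), 13L)
  expect_identical(td$term[1], "(Intercept)")
  expect_true(glance(fit)$converged)

  fr <- friedman_test(matrix(runif(40), 10, 4))
  expect_identical(nrow(tidy(fr)), 4L)
  expect_identical(glance(fr)$df, 3L)
})
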