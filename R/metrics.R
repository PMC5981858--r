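# Classification metrics, ranking-curve areas, the Friedman rank test and
# Fisher's linear discriminant projection. Positive class = smoker (label 1).

#' Confusion-matrix metrics
#'
#' Accuracy (percent), sensitivity/specificity (TPR/TNR), support-weighted
#' two-class F measure (per-class F1 also returned) and Cohen's kappa, all
#' from the 2x2 confusion counts with smokers (label 1) as the positive
#' class. When expected chance agreement is 1, kappa is 0 by convention.
#'
#' @param y_true,y_pred Binary label vectors of equal length.
#' @return One-row tibble: `acc`, `tpr`, `tnr`, `f`, `f_pos`, `f_neg`,
#'   `kappa`, `tp`, `fn`, `fp`, `tn`, `n`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
confusion_metrics <- function(y_true, y_pred) {
  n <- length(y_true)
  if (n == 0 || length(y_pred) != n) {
    abort("`y_true` and `y_pred` must be equal-length, non-empty",
          class = "tidybreathe_domain")
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  prec_pos <- safe_div(tp, tp + fp)
  prec_neg <- safe_div(tn, tn + fn)
  f1 <- function(prec, rec) {
    if (is.na(prec) || is.na(rec) || prec + rec == 0) return(0)
    2 * prec * rec / (prec + rec)
  }
  f_pos <- f1(prec_pos, tpr)
  f_neg <- f1(prec_neg, tnr)
  n_pos <- tp + fn
  n_neg <- tn + fp
  f <- (n_pos * f_pos + n_neg * f_neg) / n
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(acc = 100 * p_o, tpr = tpr, tnr = tnr, f = f,
                 f_pos = f_pos, f_neg = f_neg, kappa = kappa,
                 tp = tp, fn = fn, fp = fp, tn = tn, n = n)
}

#' Areas under the ROC and precision-recall curves
#'
#' AUC is the tie-corrected Mann-Whitney statistic (equivalently the
#' trapezoidal ROC area); AUP is the trapezoidal area under the
#' precision-recall curve over the distinct score thresholds.
#'
#' @param y_true Binary labels; both classes must be present.
#' @param scores Numeric scores (higher = more smoker-like).
#' @return One-row tibble with `auc` and `aup`.
#' @export
rank_curve_areas <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present to compute ranking areas",
          class = "tidybreathe_domain")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # precision-recall curve over distinct thresholds, descending
  ord <- order(scores, decreasing = TRUE)
  ys <- y_true[ord]
  ss <- scores[ord]
  cum_tp <- cumsum(ys)
  cum_fp <- cumsum(1 - ys)
  keep <- c(diff(ss) != 0, TRUE)     # last index of each distinct score
  tp <- cum_tp[keep]
  fp <- cum_fp[keep]
  recall <- c(0, tp / n1)
  precision <- c(1, tp / (tp + fp))
  aup <- sum(diff(recall) * (head(precision, -1) + tail(precision, -1)) / 2)
  tibble::tibble(auc = auc, aup = aup)
}

#' Friedman rank test for comparing classifiers across datasets
#'
#' Ranks the `d` algorithms within each of the `N` datasets (rank 1 = highest
#' accuracy, ties share the average rank) and computes the Friedman statistic
#' `chi2_F = 12 N / (d (d + 1)) * (sum_j R_j^2 - d (d + 1)^2 / 4)` on the mean
#' ranks `R_j`, referred to a chi-square distribution with `d - 1` degrees of
#' freedom.
#'
#' @param accuracy_matrix Numeric N x d matrix: rows = datasets, columns =
#'   algorithms.
#' @param confidence Confidence level for the critical value (default 0.99).
#' @return A `friedman_rank_test`: list with `chi2_f`, `d`, `n_datasets`,
#'   `mean_ranks`, `df`, `critical`, `reject`.
#' @export
#' @examples
#' acc <- cbind(a = c(90, 85, 88), b = c(80, 80, 79), c = c(70, 75, 71))
#' friedman_test(acc)
friedman_test <- function(accuracy_matrix, confidence = 0.99) {
  m <- as.matrix(accuracy_matrix)
  if (anyNA(m)) abort("accuracy matrix has missing cells",
                      class = "tidybreathe_domain")
  n <- nrow(m)
  d <- ncol(m)
  if (n < 2 || d < 2) {
    abort("need at least 2 datasets and 2 algorithms",
          class = "tidybreathe_domain")
  }
  ranks <- t(apply(-m, 1, rank, ties.method = "average"))
  mean_ranks <- colMeans(ranks)
  chi2_f <- 12 * n / (d * (d + 1)) * (sum(mean_ranks^2) - d * (d + 1)^2 / 4)
  df <- d - 1L
  critical <- qchisq(confidence, df)
  structure(
    list(chi2_f = chi2_f, d = d, n_datasets = n, mean_ranks = mean_ranks,
         df = df, confidence = confidence, critical = critical,
         reject = chi2_f > critical),
    class = "friedman_rank_test"
  )
}

#' @export
print.friedman_rank_test <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: chi2_F = %.3f on %d df (N = %d datasets, d = %d algorithms)\n",
    x$chi2_f, x$df, x$n_datasets, x$d))
  cat(sprintf("critical value at %.0f%% confidence: %.2f -> %s H0 of equal performance\n",
              100 * x$confidence, x$critical,
              if (x$reject) "reject" else "do not reject"))
  cat("mean ranks (1 = best):\n")
  print(round(x$mean_ranks, 3))
  invisible(x)
}

#' @export
tidy.friedman_rank_test <- function(x, ...) {
  tibble::tibble(
    algorithm = names(x$mean_ranks) %||% paste0("alg", seq_along(x$mean_ranks)),
    mean_rank = unname(x$mean_ranks)
  )
}

#' @export
glance.friedman_rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi2_f, df = x$df, critical = x$critical,
                 confidence = x$confidence, reject = x$reject,
                 n_datasets = x$n_datasets, n_algorithms = x$d)
}

#' Fisher's linear discriminant projection to one dimension
#'
#' Projects the 12-dimensional feature set onto the direction
#' `S_W^-1 (mu_1 - mu_0)` (within-class scatter `S_W`, regularized by
#' `lambda I` with `lambda = 1e-9 tr(S_W)/p` when singular), normalized to
#' unit length with the sign chosen so the smoker mean projects higher.
#'
#' @param table Feature table with both classes.
#' @return An `fld_projection`: list with `direction` (unit vector over
#'   [feature_names()]) and `projections` (input identifiers, labels and
#'   projection scalars).
#' @export
fld_project <- function(table) {
  X <- feature_matrix(table)
  y <- check_labels(table$label)
  if (min(table(y)) < 2) {
    abort("need at least 2 rows per class", class = "tidybreathe_domain")
  }
  p <- ncol(X)
  sw <- matrix(0, p, p)
  mu <- list()
  for (g in c(0, 1)) {
    Xg <- X[y == g, , drop = FALSE]
    mu[[as.character(g)]] <- colMeans(Xg)
    Xc <- sweep(Xg, 2, colMeans(Xg))
    sw <- sw + crossprod(Xc)
  }
  delta <- mu[["1"]] - mu[["0"]]
  w <- tryCatch(solve(sw, delta), error = function(e) {
    lambda <- 1e-9 * sum(diag(sw)) / p
    if (lambda == 0) lambda <- 1e-9
    solve(sw + diag(lambda, p), delta)
  })
  nw <- sqrt(sum(w^2))
  # identical class means: any direction is stationary; report an equal-loading
  # unit vector so the projection is defined (and separates nothing)
  w <- if (nw == 0) rep(1 / sqrt(p), p) else w / nw
  proj <- drop(X %*% w)
  if (mean(proj[y == 1]) < mean(proj[y == 0])) {
    w <- -w
    proj <- -proj
  }
  names(w) <- feature_names()
  keep <- intersect(c("subject_id", "trial", "label"), names(table))
  structure(
    list(direction = w,
         projections = dplyr::bind_cols(table[, keep],
                                        tibble::tibble(projection = proj))),
    class = "fld_projection"
  )
}

#' @export
print.fld_projection <- function(x, ...) {
  cat("Fisher linear discriminant projection\n")
  cat("direction (unit norm):\n")
  print(round(x$direction, 4))
  invisible(x)
}
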