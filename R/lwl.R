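# Locally weighted learning with ridge-penalized local logistic regression.
#
# The classifier is lazy: training stores the feature table verbatim. For a
# query it (1) finds the k nearest training rows by Euclidean distance on the
# raw, unnormalized features, (2) weights them with a linear kernel whose
# bandwidth is the (k+1)-th neighbor distance, and (3) fits a locally weighted
# logistic regression with an L2 (ridge) penalty of strength R on the slopes
# by iteratively reweighted least squares, predicting the smoker probability
# at the query. Working on raw features is the method's premise: neighbors of
# a subject share a similar lung capacity, so no global normalization is
# applied anywhere in the pipeline.

#' Numerically stable logistic link
#'
#' `logistic_link(t) = exp(t) / (1 + exp(t))`, evaluated without overflow for
#' any finite `t`.
#'
#' @param t Numeric vector of linear predictors.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' logistic_link(0)      # 0.5
#' logistic_link(c(-30, 30))
logistic_link <- function(t) {
  out <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  out[pos] <- 1 / (1 + exp(-t[pos]))
  et <- exp(t[!pos])
  out[!pos] <- et / (1 + et)
  out[is.na(t)] <- NA_real_
  out
}

# Penalized weighted log-likelihood: sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)]
# - R * ||slopes||^2, with the linear predictor clipped to +/-clip.
penalized_loglik <- function(beta, Xa, y, w, R, clip = 30) {
  lp <- clamp(drop(Xa %*% beta), -clip, clip)
  p <- clamp(logistic_link(lp), 1e-12, 1 - 1e-12)
  sum(w * (y * log(p) + (1 - y) * log1p(-p))) - R * sum(beta[-1]^2)
}

#' Fit a weighted logistic regression with ridge-penalized slopes
#'
#' Maximizes the locality-weighted log-likelihood minus `R * ||slopes||^2`
#' (the intercept is not penalized) by iteratively reweighted least squares
#' with step halving. Linear predictors are clipped to +/-30 throughout.
#' Singular inner systems (possible when `R = 0` and n < p + 1, or under
#' complete separation) fall back to a pseudo-inverse (minimum-norm) Newton
#' step and are flagged in the result.
#'
#' @param X Design matrix, n x p, raw feature units (no intercept column).
#' @param y Binary responses in \{0, 1\}.
#' @param w Positive observation weights (recycled if length 1).
#' @param R Ridge penalty on the slopes, >= 0.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `max(abs(delta beta))`.
#' @return A `ridge_logistic_fit`: list with `intercept`, `slopes`,
#'   `objective` (the penalized log-likelihood), `iterations`, `converged`,
#'   and `singular` (whether the pseudo-inverse fallback was used).
#' @export
fit_weighted_logistic_ridge <- function(X, y, w = 1, R = 0,
                                        max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  y <- as.numeric(y)
  w <- rep_len(as.numeric(w), n)
  stopifnot(length(y) == n, all(w > 0), R >= 0, n >= 1)
  clip <- 30

  Xa <- cbind(1, X)
  pen <- c(0, rep(1, p))          # intercept unpenalized
  beta <- numeric(p + 1)
  obj <- penalized_loglik(beta, Xa, y, w, R, clip)
  singular <- FALSE
  converged <- FALSE
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    lp <- clamp(drop(Xa %*% beta), -clip, clip)
    pr <- clamp(logistic_link(lp), 1e-12, 1 - 1e-12)
    grad <- drop(crossprod(Xa, w * (y - pr))) - 2 * R * pen * beta
    W <- pmax(w * pr * (1 - pr), 1e-12)
    H <- crossprod(Xa, Xa * W) + diag(2 * R * pen, p + 1)
    delta <- tryCatch(solve(H, grad), error = function(e) {
      singular <<- TRUE
      drop(MASS::ginv(H) %*% grad)
    })
    # step halving keeps the penalized likelihood non-decreasing
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_obj <- penalized_loglik(cand, Xa, y, w, R, clip)
      if (cand_obj >= obj - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    if (cand_obj > obj) {
      beta <- cand
      obj <- cand_obj
    } else {
      converged <- TRUE
      break
    }
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }

  structure(
    list(intercept = beta[1], slopes = beta[-1], objective = obj,
         iterations = iter, converged = converged, singular = singular,
         ridge = R, n = n),
    class = "ridge_logistic_fit"
  )
}

#' @export
print.ridge_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Ridge-penalized logistic fit (R = %g, n = %d): objective %.4f after %d IRLS iteration(s)%s\n",
    x$ridge, x$n, x$objective, x$iterations,
    if (x$singular) " [pseudo-inverse fallback]" else ""))
  print(c(intercept = x$intercept, x$slopes))
  invisible(x)
}

#' Predict probabilities from a ridge-logistic fit
#'
#' @param object A `ridge_logistic_fit`.
#' @param newdata Matrix or data frame of predictors (raw feature units).
#' @param ... Unused.
#' @return Vector of probabilities (linear predictor clipped to +/-30).
#' @export
predict.ridge_logistic_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  lp <- clamp(drop(object$intercept + X %*% object$slopes), -30, 30)
  logistic_link(lp)
}

#' k-nearest neighborhood with linear locality weights
#'
#' Euclidean distance on raw features; ties broken by lower training-row
#' index. Weights are `1 - d_i / h` with bandwidth `h` equal to the
#' (k+1)-th nearest distance (or `1.1 * d_k` when the query exhausts the
#' training set); if `h = 0` (all neighbors coincide with the query) the
#' weights are uniform. Weights are floored at a tiny positive value so
#' boundary ties never receive zero weight.
#'
#' @param train_X Training matrix, n x p.
#' @param query Numeric vector of length p.
#' @param k Neighborhood size.
#' @param kernel `"linear"` (default), `"tricube"` or `"uniform"`.
#' @return List with `indices`, `distances` (non-decreasing) and `weights`.
#' @export
knn_neighborhood <- function(train_X, query, k, kernel = "linear") {
  train_X <- as.matrix(train_X)
  n <- nrow(train_X)
  if (n < k) {
    abort(sprintf("need at least k = %d training rows, have %d", k, n),
          class = "tidybreathe_config")
  }
  d <- sqrt(colSums((t(train_X) - as.numeric(query))^2))
  ord <- order(d)                  # radix order: ties keep index order
  idx <- ord[seq_len(k)]
  dk <- d[idx]
  h <- if (n > k) d[ord[k + 1]] else 1.1 * dk[k]
  if (h == 0) {
    w <- rep(1, k)
  } else {
    u <- dk / h
    w <- switch(kernel,
      linear = 1 - u,
      tricube = (1 - pmin(u, 1)^3)^3,
      uniform = rep(1, k),
      abort(paste0("unknown kernel: ", kernel), class = "tidybreathe_config")
    )
    w <- pmax(w, 1e-9)
  }
  list(indices = idx, distances = dk, weights = w)
}

#' Build a locally weighted learning classifier
#'
#' A lazy learner: stores the training feature table verbatim together with
#' its configuration. `ridge = 0` gives the ordinary-logistic variant
#' (LWL+L-O); the default `ridge = 1e-3` with `k = 5` is the tuned
#' ridge-logistic variant (LWL+L-R).
#'
#' @param train Feature table with a `label` column and the columns of
#'   [feature_names()].
#' @param k Neighborhood size.
#' @param ridge Ridge penalty R on the local slopes.
#' @param kernel Locality kernel, see [knn_neighborhood()].
#' @param threshold Decision probability; probability >= threshold is
#'   classified as smoker (class 1).
#' @return An `lwl_model`.
#' @export
#' @examples
#' tbl <- toy_feature_table(seed = 1)
#' fit <- lwl(tbl, k = 5, ridge = 1e-3)
#' predict(fit, tbl[1:3, ], type = "prob")
lwl <- function(train, k = 5, ridge = 1e-3, kernel = "linear", threshold = 0.5) {
  stopifnot(k >= 1, ridge >= 0, threshold > 0, threshold < 1)
  X <- feature_matrix(train)
  y <- check_labels(train$label)
  if (nrow(X) < k) {
    abort("fewer training rows than k", class = "tidybreathe_config")
  }
  structure(
    list(train = train, X = X, y = y,
         config = list(k = k, ridge = ridge, kernel = kernel,
                       threshold = threshold)),
    class = "lwl_model"
  )
}

# Local fit at one query. The design is centered at the query, so the fitted
# intercept is the linear predictor there. For R = 0 the (often
# underdetermined) likelihood is solved in bandwidth-scaled coordinates: the
# same maximum-likelihood problem by affine equivariance, but the minimum-norm
# Newton fallback then picks a canonical solution that is invariant under a
# common rescaling of all features. For R > 0 the slope penalty is defined in
# raw feature units, so no scaling is applied.
lwl_local_fit <- function(model, query) {
  cfg <- model$config
  nb <- knn_neighborhood(model$X, query, cfg$k, cfg$kernel)
  Xc <- sweep(model$X[nb$indices, , drop = FALSE], 2, as.numeric(query))
  scale_h <- 1
  if (cfg$ridge == 0) {
    h <- max(nb$distances)
    if (h == 0) h <- 1
    scale_h <- h
  }
  fit <- fit_weighted_logistic_ridge(Xc / scale_h, model$y[nb$indices],
                                     w = nb$weights, R = cfg$ridge)
  list(fit = fit, neighborhood = nb,
       prob = logistic_link(clamp(fit$intercept, -30, 30)))
}

#' Predict from a locally weighted learning model
#'
#' @param object An `lwl_model`.
#' @param newdata Feature table (or matrix) of query rows.
#' @param type `"prob"` for smoker probabilities, `"class"` for 0/1 labels
#'   (probability >= threshold maps to 1).
#' @param ... Unused.
#' @return Numeric vector, one value per query row.
#' @export
predict.lwl_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  pr <- purrr::map_dbl(seq_len(nrow(X)), function(i) {
    lwl_local_fit(object, X[i, ])$prob
  })
  if (type == "prob") pr else as.integer(pr >= object$config$threshold)
}

#' @export
print.lwl_model <- function(x, ...) {
  cat(sprintf(
    "Locally weighted %s logistic classifier: k = %d, R = %g, kernel = %s, %d stored training rows\n",
    if (x$config$ridge > 0) "ridge-penalized" else "ordinary", x$config$k,
    x$config$ridge, x$config$kernel, nrow(x$X)))
  invisible(x)
}

#' Global (non-local) ridge-penalized logistic regression
#'
#' Fits [fit_weighted_logistic_ridge()] on the full table with unit weights:
#' the L-R comparison classifier; `ridge = 0` gives ordinary logistic (L-O).
#'
#' @inheritParams lwl
#' @return A `global_logistic_model` wrapping the fit.
#' @export
global_logistic_ridge <- function(train, ridge = 1e-3, threshold = 0.5) {
  X <- feature_matrix(train)
  y <- check_labels(train$label)
  fit <- fit_weighted_logistic_ridge(X, y, w = 1, R = ridge)
  structure(list(fit = fit, threshold = threshold), class = "global_logistic_model")
}

#' @export
predict.global_logistic_model <- function(object, newdata,
                                          type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  pr <- predict(object$fit, X)
  if (type == "prob") pr else as.integer(pr >= object$threshold)
}

#' k-nearest-neighbor majority vote
#'
#' Unweighted majority vote among the k nearest training rows (Euclidean,
#' raw features); a tied vote takes the label of the single nearest neighbor.
#'
#' @param train Feature table with labels.
#' @param query Feature table (or matrix) of query rows.
#' @param k Number of neighbors.
#' @param type `"class"` (default) or `"prob"` (fraction of positive votes).
#' @return Integer labels or vote fractions, one per query row.
#' @export
knn_classify <- function(train, query, k = 5, type = c("class", "prob")) {
  type <- match.arg(type)
  X <- feature_matrix(train)
  y <- check_labels(train$label, both_classes = FALSE)
  Q <- if (is.matrix(query)) query else feature_matrix(query)
  out <- purrr::map_dbl(seq_len(nrow(Q)), function(i) {
    nb <- knn_neighborhood(X, Q[i, ], k, kernel = "uniform")
    votes <- y[nb$indices]
    frac <- mean(votes)
    if (type == "prob") return(frac)
    if (frac > 0.5) 1 else if (frac < 0.5) 0 else votes[1]
  })
  if (type == "class") as.integer(out) else out
}
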