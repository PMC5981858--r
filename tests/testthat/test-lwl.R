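# The LWL + ridge-logistic classifier family.

test_that("logistic link is symmetric, saturating and stable", {
  expect_identical(logistic_link(0), 0.5)
  expect_gte(logistic_link(30), 1 - 1e-12)
  expect_lte(logistic_link(-30), 1e-12)
  set.seed(2)
  t <- rnorm(100, sd = 10)
  expect_equal(logistic_link(t) + logistic_link(-t), rep(1, 100))
  expect_false(any(is.nan(logistic_link(c(-750, 750)))))
})

test_that("knn_neighborhood follows the stated distance/bandwidth/weight rule", {
  X <- matrix(c(0, 1, 2, 4))
  nb <- knn_neighborhood(X, 0, k = 2)
  expect_identical(nb$indices, c(1L, 2L))
  expect_equal(nb$distances, c(0, 1))
  expect_equal(nb$weights, c(1, 0.5))   # h = d3 = 2

  # self-match, k = 1
  nb1 <- knn_neighborhood(X, 1, k = 1)
  expect_identical(nb1$indices, 2L)
  expect_equal(nb1$distances, 0)
  expect_equal(nb1$weights, 1)

  # duplicated rows at the query: h = 0 branch gives uniform weights
  nb0 <- knn_neighborhood(matrix(c(5, 5)), 5, k = 2)
  expect_equal(nb0$weights, c(1, 1))

  # ties broken by lower training-row index
  nbt <- knn_neighborhood(matrix(c(1, -1, 3)), 0, k = 1)
  expect_identical(nbt$indices, 1L)

  expect_error(knn_neighborhood(X, 0, k = 5), class = "tidybreathe_config")
})

test_that("the two-point symmetric problem satisfies the penalized stationarity condition", {
  R <- 0.5
  fit <- fit_weighted_logistic_ridge(matrix(c(-1, 1)), c(0, 1), w = 1, R = R)
  b_star <- uniroot(function(b) 1 - logistic_link(b) - R * b, c(0, 5),
                    tol = 1e-12)$root
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(unname(fit$slopes), b_star, tolerance = 1e-6)
})

test_that("IRLS matches a generic penalized-likelihood maximizer and beats random draws", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 20; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    w <- runif(n, 0.2, 1)
    R <- 10^runif(1, -1.3, 0)
    fit <- fit_weighted_logistic_ridge(X, y, w = w, R = R)
    beta_hat <- c(fit$intercept, fit$slopes)
    beta_opt <- oracle_fit(X, y, w, R)
    expect_lt(max(abs(beta_hat - beta_opt)), 1e-4)
    expect_equal(fit$objective, oracle_objective(beta_hat, X, y, w, R),
                 tolerance = 1e-10)
    draws <- matrix(rnorm(1000 * (p + 1), sd = 2), 1000)
    best_draw <- max(apply(draws, 1, oracle_objective, X, y, w, R))
    expect_gte(fit$objective, best_draw - 1e-9)
  }
})

test_that("R = 0 reproduces glm's ordinary logistic fit", {
  set.seed(5)
  X <- matrix(rnorm(400), 100, 4)
  lp <- 0.3 + X %*% c(0.5, -0.8, 0.2, 0)
  y <- rbinom(100, 1, 1 / (1 + exp(-lp)))
  ours <- fit_weighted_logistic_ridge(X, y, R = 0)
  ref <- glm.fit(cbind(1, X), y, family = binomial(),
                 control = glm.control(epsilon = 1e-12))
  expect_lt(max(abs(c(ours$intercept, ours$slopes) - ref$coefficients)), 1e-6)
})

test_that("slope norm shrinks monotonically in R and vanishes in the limit", {
  set.seed(6)
  X <- matrix(rnorm(120), 40, 3)
  y <- rbinom(40, 1, logistic_link(X[, 1]))
  norms <- sapply(10^seq(-4, 3, length.out = 10), function(R) {
    sqrt(sum(fit_weighted_logistic_ridge(X, y, R = R)$slopes^2))
  })
  expect_true(all(diff(norms) <= 1e-8))
  expect_lt(norms[10], 1e-2)
  # degenerate prevalence model: intercept keeps the class balance
  big <- fit_weighted_logistic_ridge(X, y, R = 1e6)
  expect_equal(logistic_link(big$intercept), mean(y), tolerance = 0.01)
})

test_that("degenerate single-class fits saturate on the correct side", {
  X <- matrix(rnorm(10), 5, 2)
  up <- fit_weighted_logistic_ridge(X, rep(1, 5), R = 1e-3)
  expect_true(all(predict(up, X) > 0.5))
  down <- fit_weighted_logistic_ridge(X, rep(0, 5), R = 1e-3)
  expect_true(all(predict(down, X) < 0.5))
})

test_that("LWL predictions: saturation, symmetry and the R = 0 equivalence", {
  tbl <- cached_toy_table()
  model <- lwl(tbl, k = 5, ridge = 1e-3)
  # deep inside the smoker cluster the neighborhood is pure class 1
  smokers <- tbl[tbl$label == 1, ]
  pr <- predict(model, smokers[3, ])
  expect_gt(pr, 0.99)

  # mirror-symmetric classes around a query at the symmetry point
  sym <- tibble::tibble(x = c(-3, -2, -1, 1, 2, 3), label = c(0, 0, 0, 1, 1, 1))
  X <- matrix(sym$x)
  nb <- knn_neighborhood(X, 0, k = 6)
  f <- fit_weighted_logistic_ridge(X[nb$indices, , drop = FALSE] - 0,
                                   sym$label[nb$indices], nb$weights, R = 1e-3)
  expect_equal(predict(f, matrix(0)), 0.5, tolerance = 1e-6)

  # lwl-lo equals the lwl-lr code path at R = 0
  m0 <- lwl(tbl, k = 5, ridge = 0)
  f0 <- fit_classifier(tbl, "lwl-lo", k = 5)
  expect_identical(predict(m0, tbl[1:4, ]), predict(f0, tbl[1:4, ]))
})

test_that("thresholding is a documented, monotone tie-up rule", {
  tbl <- cached_toy_table()
  m <- lwl(tbl, threshold = 0.5)
  pr <- predict(m, tbl)
  expect_identical(predict(m, tbl, type = "class"), as.integer(pr >= 0.5))
  # raising the threshold can only turn 1s into 0s
  hi <- lwl(tbl, threshold = 0.9)
  expect_true(all(predict(hi, tbl, type = "class") <=
                  predict(m, tbl, type = "class")))
})

test_that("the learner is lazy: stored table unchanged, rebuilds predict identically", {
  tbl <- cached_toy_table()
  m1 <- lwl(tbl)
  m2 <- lwl(tbl)
  expect_identical(m1$train, tbl)
  expect_identical(predict(m1, tbl), predict(m2, tbl))
})

test_that("LWL+L-O class predictions are invariant to a common feature rescaling", {
  tbl <- cached_toy_table()
  base <- predict(lwl(tbl, ridge = 0), tbl, type = "class")
  for (c0 in c(0.1, 3, 100)) {
    scaled <- tbl
    scaled[feature_names()] <- scaled[feature_names()] * c0
    expect_identical(predict(lwl(scaled, ridge = 0), scaled, type = "class"),
                     base)
  }
})

test_that("no normalization sneaks into the pipeline: z-score round-trip is a no-op", {
  tbl <- cached_toy_table()
  X <- as.matrix(tbl[feature_names()])
  Z <- scale(X)
  back <- sweep(sweep(Z, 2, attr(Z, "scaled:scale"), "*"), 2,
                attr(Z, "scaled:center"), "+")
  tbl2 <- tbl
  tbl2[feature_names()] <- tibble::as_tibble(as.data.frame(back))
  expect_equal(as.matrix(tbl2[feature_names()]), X, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(predict(lwl(tbl2), tbl2, type = "class"),
                   predict(lwl(tbl), tbl, type = "class"))
})

test_that("knn majority vote and its tie rule", {
  tr <- tibble::tibble(x = c(0, 1, 2, 10), label = c(1, 1, 0, 0))
  tr_tbl <- dplyr::bind_cols(
    tibble::as_tibble(matrix(0, 4, 11,
                             dimnames = list(NULL, feature_names()[-1]))),
    tibble::tibble(ti_s = tr$x, label = tr$label))
  q <- tr_tbl[1, ]
  expect_identical(knn_classify(tr_tbl, q, k = 1), 1L)
  expect_identical(knn_classify(tr_tbl, q, k = 3), 1L)   # votes {1,1,0}
  # k = 2 tie at query 1.6: nearest (x = 2, label 0) decides
  q2 <- q; q2$ti_s <- 1.6
  expect_identical(knn_classify(tr_tbl, q2, k = 2), 0L)
})
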