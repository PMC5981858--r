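# Uniform interface over the classifier family compared in the study:
#   lwl-lr  locally weighted ridge-logistic (tuned default k = 5, R = 1e-3)
#   lwl-lo  locally weighted ordinary logistic (R = 0)
#   lr      global ridge-logistic
#   lo      global ordinary logistic
#   knn     k-nearest-neighbor majority vote (k = 5 for parity)

#' Classifier specification strings
#'
#' @return Character vector of supported specs.
#' @export
classifier_specs <- function() c("lwl-lr", "lwl-lo", "lr", "lo", "knn")

#' Fit a classifier by specification string
#'
#' @param train Feature table with labels.
#' @param spec One of [classifier_specs()].
#' @param k Neighborhood size (lwl and knn specs).
#' @param ridge Ridge penalty R (overrides the spec default; ignored by the
#'   ordinary-logistic and knn specs).
#' @param threshold Decision probability.
#' @param kernel Locality kernel for the lwl specs.
#' @return A `tb_classifier` supporting `predict(type = "prob"/"class")`.
#' @export
fit_classifier <- function(train, spec = "lwl-lr", k = 5, ridge = NULL,
                           threshold = 0.5, kernel = "linear") {
  spec <- match.arg(spec, classifier_specs())
  inner <- switch(spec,
    "lwl-lr" = lwl(train, k = k, ridge = ridge %||% 1e-3, kernel = kernel,
                   threshold = threshold),
    "lwl-lo" = lwl(train, k = k, ridge = 0, kernel = kernel,
                   threshold = threshold),
    "lr" = global_logistic_ridge(train, ridge = ridge %||% 1e-3,
                                 threshold = threshold),
    "lo" = global_logistic_ridge(train, ridge = 0, threshold = threshold),
    "knn" = list(train = train, k = k)
  )
  structure(list(spec = spec, inner = inner, threshold = threshold),
            class = "tb_classifier")
}

#' @export
predict.tb_classifier <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (object$spec == "knn") {
    knn_classify(object$inner$train, newdata, k = object$inner$k, type = type)
  } else {
    predict(object$inner, newdata, type = type)
  }
}

#' @export
print.tb_classifier <- function(x, ...) {
  cat("Classifier spec:", x$spec, "\n")
  invisible(x)
}

#' A small deterministic feature table for examples and tests
#'
#' Simulates a miniature cohort at full class separation and extracts its
#' feature table; cached-free, runs in about a second.
#'
#' @param n_per_class,trials,duration_s,separation,seed Passed to
#'   [synth_cohort()].
#' @return A labelled feature table.
#' @export
toy_feature_table <- function(n_per_class = 5, trials = 2, duration_s = 30,
                              separation = 1, seed = 1) {
  cohort <- synth_cohort(n_per_class = n_per_class, trials = trials,
                         duration_s = duration_s, fs = 100,
                         separation = separation, seed = seed)
  build_feature_table(cohort)
}

#' @importFrom rlang %||%
NULL
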