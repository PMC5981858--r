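# broom-style tidiers for fitted objects.

#' @export
tidy.ridge_logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)",
             names(x$slopes) %||% paste0("x", seq_along(x$slopes))),
    estimate = c(x$intercept, unname(x$slopes))
  )
}

#' @export
glance.ridge_logistic_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, ridge = x$ridge, n = x$n,
                 iterations = x$iterations, converged = x$converged,
                 singular = x$singular)
}

#' @export
tidy.lwl_model <- function(x, ...) {
  tibble::tibble(parameter = c("k", "ridge", "kernel", "threshold"),
                 value = as.character(unlist(x$config)))
}

#' @export
glance.lwl_model <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$X), k = x$config$k, ridge = x$config$ridge,
                 kernel = x$config$kernel, threshold = x$config$threshold)
}

#' @export
glance.cv_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(x[, c("metric", "mean")],
                             names_from = "metric", values_from = "mean")
  dplyr::mutate(wide, spec = attr(x, "spec"), n = attr(x, "n"),
                repeats = attr(x, "repeats"))
}
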