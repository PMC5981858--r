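# ggplot2 views of the pipeline's result objects.

#' Plot a flow trace with its segmented breath phases
#'
#' @param flow Flow tibble (`time_s`, `flow_lps`).
#' @param cycles Optional cycle tibble from [segment_breaths()]; when given,
#'   inspiration and expiration spans are shaded.
#' @param fs Sampling rate, Hz (needed with `cycles`).
#' @return A ggplot.
#' @export
plot_flow <- function(flow, cycles = NULL, fs = NULL) {
  p <- ggplot2::ggplot(flow, ggplot2::aes(x = .data$time_s, y = .data$flow_lps)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "flow (L/s)",
                  title = "Tidal breathing flow")
  if (!is.null(cycles) && !is.null(fs)) {
    shade <- dplyr::bind_rows(
      tibble::tibble(phase = "inspiration",
                     xmin = (cycles$insp_onset - 1) / fs,
                     xmax = (cycles$exp_onset - 1) / fs),
      tibble::tibble(phase = "expiration",
                     xmin = (cycles$exp_onset - 1) / fs,
                     xmax = (cycles$cycle_end - 1) / fs))
    p <- p +
      ggplot2::geom_rect(
        data = shade, inherit.aes = FALSE, alpha = 0.15,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                     ymin = -Inf, ymax = Inf, fill = .data$phase)) +
      ggplot2::scale_fill_manual(values = c(inspiration = "#D55E00",
                                            expiration = "#009E73"))
  }
  p
}

#' @describeIn fld_project One-dimensional strip of the projections, colored
#'   by class with a jittered vertical spread for visibility.
#' @param x An `fld_projection`.
#' @param ... Unused.
#' @export
autoplot.fld_projection <- function(x, ...) {
  d <- dplyr::mutate(x$projections,
                     class = factor(.data$label, c(0, 1),
                                    c("non-smoker", "smoker")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$projection, y = 0,
                                  colour = .data$class)) +
    ggplot2::geom_jitter(height = 0.3, width = 0, alpha = 0.8) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(-1, 1)) +
    ggplot2::labs(x = "projection on the Fisher discriminant line", y = NULL,
                  title = "Fisher linear discriminant projection")
}

#' @describeIn grid_search Accuracy tiles over the (k, r) grid, faceted by
#'   test fraction 1/t.
#' @param x A `grid_result`.
#' @param ... Unused.
#' @export
autoplot.grid_result <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$k), y = factor(.data$r),
                                  fill = .data$accuracy_pct)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~t, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = "accuracy (%)") +
    ggplot2::labs(x = "neighborhood size k", y = "ridge exponent r (R = 10^-r)",
                  title = "Hold-out accuracy over the {T, k, R} grid")
}

#' @describeIn repeated_stratified_cv Mean +/- sd of each cross-validated
#'   metric.
#' @param x A `cv_summary`.
#' @param ... Unused.
#' @export
autoplot.cv_summary <- function(x, ...) {
  d <- dplyr::mutate(x, value = ifelse(.data$metric == "acc",
                                       .data$mean / 100, .data$mean),
                     spread = ifelse(.data$metric == "acc",
                                     .data$sd / 100, .data$sd))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$spread,
                                        ymax = .data$value + .data$spread),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "value (accuracy rescaled to [0,1])",
                  title = paste0("Cross-validated metrics: ",
                                 attr(x, "spec")))
}
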