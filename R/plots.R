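# ggplot2 displays for fits, selection reports and MID time courses.

#' @export
autoplot.exp_fit <- function(object, log_y = FALSE, ...) {
  grid <- tibble::tibble(time_min = seq(min(object$series$time_min),
                                        max(object$series$time_min),
                                        length.out = 200))
  grid$fit <- predict(object, grid)
  p <- ggplot2::ggplot(object$series,
                       ggplot2::aes(x = .data$time_min, y = .data$pct_12c)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::labs(x = "time (min)", y = "% 12C remaining",
                  title = paste0(object$K, "-exponential fit",
                                 if (object$has_constant) " + constant"))
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
autoplot.bootstrap_band <- function(object, ...) {
  ggplot2::ggplot(object$band, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "orange", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::labs(x = "time (min)", y = "% 12C remaining",
                  title = sprintf("%.0f%% bootstrap band (n = %d)",
                                  100 * object$level, object$n_resamples))
}

#' @export
autoplot.selection_report <- function(object, ...) {
  long <- object$table |>
    dplyr::select("name", "aic", "bic", "cv") |>
    tidyr::pivot_longer(-"name", names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$name,
                                                levels = object$table$name),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("consensus:", object$consensus$model))
}

#' @export
autoplot.variant_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$variant, .data$ssr), y = .data$ssr)) +
    ggplot2::geom_col(fill = "grey50") +
    ggplot2::labs(x = "model variant", y = "weighted SSR")
}

#' Plot percent-12C decay curves of a dataset
#'
#' @param d A `cbc_dataset`.
#' @param species Species to draw (default: all).
#' @param log_y Log-scale y axis (semilog display).
#' @return A ggplot.
#' @export
plot_labeling <- function(d, species = NULL, log_y = TRUE) {
  ser <- twelve_c_series(d$mids)
  if (!is.null(species)) {
    ser <- dplyr::filter(ser, .data$metabolite %in% species)
  }
  p <- ggplot2::ggplot(ser, ggplot2::aes(x = .data$time_min,
                                         y = .data$pct_12c,
                                         colour = .data$metabolite)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "% 12C remaining")
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
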