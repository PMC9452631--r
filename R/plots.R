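#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a cross-correlogram
#'
#' Bars of MEC-around-CA1 event rate against lag; a dashed line marks zero
#' lag and a point marks the extracted peak lag.
#'
#' @param object A [cross_correlogram()].
#' @param smooth_bins Passed to [peak_lag()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_correlogram <- function(object, smooth_bins = 3, ...) {
  pl <- peak_lag(object, smooth_bins = smooth_bins)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$rate)) +
    ggplot2::geom_col(width = attr(object, "bin_ms") * 0.9, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "lag (ms, negative = target leads)",
                  y = "events / s immobile",
                  title = sprintf("Cross-correlogram (peak lag %s ms)",
                                  ifelse(is.na(pl), "undefined", format(pl)))) +
    ggplot2::theme_minimal()
  if (!is.na(pl)) {
    p <- p + ggplot2::annotate("point", x = pl,
                               y = max(object$rate), shape = 25, fill = "red")
  }
  p
}

#' Plot event durations
#'
#' Histogram of detected event durations with the long-ripple cutoff marked.
#'
#' @param object A `swr_events` table.
#' @param long_cutoff_ms Cutoff line, ms.
#' @param binwidth Histogram bin width, ms.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.swr_events <- function(object, long_cutoff_ms = 25, binwidth = 5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$duration_ms)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40", color = "white") +
    ggplot2::geom_vline(xintercept = long_cutoff_ms, linetype = "dashed") +
    ggplot2::labs(x = "SWR duration (ms)", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot a duration-fraction curve
#'
#' @param object A [duration_fraction_curve()] result.
#' @param cumulative Plot the cumulative curve instead of the histogram.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.duration_curve <- function(object, cumulative = FALSE, ...) {
  y <- if (cumulative) "cumulative" else "fraction"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$duration_ms, y = .data[[y]])) +
    (if (cumulative) ggplot2::geom_step() else
      ggplot2::geom_col(fill = "grey40")) +
    ggplot2::labs(x = "SWR duration (ms)",
                  y = if (cumulative) "cumulative fraction" else "fraction") +
    ggplot2::theme_minimal()
}

#' Plot an LFP snippet around an event
#'
#' Raw trace with the detected event interval shaded.
#'
#' @param lfp An [lfp_trace()].
#' @param event One-row slice of an event table.
#' @param pad_s Seconds of context either side.
#' @return A ggplot.
#' @export
plot_event_snippet <- function(lfp, event, pad_s = 0.1) {
  i0 <- max(1, time_index(lfp, event$start - pad_s) + 1)
  i1 <- min(length(lfp$samples), time_index(lfp, event$end + pad_s) + 1)
  df <- tibble::tibble(time = sample_time(lfp, (i0:i1) - 1),
                       uV = lfp$samples[i0:i1])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$uV)) +
    ggplot2::annotate("rect", xmin = event$start, xmax = event$end,
                      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "LFP (µV)") +
    ggplot2::theme_minimal()
}
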