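#' Plot an STA fit
#'
#' Corrected STA with its bootstrap confidence band, plus the raw and
#' jittered STAs (mean-subtracted) for context.
#'
#' @param object An [sta_connection()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sta_fit <- function(object, ...) {
  td <- tidy(object)
  long <- td %>%
    dplyr::mutate(raw = .data$raw - mean(.data$raw),
                  jittered = .data$jittered - mean(.data$jittered)) %>%
    tidyr::pivot_longer(c("raw", "jittered", "corrected"),
                        names_to = "trace", values_to = "vm")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$vm)) +
    ggplot2::geom_ribbon(
      data = td,
      ggplot2::aes(x = .data$time_ms, ymin = .data$band_lower,
                   ymax = .data$band_upper),
      inherit.aes = FALSE, fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$trace)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "time from LGN spike (ms)", y = "Vm (mV, mean-subtracted)",
      colour = NULL,
      title = if (isTRUE(object$connected)) "connected pair" else "not connected"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a LIF simulation
#'
#' Membrane potential with spike times and threshold, over an optional time
#' window.
#'
#' @param object A [simulate_lif()] result.
#' @param window_s Two-element time window, seconds (default first 2 s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lif_sim <- function(object, window_s = c(0, 2), ...) {
  td <- tidy(object) %>%
    dplyr::filter(.data$time_s >= window_s[1], .data$time_s <= window_s[2])
  sp <- object$spike_times_s
  sp <- sp[sp >= window_s[1] & sp <= window_s[2]]
  ggplot2::ggplot(td, ggplot2::aes(.data$time_s, .data$vm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$params$v_thresh,
                        linetype = 2, colour = "red") +
    ggplot2::annotate("point", x = sp,
                      y = rep(object$params$v_thresh + 1, length(sp)),
                      shape = 3) +
    ggplot2::labs(x = "time (s)", y = "Vm (mV)",
                  title = sprintf("%s synapses: %.1f Hz", object$mode,
                                  object$rate_hz)) +
    ggplot2::theme_minimal()
}

#' Population scatter plots of synaptic reliability and variability
#'
#' Average amplitude and CV against percent-undetectable across connected
#' pairs.
#'
#' @param summaries Row-bound [summarize_pair()] tibbles.
#' @return A ggplot object (faceted).
#' @export
plot_population_summary <- function(summaries) {
  long <- summaries %>%
    tidyr::pivot_longer(c("avg_amp_all", "cv_all"), names_to = "stat",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$pct_undetectable, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::facet_wrap(~stat, scales = "free_y") +
    ggplot2::labs(x = "% undetectable single-spike EPSPs", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a reverse-correlation receptive field map
#'
#' @param object An [reverse_correlation_rf()] result.
#' @param lag_ms Which lag to show (defaults to the strongest).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rf_map <- function(object, lag_ms = object$peak_lag_ms, ...) {
  td <- tidy(object) %>% dplyr::filter(.data$lag_ms == !!lag_ms)
  ggplot2::ggplot(td, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("RF at %g ms lag", lag_ms),
                  x = NULL, y = NULL, fill = "weight") +
    ggplot2::theme_minimal()
}
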