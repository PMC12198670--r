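#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_ribbon labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a coherence spectrum
#'
#' @param object A `coh_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coh_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$cf, y = .data$coherence)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "center frequency (Hz)", y = "wavelet coherence") +
    theme_minimal()
}

#' Plot a lag profile
#'
#' Afferent side (EMG leads) at negative lags, efferent side (EEG leads) at
#' positive lags; the dashed line marks lag zero.
#'
#' @param object A `lag_profile` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lag_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$lag_ms, y = .data$coherence)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "lag (ms; > 0 = EEG leads, efferent)",
         y = sprintf("coherence at %.2f Hz", attr(object, "peak_cf") %||% NA)) +
    theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `psd_spectrum` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psd_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$freq, y = .data$power)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz))) +
    theme_minimal()
}

#' Plot an NMDS embedding
#'
#' @param object A `cmc_nmds` object.
#' @param colour Optional vector (e.g. group labels) to colour points by.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cmc_nmds <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  names(df)[1:2] <- c("NMDS1", "NMDS2")
  if (!is.null(colour)) df$colour <- colour
  p <- if (is.null(colour)) {
    ggplot(df, aes(x = .data$NMDS1, y = .data$NMDS2))
  } else {
    ggplot(df, aes(x = .data$NMDS1, y = .data$NMDS2, colour = .data$colour)) +
      labs(colour = NULL)
  }
  p + geom_point() +
    labs(caption = sprintf("stress = %.3f", object$stress)) +
    theme_minimal()
}

#' Plot grouped PSD summaries with SEM ribbons
#'
#' @param psd_summary Output of [summarise_psd()].
#' @param max_hz Upper frequency limit for display.
#' @return A ggplot faceted by task and channel.
#' @export
plot_psd_summary <- function(psd_summary, max_hz = 63) {
  df <- filter(psd_summary, .data$freq <= max_hz)
  ggplot(df, aes(x = .data$freq, y = .data$mean_power,
                 colour = .data$group, fill = .data$group)) +
    geom_ribbon(aes(ymin = .data$mean_power - .data$sem,
                    ymax = .data$mean_power + .data$sem),
                alpha = 0.25, colour = NA) +
    geom_line() +
    facet_wrap(~ .data$task + .data$channel, scales = "free_y") +
    labs(x = "frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz))) +
    theme_minimal()
}
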