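#' Plot voltage traces of a trace set
#'
#' @param object An `ivl_trace_set`.
#' @param sites Sites to show (default all).
#' @param window Optional time window `c(from, to)` (ms).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_trace_set <- function(object, sites = object$sites,
                                   window = NULL, ...) {
  df <- dplyr::filter(as_tibble(object), .data$series == "v",
                      .data$site %in% sites)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time >= window[1],
                        .data$time <= window[2])
  }
  df$site <- factor(df$site, levels = sites)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)")
}

#' Currentscape plot: stacked percent contributions
#'
#' Stacked share-of-pool plot of each channel's contribution to the
#' total outward current (upper panel, 0..1) and total inward current
#' (lower panel, 0..-1), over time.
#'
#' @param object An `ivl_currentscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_currentscape <- function(object, ...) {
  df <- dplyr::mutate(object,
                      signed = ifelse(.data$pool == "inward",
                                      -.data$fraction, .data$fraction))
  df <- dplyr::filter(df, !is.na(.data$signed))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$signed,
                                   fill = .data$channel)) +
    ggplot2::geom_area(position = ggplot2::position_stack()) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$pool), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "share of pool current",
                  fill = "channel")
}

#' Plot a correlogram
#'
#' @param object An `ivl_correlogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "lag (ms)", y = "normalized cross-correlation")
}

#' Plot an F-I line with its calibration points
#'
#' @param object An `ivl_fi_line`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_fi_line <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$current, .data$rate)) +
    ggplot2::geom_abline(slope = object$m, intercept = object$b,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "holding current (pA)", y = "spike rate (Hz)")
}

#' Paired charge comparison plot (in vitro vs IVL)
#'
#' One line per seed and site connecting the in-vitro total charge to
#' the paired IVL total charge, facetted by channel.
#'
#' @param object An `ivl_state_comparison`.
#' @param channels Channels to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ivl_state_comparison <- function(object, channels = NULL, ...) {
  df <- object$charges
  if (!is.null(channels)) {
    df <- dplyr::filter(df, .data$channel %in% channels)
  }
  df$state <- factor(df$state, levels = c("vitro", "ivl"),
                     labels = c("in vitro", "IVL"))
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$charge,
                                   group = interaction(.data$replicate,
                                                       .data$site),
                                   colour = .data$site)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "total charge (pA ms)", colour = "site")
}
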