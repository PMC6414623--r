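#' Plot normalized pulsatility traces
#'
#' Reproduces the standard presentation of the venous pulsation analysis:
#' normalized transversal diameter, perfused area, mean phase difference and
#' flow proxy against time, with cycle boundaries marked.
#'
#' @param object A `srvp_pulsatility`.
#' @param traces Which traces to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srvp_pulsatility
#' @export
autoplot.srvp_pulsatility <- function(object,
                                      traces = c("norm_lat_diameter",
                                                 "norm_area", "norm_flow"),
                                      ...) {
  long <- tidyr::pivot_longer(object$series,
                              cols = dplyr::all_of(traces),
                              names_to = "trace", values_to = "value")
  starts <- object$series$t_s[object$cycles$start_idx]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value,
                                     colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = starts, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "time (s)", y = "normalized value",
                  colour = NULL,
                  title = "Venous pulsatility traces") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Doppler frame
#'
#' Phase-difference tomogram as a diverging-colour raster, optionally with
#' the segmented lumen outline.
#'
#' @param dseq A `doppler_sequence`.
#' @param frame Frame index.
#' @param seg Optional `lumen_segmentation` to outline.
#' @return A ggplot object.
#' @export
plot_doppler_frame <- function(dseq, frame = 1, seg = NULL) {
  d <- dseq$frames[[frame]]
  df <- tidyr::expand_grid(z = seq_len(nrow(d$dphi)),
                           x = seq_len(ncol(d$dphi)))
  df$dphi <- as.vector(d$dphi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                        fill = .data$dphi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "grey20",
                                  high = "orange", limits = c(-pi, pi)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "A-scan", y = "depth (px)",
                  fill = expression(Delta * phi)) +
    ggplot2::theme_minimal()
  if (!is.null(seg) && !seg$empty) {
    idx <- which(seg$mask, arr.ind = TRUE)
    p <- p + ggplot2::annotate("point", x = idx[, 2], y = idx[, 1],
                               size = 0.1, alpha = 0.2, colour = "white")
  }
  p
}

#' Plot dual-site flow traces
#'
#' @param series_a,series_b Normalized flow traces.
#' @param fps Frame rate.
#' @return A ggplot object.
#' @export
plot_dual_site_flow <- function(series_a, series_b, fps) {
  n <- length(series_a)
  df <- tibble::tibble(t_s = rep((seq_len(n) - 1) / fps, 2),
                       flow = c(series_a, series_b),
                       site = rep(c("A (collapse)", "B (remote)"), each = n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_s, y = .data$flow,
                                   colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "normalized flow", colour = NULL) +
    ggplot2::theme_minimal()
}
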