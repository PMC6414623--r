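#' ROI mean-intensity time series
#'
#' Tracks the mean linear intensity inside a fixed rectangular ROI across a
#' sequence of frames and normalizes the trace to its maximum. For OCT
#' input (a `doppler_sequence`) the stored dB frames are converted back to
#' linear intensity before averaging — mean reflectivity is the physical
#' quantity; SLO frames are already linear.
#'
#' @param seq A `doppler_sequence` (modality "OCT") or `slo_sequence`
#'   (modality "SLO"), or a plain list of numeric matrices with a `t_s`
#'   vector supplied via `t_s`.
#' @param roi ROI `list(z = c(z1, z2), x = c(x1, x2))` (1-based, inclusive;
#'   rows/columns for SLO frames).
#' @param t_s Timestamps when `seq` is a bare list of matrices.
#' @return Tibble of class `roi_intensity_series`: `t_s`, `mean_intensity`,
#'   `norm_intensity`, with `roi`, `modality` and `fps` attributes.
#' @export
roi_mean_intensity <- function(seq, roi, t_s = NULL) {
  if (inherits(seq, "doppler_sequence")) {
    frames <- lapply(seq$frames, function(d) 10^(d$intensity_db / 10))
    t_s <- seq$t_s
    modality <- "OCT"
  } else if (inherits(seq, "slo_sequence")) {
    frames <- seq$frames
    t_s <- seq$t_s
    modality <- "SLO"
  } else {
    stopifnot(is.list(seq), !is.null(t_s), length(t_s) == length(seq))
    frames <- seq
    modality <- "OCT"
  }
  d1 <- dim(frames[[1]])
  if (roi$z[1] < 1 || roi$z[2] > d1[1] || roi$x[1] < 1 || roi$x[2] > d1[2] ||
      roi$z[1] > roi$z[2] || roi$x[1] > roi$x[2])
    stop("ROI out of bounds")
  mi <- vapply(frames, function(fr)
    mean(fr[roi$z[1]:roi$z[2], roi$x[1]:roi$x[2]]), numeric(1))
  out <- tibble::tibble(t_s = t_s, mean_intensity = mi,
                        norm_intensity = normalize_series(mi))
  class(out) <- c("roi_intensity_series", class(out))
  attr(out, "roi") <- roi
  attr(out, "modality") <- modality
  attr(out, "fps") <- 1 / stats::median(diff(t_s))
  out
}

#' Compare pulsatile intensity between OCT and SLO
#'
#' Resamples the faster-sampled trace linearly onto the timestamps of the
#' slower one (no information is invented at the lower rate) and reports
#' the Pearson correlation plus the best cross-correlation lag of the two
#' normalized intensity traces over their overlap.
#'
#' @param oct_series,slo_series `roi_intensity_series` tibbles (any two
#'   modalities/rates; named for the canonical use).
#' @param min_overlap_s Minimum required overlap (seconds), nominally one
#'   cardiac cycle.
#' @return Tibble with `r`, `lag_s`, `n`.
#' @export
compare_modalities <- function(oct_series, slo_series, min_overlap_s = 0.8) {
  t1 <- oct_series$t_s; t2 <- slo_series$t_s
  overlap <- c(max(min(t1), min(t2)), min(max(t1), max(t2)))
  if (diff(overlap) < min_overlap_s) stop("insufficient overlap")
  fps1 <- attr(oct_series, "fps"); fps2 <- attr(slo_series, "fps")
  if (is.null(fps1)) fps1 <- 1 / stats::median(diff(t1))
  if (is.null(fps2)) fps2 <- 1 / stats::median(diff(t2))
  if (fps1 >= fps2) {
    slow <- slo_series; fast <- oct_series; fps_slow <- fps2
  } else {
    slow <- oct_series; fast <- slo_series; fps_slow <- fps1
  }
  keep <- slow$t_s >= overlap[1] & slow$t_s <= overlap[2]
  ts <- slow$t_s[keep]
  y_slow <- slow$norm_intensity[keep]
  y_fast <- stats::approx(fast$t_s, fast$norm_intensity, xout = ts,
                          rule = 2)$y
  d <- estimate_delay(y_slow, y_fast, fps_slow)
  tibble::tibble(r = stats::cor(y_slow, y_fast),
                 lag_s = d$delay_s, n = length(ts))
}
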