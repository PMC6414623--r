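#' Normalize a series to its maximum
#'
#' Divides by the maximum absolute value over the analysis window, so the
#' normalized trace has maximum (magnitude) exactly 1. Idempotent.
#'
#' @param x Numeric series.
#' @param window Optional index range `c(first, last)` defining the analysis
#'   window (default: full series).
#' @return `x / max(|x|)` over the window.
#' @export
normalize_series <- function(x, window = NULL) {
  if (is.null(window)) window <- c(1L, length(x))
  w <- x[window[1]:window[2]]
  w <- w[is.finite(w)]
  if (length(w) == 0 || all(w == 0)) stop("degenerate series")
  x / max(abs(w))
}

# rolling median, window k (odd); edges use shrunken windows
roll_median <- function(x, k = 3) {
  if (k <= 1) return(x)
  h <- k %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Detect cardiac cycles in a reference trace
#'
#' Finds cycle boundaries at successive maxima of the reference series
#' (arterial waveform if available, otherwise the inverted area trace, whose
#' peaks are the collapse events), using peak detection with a minimum
#' separation of one period at the upper heart-rate bound. If at least one
#' median period of data follows the last peak, a final window of median
#' period length is appended so complete trailing cycles are not discarded.
#'
#' @param reference Numeric reference series.
#' @param fps Sampling rate (frames per second).
#' @param bpm_range Plausible heart-rate band, default `c(40, 120)`.
#' @return Tibble of cycle windows: `cycle`, `start_idx`, `end_idx`
#'   (1-based, `end_idx` exclusive of the next window's start).
#' @export
detect_cycles <- function(reference, fps, bpm_range = c(40, 120)) {
  stopifnot(length(reference) > 2, fps > 0)
  if (diff(range(reference)) == 0) stop("no cycles detected")
  min_sep <- max(2L, floor(fps * 60 / bpm_range[2]))
  r <- (reference - min(reference)) / diff(range(reference))
  pk <- pracma::findpeaks(r, minpeakdistance = min_sep,
                          minpeakheight = 0.5)
  if (is.null(pk) || nrow(pk) < 2) stop("no cycles detected")
  peaks <- sort(pk[, 2])
  windows <- tibble::tibble(start_idx = peaks[-length(peaks)],
                            end_idx = peaks[-1])
  med_period <- stats::median(diff(peaks))
  last <- peaks[length(peaks)]
  if (length(reference) - last >= 0.95 * med_period) {
    windows <- dplyr::bind_rows(
      windows,
      tibble::tibble(start_idx = last,
                     end_idx = last + as.integer(round(med_period))))
  }
  dplyr::mutate(windows, cycle = dplyr::row_number(),
                .before = "start_idx")
}

#' Pulsation amplitude of a trace
#'
#' The relative pulsatile excursion `(max - min) / max` of the raw trace,
#' reported per cardiac cycle (with the median across cycles as the robust
#' summary) and over the whole analysed sequence (the per-sequence maximum
#' change).
#'
#' @param x Raw (pre-normalization) series; a short rolling median
#'   (`smooth_k`, default 3 frames) suppresses single-frame segmentation
#'   jitter before the excursion is read off.
#' @param cycle_windows Tibble from [detect_cycles()].
#' @param smooth_k Rolling-median window (frames); 1 disables smoothing.
#' @return List with `per_cycle` (tibble: `cycle`, `amplitude`), `median`
#'   and `sequence` (amplitude over the full span of the windows).
#' @export
pulsation_amplitude <- function(x, cycle_windows, smooth_k = 3) {
  stopifnot(nrow(cycle_windows) >= 1)
  xs <- roll_median(x, smooth_k)
  amp <- function(v) {
    if (max(v) == 0) return(0)
    (max(v) - min(v)) / max(v)
  }
  per_cycle <- dplyr::mutate(
    cycle_windows,
    amplitude = purrr::map2_dbl(.data$start_idx, .data$end_idx,
                                ~ amp(xs[.x:min(.y, length(xs))])))
  span <- c(min(cycle_windows$start_idx),
            min(max(cycle_windows$end_idx), length(xs)))
  list(per_cycle = per_cycle[, c("cycle", "amplitude")],
       median = stats::median(per_cycle$amplitude),
       sequence = amp(xs[span[1]:span[2]]))
}

#' DOCT-vs-diameter sensitivity ratio
#'
#' Ratio of the relative perfused-area pulsation amplitude to the relative
#' transversal-diameter pulsation amplitude; values above 1 quantify how
#' much more sensitively the cross-sectional (tomographic) measurement
#' detects the venous pulsation than an en-face diameter reading.
#'
#' @param area_amp Relative area-change amplitude (fraction).
#' @param diam_amp Relative transversal-diameter-change amplitude
#'   (fraction), must be positive.
#' @return `area_amp / diam_amp`.
#' @export
sensitivity_ratio <- function(area_amp, diam_amp) {
  if (diam_amp <= 0) stop("no lateral pulsation detected")
  area_amp / diam_amp
}

#' Pulsatility analysis of a measured sequence
#'
#' Turns the per-frame measurement table into normalized pulsatility traces
#' with cardiac-cycle annotations and amplitude summaries: transversal
#' diameter, perfused area, mean phase difference and flow proxy.
#'
#' @param measurements Tibble from [measure_sequence()].
#' @param fps Frame rate (frames per second).
#' @param reference Optional reference series for cycle detection; default
#'   is the inverted area trace (collapse peaks).
#' @param bpm_range Heart-rate band for cycle detection.
#' @param smooth_k Rolling-median smoothing for the traces (frames).
#' @return Object of class `srvp_pulsatility`: list with `series` (tibble:
#'   `t_s`, `frame`, `cycle`, normalized traces), `cycles`, `amplitudes`
#'   (tibble: trace, per-sequence max, per-cycle median), `flow_deviation`
#'   (max absolute fractional deviation of the normalized flow trace from
#'   its mean) and `sensitivity_ratio`.
#' @export
pulsatility <- function(measurements, fps, reference = NULL,
                        bpm_range = c(40, 120), smooth_k = 3) {
  m <- measurements
  stopifnot(all(c("lat_diameter_um", "area_um2", "mean_dphi_rad",
                  "flow_au", "t_s") %in% names(m)))
  if (is.null(reference)) reference <- max(m$area_um2) - m$area_um2
  cycles <- detect_cycles(reference, fps, bpm_range)

  # the rolling median guards the pixel-quantised diameter traces against
  # single-frame extent flicker; the area/phase/flow traces are
  # area-integrated and continuous-valued, so their extremes are read raw
  traces <- list(lat_diameter = m$lat_diameter_um,
                 area = m$area_um2,
                 mean_dphi = abs(m$mean_dphi_rad),
                 flow = abs(m$flow_au))
  ks <- c(lat_diameter = smooth_k, area = 1L, mean_dphi = 1L, flow = 1L)
  amps <- purrr::imap_dfr(traces, function(x, nm) {
    a <- pulsation_amplitude(x, cycles, ks[[nm]])
    tibble::tibble(trace = nm, sequence_amplitude = a$sequence,
                   cycle_median_amplitude = a$median)
  })

  cyc_id <- rep(NA_integer_, nrow(m))
  for (i in seq_len(nrow(cycles)))
    cyc_id[cycles$start_idx[i]:min(cycles$end_idx[i], nrow(m))] <- cycles$cycle[i]

  flow_n <- normalize_series(abs(m$flow_au))
  flow_dev <- max(abs(flow_n - mean(flow_n))) / mean(flow_n)

  series <- tibble::tibble(
    frame = m$frame, t_s = m$t_s, cycle = cyc_id,
    norm_lat_diameter = normalize_series(roll_median(m$lat_diameter_um, smooth_k)),
    norm_area = normalize_series(m$area_um2),
    norm_mean_dphi = normalize_series(abs(m$mean_dphi_rad)),
    norm_flow = flow_n)

  diam_amp <- amps$sequence_amplitude[amps$trace == "lat_diameter"]
  area_amp <- amps$sequence_amplitude[amps$trace == "area"]
  sr <- if (diam_amp > 0) area_amp / diam_amp else NA_real_

  structure(list(series = series, cycles = cycles, amplitudes = amps,
                 flow_deviation = flow_dev, sensitivity_ratio = sr,
                 fps = fps),
            class = "srvp_pulsatility")
}

#' @export
print.srvp_pulsatility <- function(x, ...) {
  cat(sprintf("<srvp_pulsatility> %d frames, %d cycles\n",
              nrow(x$series), nrow(x$cycles)))
  cat(sprintf("  diameter change (max): %.1f%%   area change (max): %.1f%%\n",
              100 * x$amplitudes$sequence_amplitude[
                x$amplitudes$trace == "lat_diameter"],
              100 * x$amplitudes$sequence_amplitude[x$amplitudes$trace == "area"]))
  cat(sprintf("  sensitivity ratio: %.2f   flow deviation: +/-%.1f%%\n",
              x$sensitivity_ratio, 100 * x$flow_deviation))
  invisible(x)
}
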