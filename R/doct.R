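#' Intensity tomogram in decibels
#'
#' Log-magnitude image `20 log10(|C| / ref)` with the reference fixed at the
#' median magnitude of the first frame of the sequence (so tissue sits near
#' 0 dB), floored at -60 dB.
#'
#' @param frame Complex matrix (depth x A-scans).
#' @param ref Reference magnitude; defaults to the median magnitude of
#'   `frame` itself.
#' @param floor_db Lower display floor in dB.
#' @return Numeric matrix of dB values.
#' @export
intensity_tomogram <- function(frame, ref = NULL, floor_db = -60) {
  stopifnot(is.complex(frame), length(frame) > 0)
  mag <- Mod(frame)
  if (all(mag == 0)) stop("empty frame")
  if (is.null(ref)) ref <- stats::median(mag)
  db <- 20 * log10(pmax(mag / ref, 10^(floor_db / 20)))
  matrix(db, nrow(frame), ncol(frame))
}

#' Phase-difference (Doppler) tomogram of one frame
#'
#' Computes the per-pixel phase difference between laterally adjacent
#' A-scans, `dphi(z, j) = Arg(C(z, j+1) * Conj(C(z, j)))`, wrapped to
#' \eqn{[-\pi, \pi)}. The Doppler frame is one A-scan column narrower than
#' the source; the paired intensity frame is cropped to match. A validity
#' mask marks pixels whose intensity exceeds the estimated noise floor by
#' 3 dB.
#'
#' @param frame Complex matrix with at least 2 A-scans.
#' @param tau_s Inter-A-scan period (s), stored for velocity conversion.
#' @param ref Intensity reference magnitude (see [intensity_tomogram()]).
#' @param noise_floor_db Noise floor in dB relative to `ref`; by default the
#'   5th percentile of the intensity frame.
#' @return An object of class `doppler_frame`: list with `dphi`,
#'   `intensity_db`, `mask_valid`, `tau_s`, `noise_floor_db`.
#' @export
phase_difference_tomogram <- function(frame, tau_s, ref = NULL,
                                      noise_floor_db = NULL) {
  stopifnot(is.complex(frame))
  if (ncol(frame) < 2) stop("frame must contain at least 2 A-scans")
  nx <- ncol(frame)
  prod <- frame[, 2:nx, drop = FALSE] * Conj(frame[, 1:(nx - 1), drop = FALSE])
  dphi <- wrap_phase(Arg(prod))
  db <- intensity_tomogram(frame, ref = ref)[, 1:(nx - 1), drop = FALSE]
  if (is.null(noise_floor_db))
    noise_floor_db <- stats::quantile(db, 0.05, names = FALSE)
  structure(list(dphi = dphi, intensity_db = db,
                 mask_valid = db > noise_floor_db + 3,
                 tau_s = tau_s, noise_floor_db = noise_floor_db,
                 bulk_corrected = FALSE),
            class = "doppler_frame")
}

#' De-interleave an inter-A-scan-switched sequence
#'
#' Splits an interleaved acquisition into its channels: channel `k` receives
#' A-scans `k, k + n, k + 2n, ...`. Each output's A-scan period and lateral
#' pixel pitch are `n_channels` times those of the interleaved stream.
#'
#' @param seq An `oct_sequence` whose A-scan count is divisible by
#'   `n_channels`.
#' @param n_channels Number of interleaved channels.
#' @return List of `oct_sequence` objects, one per channel.
#' @export
demux_channels <- function(seq, n_channels) {
  stopifnot(inherits(seq, "oct_sequence"), n_channels >= 1)
  nx <- ncol(seq$frames[[1]])
  if (nx %% n_channels != 0)
    stop("A-scan count not divisible by n_channels")
  if (n_channels == 1) return(list(seq))
  lapply(seq_len(n_channels), function(k) {
    out <- seq
    cols <- seq(k, nx, by = n_channels)
    out$frames <- lapply(seq$frames, function(fr) fr[, cols, drop = FALSE])
    out$tau_s <- seq$tau_s * n_channels
    out$lateral_px_um <- seq$lateral_px_um * n_channels
    out$channel_id <- k
    out
  })
}

#' Bulk-motion phase correction
#'
#' Removes the per-A-scan bulk phase offset caused by axial eye motion:
#' for every A-scan column the circular median of the phase difference over
#' static-tissue pixels (valid pixels outside the lumen region of interest)
#' is subtracted and the result re-wrapped, leaving the static-tissue phase
#' centred on zero.
#'
#' @param d A `doppler_frame`.
#' @param lumen_roi Optional ROI `list(z = c(z1, z2), x = c(x1, x2))`
#'   (1-based, inclusive) excluded from the tissue estimate.
#' @param min_tissue_px Minimum number of tissue pixels per frame; below
#'   this the frame is passed through with a warning flag.
#' @return The corrected `doppler_frame` (field `bulk_corrected` set).
#' @export
bulk_motion_correct <- function(d, lumen_roi = NULL, min_tissue_px = 100) {
  stopifnot(inherits(d, "doppler_frame"))
  tissue <- d$mask_valid
  if (!is.null(lumen_roi)) {
    tissue[lumen_roi$z[1]:lumen_roi$z[2],
           max(1, lumen_roi$x[1]):min(ncol(tissue), lumen_roi$x[2])] <- FALSE
  }
  if (sum(tissue) < min_tissue_px) {
    d$bulk_warning <- TRUE
    return(d)
  }
  med <- vapply(seq_len(ncol(d$dphi)), function(j) {
    v <- d$dphi[tissue[, j], j]
    if (length(v) < 5) 0 else circ_median(v)
  }, numeric(1))
  d$dphi <- wrap_phase(sweep(d$dphi, 2, med, "-"))
  d$bulk_corrected <- TRUE
  d
}

#' Convert phase difference to axial and absolute velocity
#'
#' Applies the phase-resolved Doppler relation
#' \eqn{v_z = \lambda_0 \Delta\phi / (4 \pi n \tau)} and, where the Doppler
#' geometry permits (`|cos(theta)| > 0.05`, i.e. theta outside 90 +/- ~2.9
#' degrees), the absolute velocity `v = v_z / cos(theta)`. Within that band
#' the absolute velocity is undetermined (`NA`) while the axial component is
#' still returned.
#'
#' @param dphi_rad Phase difference(s), radians.
#' @param lambda0_nm Centre wavelength (nm).
#' @param tau_s Inter-A-scan period (s).
#' @param n_index Tissue refractive index.
#' @param theta_deg Doppler angle (degrees).
#' @return Tibble with `v_axial_mm_s`, `v_abs_mm_s`, `undetermined`.
#' @export
phase_to_velocity <- function(dphi_rad, lambda0_nm, tau_s, n_index = 1.38,
                              theta_deg = 90) {
  stopifnot(tau_s > 0, all(is.finite(dphi_rad)))
  v_axial <- (lambda0_nm * 1e-9) * dphi_rad /
    (4 * pi * n_index * tau_s) * 1e3  # mm/s
  ct <- cos(theta_deg * pi / 180)
  undet <- abs(ct) <= 0.05
  v_abs <- if (undet) rep(NA_real_, length(v_axial)) else v_axial / ct
  tibble::tibble(v_axial_mm_s = v_axial, v_abs_mm_s = v_abs,
                 undetermined = undet)
}

#' Process a complex sequence into a Doppler sequence
#'
#' Runs [phase_difference_tomogram()] on every frame with a common intensity
#' reference (median magnitude of the first frame) and, optionally,
#' [bulk_motion_correct()].
#'
#' @param seq An `oct_sequence`.
#' @param bulk_correction Apply the per-A-scan bulk phase correction.
#' @param lumen_roi Optional lumen ROI excluded from the tissue estimate.
#' @return An object of class `doppler_sequence`: list with `frames` (list
#'   of `doppler_frame`), `t_s`, pixel pitches and acquisition metadata.
#' @export
process_sequence <- function(seq, bulk_correction = TRUE, lumen_roi = NULL) {
  stopifnot(inherits(seq, "oct_sequence"))
  ref <- stats::median(Mod(seq$frames[[1]]))
  db1 <- intensity_tomogram(seq$frames[[1]], ref = ref)
  nf_db <- stats::quantile(db1, 0.05, names = FALSE)
  frames <- lapply(seq$frames, function(fr) {
    d <- phase_difference_tomogram(fr, seq$tau_s, ref = ref,
                                   noise_floor_db = nf_db)
    if (bulk_correction) d <- bulk_motion_correct(d, lumen_roi = lumen_roi)
    d
  })
  structure(list(frames = frames, t_s = seq$t_s, tau_s = seq$tau_s,
                 lambda0_nm = seq$lambda0_nm, n_index = seq$n_index,
                 axial_px_um = seq$axial_px_um,
                 lateral_px_um = seq$lateral_px_um,
                 channel_id = seq$channel_id,
                 location_offset_mm = seq$location_offset_mm),
            class = "doppler_sequence")
}

#' @export
print.doppler_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$dphi)
  cat(sprintf("<doppler_sequence> %d frames of %d x %d, channel %d\n",
              length(x$frames), d[1], d[2], x$channel_id))
  invisible(x)
}
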