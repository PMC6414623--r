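#' Phantom acquisition configuration
#'
#' Full parameterisation of a synthetic DOCT acquisition of a (partially
#' collapsing) retinal vein: swept-source and scan geometry, acquisition
#' timing for single- or double-channel inter-A-scan-switched operation, the
#' vessel and cardiac models, and the lumen signal-to-noise ratio.
#'
#' In double-channel mode the two beams image laterally separated locations
#' and share the sweep alternately, so the per-channel A-scan rate is
#' `ascan_rate_hz / 2` and each channel's B-scan holds `n_ascans / 2`
#' A-scans over the same scan length.
#'
#' @param lambda0_nm Centre wavelength (nm).
#' @param ascan_rate_hz Total sweep/A-scan rate (Hz).
#' @param n_channels 1 (single-channel) or 2 (inter-A-scan switched).
#' @param channel_separation_mm Lateral offset of the channel-2 B-scan (mm).
#' @param bscan_length_mm Lateral scan length (mm).
#' @param n_ascans A-scans per recorded (interleaved) B-scan.
#' @param frame_rate_fps OCT B-scan frame rate (per channel).
#' @param slo_frame_rate_fps Frame rate of the SLO-like en-face video.
#' @param duration_s Recording length (s); must cover at least two cardiac
#'   cycles.
#' @param depth_px Axial pixels per A-scan.
#' @param axial_px_um,lateral_px_um Pixel pitch; `lateral_px_um` defaults to
#'   the per-channel pitch `bscan_length_mm * 1000 / (n_ascans/n_channels)`.
#' @param tissue_refractive_index Group index used in the Doppler relation.
#' @param vessel A [vessel_model()] (the vein under study).
#' @param artery Optional second [vessel_model()] of kind `"artery"`.
#' @param cardiac A [cardiac_model()].
#' @param snr_db Signal-to-noise ratio (dB) of the resting lumen signal.
#' @param pwv_mm_s Pulse wave velocity carrying the flow waveform from
#'   channel 1 to channel 2 (mm/s); `Inf` means no measurable delay.
#' @param drift_mm_s Optional lateral eye-motion drift of the vessel centre.
#' @param seed Integer RNG seed; identical configurations and seeds give
#'   bit-identical sequences.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(lambda0_nm = 1045,
                           ascan_rate_hz = 1e5,
                           n_channels = 1,
                           channel_separation_mm = 0.9,
                           bscan_length_mm = 0.8,
                           n_ascans = 512,
                           frame_rate_fps = 24,
                           slo_frame_rate_fps = 10,
                           duration_s = 3.2,
                           depth_px = 128,
                           axial_px_um = 3,
                           lateral_px_um = NULL,
                           tissue_refractive_index = 1.38,
                           vessel = vessel_model(center_z_px = depth_px / 2,
                                                 center_x_px =
                                                   n_ascans / n_channels / 2),
                           artery = NULL,
                           cardiac = cardiac_model(),
                           snr_db = 25,
                           pwv_mm_s = Inf,
                           drift_mm_s = 0,
                           seed = 1045L) {
  stopifnot(lambda0_nm > 0, ascan_rate_hz > 0, n_channels %in% c(1, 2),
            bscan_length_mm > 0, n_ascans >= 2, frame_rate_fps > 0,
            slo_frame_rate_fps > 0, duration_s > 0, depth_px >= 8,
            axial_px_um > 0, tissue_refractive_index >= 1,
            inherits(vessel, "vessel_model"), inherits(cardiac, "cardiac_model"))
  if (n_ascans %% n_channels != 0)
    stop("n_ascans must be divisible by n_channels")
  if (duration_s * cardiac$heart_rate_bpm / 60 < 2)
    stop("duration_s must cover at least two cardiac cycles")
  if (is.null(lateral_px_um))
    lateral_px_um <- bscan_length_mm * 1000 / (n_ascans / n_channels)
  structure(list(lambda0_nm = lambda0_nm, ascan_rate_hz = ascan_rate_hz,
                 n_channels = n_channels,
                 channel_separation_mm = channel_separation_mm,
                 bscan_length_mm = bscan_length_mm, n_ascans = n_ascans,
                 frame_rate_fps = frame_rate_fps,
                 slo_frame_rate_fps = slo_frame_rate_fps,
                 duration_s = duration_s, depth_px = depth_px,
                 axial_px_um = axial_px_um, lateral_px_um = lateral_px_um,
                 tissue_refractive_index = tissue_refractive_index,
                 vessel = vessel, artery = artery, cardiac = cardiac,
                 snr_db = snr_db, pwv_mm_s = pwv_mm_s,
                 drift_mm_s = drift_mm_s, seed = as.integer(seed)),
            class = "phantom_config")
}

new_oct_sequence <- function(frames, t_s, tau_s, cfg, channel_id,
                             location_offset_mm, lateral_px_um) {
  structure(list(frames = frames, t_s = t_s, tau_s = tau_s,
                 lambda0_nm = cfg$lambda0_nm,
                 n_index = cfg$tissue_refractive_index,
                 axial_px_um = cfg$axial_px_um,
                 lateral_px_um = lateral_px_um,
                 channel_id = channel_id,
                 location_offset_mm = location_offset_mm,
                 snr_db = cfg$snr_db),
            class = "oct_sequence")
}

#' @export
print.oct_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<oct_sequence> %d frames of %d x %d (depth x A-scans), channel %d\n",
    length(x$frames), d[1], d[2], x$channel_id))
  cat(sprintf("  tau = %.1f us, lambda0 = %g nm, pitch %.2f x %.2f um\n",
              x$tau_s * 1e6, x$lambda0_nm, x$axial_px_um, x$lateral_px_um))
  invisible(x)
}

# Flow drive: 1 + flow_mod * s(t) with s the mean-centred waveform scaled to
# unit maximum absolute deviation, so the drive's peak fractional deviation
# from its mean equals flow_mod.
flow_drive <- function(waveform, flow_mod) {
  s <- waveform - mean(waveform)
  m <- max(abs(s))
  if (m == 0) return(rep(1, length(waveform)))
  1 + flow_mod * s / m
}

# Per-pixel true Doppler phase increment field (radians) plus lumen mask for
# one vessel at one frame. X, Z are pixel-offset grids in um from the vessel
# centre; a, b are the current semi-axes (um).
lumen_dphi_field <- function(vessel, X, Z, a, b, v_center_mm_s,
                             tau_s, lambda0_nm, n_index, lateral_px_um) {
  r2 <- (X / a)^2 + (Z / b)^2
  lum <- r2 < 1
  theta <- vessel$doppler_angle_deg +
    vessel$angle_gradient_deg_per_mm * X * 1e-3
  vz_mm_s <- v_center_mm_s * (1 - r2) * cos(theta * pi / 180)
  dphi <- 4 * pi * n_index * (vz_mm_s * 1e-3) * tau_s / (lambda0_nm * 1e-9)
  dphi[!lum] <- 0
  list(dphi = dphi, lumen = lum)
}

rayleigh_amp <- function(intensity) {
  n <- length(intensity)
  sqrt(intensity / 2) * sqrt(stats::rnorm(n)^2 + stats::rnorm(n)^2)
}

# Simulate one channel: returns oct_sequence plus per-frame ground truth.
simulate_channel <- function(cfg, channel_id, chan_seed) {
  n_x <- cfg$n_ascans / cfg$n_channels
  n_z <- cfg$depth_px
  tau_s <- cfg$n_channels / cfg$ascan_rate_hz
  n_frames <- floor(cfg$duration_s * cfg$frame_rate_fps)
  t_s <- (seq_len(n_frames) - 1) / cfg$frame_rate_fps
  offset_mm <- (channel_id - 1) * cfg$channel_separation_mm
  delay_s <- if (is.finite(cfg$pwv_mm_s)) offset_mm / cfg$pwv_mm_s else 0

  # cardiac drivers; channel 2 sees the waveform delayed by the pulse
  # transit time, and (by construction) a non-collapsing vessel section
  wav <- make_cardiac_waveforms(cfg$cardiac, t_s, seed = cfg$seed)$series
  wav_del <- wav
  if (delay_s > 0) {
    # evaluate the same seeded waveform on the delayed time grid
    starts <- cardiac_cycle_starts(
      cfg$cardiac, t_s[length(t_s)] + 2 * 60 / cfg$cardiac$heart_rate_bpm,
      cfg$seed)
    dt <- 1 / cfg$frame_rate_fps
    td <- pmax(t_s - delay_s, 0)
    art <- arterial_eval(td, starts, cfg$cardiac$arterial_shape)
    pad <- max(1L, ceiling(3 * cfg$cardiac$venous_smoothing_s / dt)) + 4L
    tp <- seq(td[1] - pad * dt, by = dt, length.out = length(td) + 2L * pad)
    ven <- gauss_smooth(arterial_eval(pmax(tp, 0), starts,
                                      cfg$cardiac$arterial_shape),
                        dt, cfg$cardiac$venous_smoothing_s)
    keep <- (pad + 1L):(pad + length(td))
    wav_del <- tibble::tibble(t_s = t_s,
                              arterial = rescale01(art),
                              venous = rescale01(ven[keep]),
                              collapse = wav$collapse)
  }

  vein <- cfg$vessel
  if (channel_id > 1) {  # non-collapsing section at the remote location
    vein$m_lat <- 0
    vein$m_ax <- 0
  }
  collapse <- if (channel_id > 1) rep(0, n_frames) else wav$collapse
  geom <- vessel_geometry_at(vein, collapse)
  drive_wave <- if (vein$kind == "artery") wav_del$arterial else wav_del$venous
  drive <- flow_drive(drive_wave, vein$flow_mod)
  v_center <- vein$v_peak_mm_s * drive
  if (vein$conserve_flow)
    v_center <- v_center * (vein$a0_um * vein$b0_um) / (geom$a_um * geom$b_um)

  art <- cfg$artery
  art_drive <- NULL
  if (!is.null(art)) {
    art_drive <- art$v_peak_mm_s * flow_drive(
      if (art$kind == "artery") wav_del$arterial else wav_del$venous,
      art$flow_mod)
  }

  # static-tissue reflectivity: vitreous (noise only) above, depth-decaying
  # speckle below
  tissue_top <- max(2L, round(n_z / 8))
  z_idx <- seq_len(n_z)
  i_tissue <- ifelse(z_idx <= tissue_top, 0,
                     exp(-(z_idx - tissue_top) / (n_z / 1.5)))
  i_tissue_mat <- matrix(i_tissue, n_z, n_x)
  lumen_refl <- 0.8

  Xc <- outer(rep(1, n_z), seq_len(n_x))  # column index grid
  Zc <- outer(seq_len(n_z), rep(1, n_x))  # row index grid

  # resting lumen signal power sets the noise level for the configured SNR
  X0 <- (Xc - vein$center_x_px) * cfg$lateral_px_um
  Z0 <- (Zc - vein$center_z_px) * cfg$axial_px_um
  lum0 <- (X0 / vein$a0_um)^2 + (Z0 / vein$b0_um)^2 < 1
  p_lumen <- lumen_refl * mean(i_tissue_mat[lum0])
  sigma_n <- if (is.finite(cfg$snr_db))
    sqrt(p_lumen / (2 * 10^(cfg$snr_db / 10))) else 0

  # rest-state wrap check
  rest <- lumen_dphi_field(vein, X0, Z0, vein$a0_um, vein$b0_um,
                           vein$v_peak_mm_s, tau_s, cfg$lambda0_nm,
                           cfg$tissue_refractive_index, cfg$lateral_px_um)
  if (max(abs(rest$dphi)) > pi) warning("phase wrapping in phantom")

  frames <- vector("list", n_frames)
  truth_mean_vz <- numeric(n_frames)
  withr::with_seed(chan_seed, {
    amp_tissue <- matrix(rayleigh_amp(i_tissue_mat), n_z, n_x)
    phase_row <- stats::runif(n_z, -pi, pi)
    phase_static <- matrix(phase_row, n_z, n_x)
    for (f in seq_len(n_frames)) {
      xc_f <- vein$center_x_px + cfg$drift_mm_s * t_s[f] * 1e3 / cfg$lateral_px_um
      X <- (Xc - xc_f) * cfg$lateral_px_um
      Z <- (Zc - vein$center_z_px) * cfg$axial_px_um
      fld <- lumen_dphi_field(vein, X, Z, geom$a_um[f], geom$b_um[f],
                              v_center[f], tau_s, cfg$lambda0_nm,
                              cfg$tissue_refractive_index, cfg$lateral_px_um)
      dphi_field <- fld$dphi
      lumen <- fld$lumen
      theta_eff <- vein$doppler_angle_deg  # mean axial projection for truth
      truth_mean_vz[f] <- v_center[f] / 2 * cos(theta_eff * pi / 180)
      if (!is.null(art)) {
        Xa <- (Xc - art$center_x_px) * cfg$lateral_px_um
        Za <- (Zc - art$center_z_px) * cfg$axial_px_um
        flda <- lumen_dphi_field(art, Xa, Za, art$a0_um, art$b0_um,
                                 art_drive[f], tau_s, cfg$lambda0_nm,
                                 cfg$tissue_refractive_index,
                                 cfg$lateral_px_um)
        dphi_field <- dphi_field + flda$dphi
        lumen <- lumen | flda$lumen
      }
      # lateral cumulative phase: inter-A-scan increment realised as a
      # phase ramp along the fast axis
      cumphase <- t(apply(dphi_field, 1, cumsum))
      amp <- amp_tissue
      i_lum <- lumen_refl * i_tissue_mat[lumen] *
        (1 + vein$intensity_mod * collapse[f])^2
      amp[lumen] <- rayleigh_amp(i_lum)
      field <- complex(modulus = amp, argument = phase_static + cumphase)
      dim(field) <- c(n_z, n_x)
      if (sigma_n > 0) {
        field <- field +
          complex(real = stats::rnorm(n_z * n_x, sd = sigma_n),
                  imaginary = stats::rnorm(n_z * n_x, sd = sigma_n))
        dim(field) <- c(n_z, n_x)
      }
      frames[[f]] <- field
    }
  })

  truth <- tibble::tibble(
    frame = seq_len(n_frames),
    t_s = t_s,
    collapse = collapse,
    true_lat_diameter_um = 2 * geom$a_um,
    true_ax_diameter_um = 2 * geom$b_um,
    true_area_um2 = geom$area_um2,
    true_mean_vz_mm_s = truth_mean_vz,
    true_flow_au = truth_mean_vz * geom$area_um2,
    arterial = wav_del$arterial,
    venous = wav_del$venous)
  attr(truth, "cycle_starts_s") <-
    make_cardiac_waveforms(cfg$cardiac, t_s, seed = cfg$seed)$cycle_starts_s
  attr(truth, "pwv_mm_s") <- cfg$pwv_mm_s

  list(sequence = new_oct_sequence(frames, t_s, tau_s, cfg, channel_id,
                                   offset_mm, cfg$lateral_px_um),
       truth = truth)
}

#' Simulate a complex-valued OCT B-scan sequence
#'
#' Forward model of the acquisition: static tissue is fully developed
#' speckle (Rayleigh amplitudes with depth-decaying mean intensity and
#' laterally coherent phase, the fully-oversampled-beam limit), lumen pixels
#' carry a deterministic inter-A-scan phase increment
#' \eqn{\Delta\phi = 4\pi n v_z \tau / \lambda_0} with parabolic flow on the
#' elliptical lumen projected through the Doppler angle, additive complex
#' Gaussian noise sets the configured lumen SNR, and lumen reflectivity is
#' modulated by the collapse waveform (`intensity_mod`). In double-channel
#' mode channel 2 images a non-collapsing section at
#' `channel_separation_mm`, with its flow waveform delayed by
#' `channel_separation_mm / pwv_mm_s`.
#'
#' @param cfg A [phantom_config()].
#' @return A list of per-channel results, each a list with elements
#'   `sequence` (an `oct_sequence`) and `truth` (ground-truth tibble with
#'   cycle starts and PWV attached as attributes).
#' @export
simulate_complex_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  lapply(seq_len(cfg$n_channels), function(k)
    simulate_channel(cfg, k, chan_seed = cfg$seed + 7919L * k))
}

#' Interleave per-channel sequences into the recorded container
#'
#' Reconstructs the inter-A-scan-switched acquisition stream in which
#' consecutive A-scans alternate between channels; [demux_channels()]
#' inverts this.
#'
#' @param channels List of per-channel `oct_sequence` objects of equal
#'   geometry.
#' @return A single `oct_sequence` whose A-scan period and lateral pitch are
#'   those of the raw interleaved stream.
#' @export
interleave_channels <- function(channels) {
  n <- length(channels)
  stopifnot(n >= 1)
  if (n == 1) return(channels[[1]])
  nx <- ncol(channels[[1]]$frames[[1]])
  frames <- purrr::map(seq_along(channels[[1]]$frames), function(f) {
    out <- matrix(0i, nrow(channels[[1]]$frames[[f]]), nx * n)
    for (k in seq_len(n)) out[, seq(k, nx * n, by = n)] <-
        channels[[k]]$frames[[f]]
    out
  })
  s <- channels[[1]]
  s$frames <- frames
  s$tau_s <- s$tau_s / n
  s$lateral_px_um <- s$lateral_px_um / n
  s$channel_id <- 0L
  s
}
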