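#' Simulate an SLO-like en-face video of the phantom vessel
#'
#' Produces the en-face counterpart of the OCT phantom at the (slower) SLO
#' frame rate: each frame is the depth-integrated reflectivity of the scene,
#' so the vessel appears as a dark band whose width tracks the lateral lumen
#' diameter `2 a(t)` and whose brightness carries the collapse-synchronous
#' hyperreflectivity coupling (`intensity_mod`). The video shares the
#' cardiac ground truth (same seed, same cycle boundaries) with the OCT
#' sequence from the same configuration.
#'
#' @param cfg A [phantom_config()].
#' @param slo_px_um Lateral pixel pitch of the SLO raster (um).
#' @param n_rows Number of slow-axis rows per frame.
#' @param noise_sd Additive Gaussian pixel noise (fraction of background).
#' @return An object of class `slo_sequence`: list with `frames` (list of
#'   matrices, linear intensity), `t_s`, `px_um`, and `truth` (tibble with
#'   the collapse waveform and the true band width per frame).
#' @export
simulate_slo_sequence <- function(cfg, slo_px_um = 5, n_rows = 64,
                                  noise_sd = 0.02) {
  stopifnot(inherits(cfg, "phantom_config"))
  n_frames <- round(cfg$duration_s * cfg$slo_frame_rate_fps)
  t_s <- (seq_len(n_frames) - 1) / cfg$slo_frame_rate_fps
  wav <- make_cardiac_waveforms(cfg$cardiac, t_s, seed = cfg$seed)$series
  vein <- cfg$vessel
  geom <- vessel_geometry_at(vein, wav$collapse)

  n_cols <- round(cfg$bscan_length_mm * 1000 / slo_px_um)
  x_um <- (seq_len(n_cols) - 0.5) * slo_px_um
  xc_um <- vein$center_x_px * cfg$lateral_px_um
  b0 <- 1          # background (perivascular) reflectance
  dark <- 0.45     # relative band reflectance at rest
  edge_um <- 2     # band edge softness

  frames <- withr::with_seed(cfg$seed + 4242L, {
    lapply(seq_len(n_frames), function(f) {
      d <- abs(x_um - xc_um)
      inside <- 1 / (1 + exp((d - geom$a_um[f]) / edge_um))
      band <- dark * (1 + vein$intensity_mod * wav$collapse[f])
      profile <- b0 * (1 - inside) + b0 * band * inside
      img <- matrix(profile, n_rows, n_cols, byrow = TRUE)
      img + matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd * b0),
                   n_rows, n_cols)
    })
  })

  structure(list(frames = frames, t_s = t_s, px_um = slo_px_um,
                 frame_rate_fps = cfg$slo_frame_rate_fps,
                 truth = tibble::tibble(frame = seq_len(n_frames),
                                        t_s = t_s,
                                        collapse = wav$collapse,
                                        true_band_width_um = 2 * geom$a_um)),
            class = "slo_sequence")
}

#' Apparent vessel band width in an SLO frame
#'
#' Measures the dark-band width of one en-face frame from its mean lateral
#' profile by half-depth threshold crossings with linear sub-pixel
#' interpolation.
#'
#' @param slo An `slo_sequence`.
#' @param frame Frame index.
#' @return Width in micrometres (NA if no band is found).
#' @export
slo_band_width <- function(slo, frame) {
  profile <- colMeans(slo$frames[[frame]])
  bg <- stats::median(profile[profile > stats::quantile(profile, 0.6)])
  lo <- min(profile)
  half <- (bg + lo) / 2
  below <- which(profile < half)
  if (length(below) < 2) return(NA_real_)
  i1 <- below[1]; i2 <- below[length(below)]
  # sub-pixel crossings
  f1 <- if (i1 > 1) (profile[i1 - 1] - half) / (profile[i1 - 1] - profile[i1]) else 0
  f2 <- if (i2 < length(profile))
    (profile[i2 + 1] - half) / (profile[i2 + 1] - profile[i2]) else 0
  ((i2 + f2) - (i1 - f1)) * slo$px_um
}
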