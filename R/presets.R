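#' Calibrated phantom presets
#'
#' Named configurations matching the acquisition conditions of the study
#' scenarios the package is tested against:
#'
#' * `phantom_S1` — single-channel, partially collapsing vein with
#'   `m_lat = 0.20`, `m_ax = 0.375` (50% peak area collapse, ~20% peak
#'   transversal diameter change).
#' * `phantom_S2` — as S1 but `m_ax = 0.50` (60% peak area collapse).
#' * `phantom_flow` — double-channel at 0.9 mm separation, mildly collapsing
#'   at the first location and non-collapsing at the second, conserved flow,
#'   `flow_mod = 0.20` (flow oscillations within about +/-20% of the mean),
#'   pulse wave velocity 1000 mm/s.
#' * `phantom_along` — a wide, shallow lumen spanning the scan with the
#'   Doppler angle sweeping linearly through 90 degrees across the B-scan,
#'   producing the characteristic sign flip of the phase-difference signal.
#'
#' Vessel caliber and velocity defaults (`a0 = 60` um semi-axis,
#' `v_peak = 15` mm/s) are plausible values for a major retinal vein at the
#' optic nerve head, not measured values for any particular subject.
#'
#' @param name Preset name.
#' @param seed RNG seed (default 1045).
#' @param snr_db Lumen SNR in dB (default 25).
#' @param ... Further [phantom_config()] overrides.
#' @return A [phantom_config()].
#' @export
phantom_preset <- function(name = c("phantom_S1", "phantom_S2",
                                    "phantom_flow", "phantom_along"),
                           seed = 1045L, snr_db = 25, ...) {
  name <- match.arg(name)
  base <- list(seed = as.integer(seed), snr_db = snr_db)
  cfg_args <- switch(
    name,
    phantom_S1 = c(base, list(
      vessel = vessel_model(center_z_px = 70, center_x_px = 256,
                            a0_um = 60, b0_um = 55,
                            m_lat = 0.20, m_ax = 0.375,
                            v_peak_mm_s = 15, doppler_angle_deg = 70,
                            flow_mod = 0.2, intensity_mod = 0.25,
                            conserve_flow = TRUE, kind = "vein"))),
    phantom_S2 = c(base, list(
      vessel = vessel_model(center_z_px = 70, center_x_px = 256,
                            a0_um = 60, b0_um = 55,
                            m_lat = 0.20, m_ax = 0.50,
                            v_peak_mm_s = 15, doppler_angle_deg = 70,
                            flow_mod = 0.2, intensity_mod = 0.25,
                            conserve_flow = TRUE, kind = "vein"))),
    phantom_flow = c(base, list(
      n_channels = 2, n_ascans = 512, channel_separation_mm = 0.9,
      pwv_mm_s = 1000,
      vessel = vessel_model(center_z_px = 70, center_x_px = 128,
                            a0_um = 60, b0_um = 55,
                            m_lat = 0.10, m_ax = 0.30,
                            v_peak_mm_s = 8, doppler_angle_deg = 70,
                            flow_mod = 0.2, intensity_mod = 0.15,
                            conserve_flow = TRUE, kind = "vein"),
      artery = vessel_model(center_z_px = 96, center_x_px = 64,
                            a0_um = 35, b0_um = 32,
                            v_peak_mm_s = 12, doppler_angle_deg = 70,
                            flow_mod = 0.5, intensity_mod = 0,
                            conserve_flow = FALSE, kind = "artery"))),
    phantom_along = c(base, list(
      vessel = vessel_model(center_z_px = 64, center_x_px = 256,
                            a0_um = 300, b0_um = 40,
                            m_lat = 0, m_ax = 0,
                            v_peak_mm_s = 10, doppler_angle_deg = 90,
                            angle_gradient_deg_per_mm = 30,
                            flow_mod = 0, intensity_mod = 0,
                            conserve_flow = FALSE, kind = "vein"))))
  do.call(phantom_config, utils::modifyList(cfg_args, list(...)))
}
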