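#' Vessel model for the flow phantom
#'
#' Describes a vessel lumen as an ellipse whose lateral and axial semi-axes
#' are modulated independently by the cardiac collapse waveform, with
#' parabolic flow projected onto the imaging beam through the Doppler angle.
#' Independent modulation of the two axes expresses the axial-dominant
#' caliber change of a partially collapsing retinal vein.
#'
#' @param center_z_px,center_x_px Lumen centre in pixels (axial row, lateral
#'   column; 1-based).
#' @param a0_um Resting lateral semi-axis (micrometres).
#' @param b0_um Resting axial semi-axis (micrometres).
#' @param m_lat,m_ax Fractional collapse amplitudes of the lateral and axial
#'   semi-axes, each in `[0, 1)`.
#' @param v_peak_mm_s Resting centreline velocity (mm/s).
#' @param doppler_angle_deg Angle between the flow direction and the imaging
#'   beam, in `(0, 180)` degrees; the axial velocity component is
#'   `v * cos(angle)`.
#' @param flow_mod Fractional amplitude of the flow waveform (peak deviation
#'   of the velocity drive from its mean).
#' @param intensity_mod Fractional lumen hyperreflectivity amplitude coupled
#'   to the collapse waveform.
#' @param conserve_flow If `TRUE`, the centreline velocity is additionally
#'   scaled by `resting area / current area` so that volumetric flow through
#'   the section is preserved during collapse.
#' @param angle_gradient_deg_per_mm Optional lateral gradient of the Doppler
#'   angle across the B-scan (degrees per mm), used to emulate a vessel
#'   running along the scan whose inclination crosses 90 degrees.
#' @param kind `"vein"` or `"artery"`; selects the driving waveform.
#' @return An object of class `vessel_model`.
#' @export
vessel_model <- function(center_z_px, center_x_px,
                         a0_um = 60, b0_um = 55,
                         m_lat = 0, m_ax = 0,
                         v_peak_mm_s = 15,
                         doppler_angle_deg = 70,
                         flow_mod = 0.2,
                         intensity_mod = 0,
                         conserve_flow = TRUE,
                         angle_gradient_deg_per_mm = 0,
                         kind = c("vein", "artery")) {
  kind <- match.arg(kind)
  stopifnot(a0_um > 0, b0_um > 0,
            m_lat >= 0, m_lat < 1, m_ax >= 0, m_ax < 1,
            doppler_angle_deg > 0, doppler_angle_deg < 180)
  structure(list(center_z_px = center_z_px, center_x_px = center_x_px,
                 a0_um = a0_um, b0_um = b0_um,
                 m_lat = m_lat, m_ax = m_ax,
                 v_peak_mm_s = v_peak_mm_s,
                 doppler_angle_deg = doppler_angle_deg,
                 flow_mod = flow_mod,
                 intensity_mod = intensity_mod,
                 conserve_flow = conserve_flow,
                 angle_gradient_deg_per_mm = angle_gradient_deg_per_mm,
                 kind = kind),
            class = "vessel_model")
}

#' Lumen geometry at a given collapse state
#'
#' Evaluates the elliptical lumen semi-axes and cross-sectional area at a
#' collapse value `c` in `[0, 1]`: `a = a0 (1 - m_lat c)`,
#' `b = b0 (1 - m_ax c)`, `area = pi a b`. At full collapse (`c = 1`) the
#' relative area reduction is `1 - (1 - m_lat)(1 - m_ax)`.
#'
#' @param vessel A [vessel_model()].
#' @param collapse_value Collapse state(s) in `[0, 1]` (vectorised).
#' @return Tibble with columns `a_um`, `b_um`, `area_um2`.
#' @export
vessel_geometry_at <- function(vessel, collapse_value) {
  stopifnot(all(collapse_value >= 0 & collapse_value <= 1))
  a <- vessel$a0_um * (1 - vessel$m_lat * collapse_value)
  b <- vessel$b0_um * (1 - vessel$m_ax * collapse_value)
  tibble::tibble(a_um = a, b_um = b, area_um2 = pi * a * b)
}
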