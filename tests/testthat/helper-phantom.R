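# Shared fixtures, generated in code. Expensive preset runs are cached for
# the duration of the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Down-scaled phantom for fast property checks: same physics, smaller frame.
small_phantom <- function(snr_db = 25, seed = 1, m_lat = 0.2, m_ax = 0.4,
                          v_peak_mm_s = 15, duration_s = 2.6,
                          doppler_angle_deg = 70, conserve_flow = TRUE,
                          intensity_mod = 0.25, flow_mod = 0.2,
                          n_channels = 1, ...) {
  phantom_config(
    n_ascans = 160, depth_px = 80, duration_s = duration_s,
    snr_db = snr_db, seed = seed, n_channels = n_channels,
    vessel = vessel_model(center_z_px = 44,
                          center_x_px = 80 / n_channels,
                          a0_um = 50, b0_um = 45,
                          m_lat = m_lat, m_ax = m_ax,
                          v_peak_mm_s = v_peak_mm_s,
                          doppler_angle_deg = doppler_angle_deg,
                          flow_mod = flow_mod,
                          intensity_mod = intensity_mod,
                          conserve_flow = conserve_flow),
    ...)
}

small_roi <- function() list(z = c(22, 66), x = c(55, 105))

# Quantify one channel of a phantom: simulate -> process -> measure.
quantify_phantom <- function(cfg, roi = small_roi(), channel = 1, k = 3) {
  ch <- simulate_complex_sequence(cfg)[[channel]]
  ds <- process_sequence(ch$sequence, lumen_roi = roi)
  m <- measure_sequence(ds, roi = roi, k = k)
  list(truth = ch$truth, doppler = ds, measurements = m,
       pulsatility = pulsatility(m, fps = cfg$frame_rate_fps))
}

s1_report <- function() cached("s1", run_pipeline(run_config(preset = "phantom_S1")))
s2_report <- function() cached("s2", run_pipeline(run_config(preset = "phantom_S2")))
flow_report <- function() cached("flow", run_pipeline(run_config(preset = "phantom_flow")))

# Synthetic doppler_frame with a prescribed dphi image (unit pitches).
synthetic_doppler_frame <- function(dphi, tau_s = 1e-5) {
  structure(list(dphi = dphi,
                 intensity_db = matrix(10, nrow(dphi), ncol(dphi)),
                 mask_valid = matrix(TRUE, nrow(dphi), ncol(dphi)),
                 tau_s = tau_s, noise_floor_db = 0, bulk_corrected = TRUE),
            class = "doppler_frame")
}
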