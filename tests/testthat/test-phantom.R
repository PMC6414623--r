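test_that("identical configuration and seed reproduce the sequence exactly", {
  cfg <- small_phantom(seed = 5, duration_s = 2.2)
  a <- simulate_complex_sequence(cfg)
  b <- simulate_complex_sequence(cfg)
  expect_identical(a[[1]]$sequence$frames, b[[1]]$sequence$frames)
  expect_identical(a[[1]]$truth, b[[1]]$truth)
})

test_that("ground truth satisfies the ellipse area identity", {
  cfg <- small_phantom(seed = 2, duration_s = 2.2)
  tr <- simulate_complex_sequence(cfg)[[1]]$truth
  expect_equal(tr$true_area_um2,
               pi * tr$true_lat_diameter_um / 2 * tr$true_ax_diameter_um / 2)
  expect_equal(nrow(tr), floor(cfg$duration_s * cfg$frame_rate_fps))
})

test_that("measured lumen SNR matches the configured value within 1 dB", {
  cfg <- small_phantom(snr_db = 20, seed = 9, m_lat = 0, m_ax = 0,
                       v_peak_mm_s = 0, intensity_mod = 0, duration_s = 2.2)
  frames <- simulate_complex_sequence(cfg)[[1]]$sequence$frames[1:5]
  v <- cfg$vessel
  X <- outer(rep(1, cfg$depth_px), seq_len(cfg$n_ascans)) - v$center_x_px
  Z <- outer(seq_len(cfg$depth_px), rep(1, cfg$n_ascans)) - v$center_z_px
  lum <- (X * cfg$lateral_px_um / v$a0_um)^2 +
    (Z * cfg$axial_px_um / v$b0_um)^2 < 1
  expect_gt(5 * sum(lum), 1000)  # averaged over > 1e3 lumen pixels
  p_total <- mean(vapply(frames, function(fr) mean(Mod(fr[lum])^2),
                         numeric(1)))
  p_noise <- mean(vapply(frames, function(fr) mean(Mod(fr[1:8, ])^2),
                         numeric(1)))
  snr_est <- 10 * log10((p_total - p_noise) / p_noise)
  expect_lt(abs(snr_est - 20), 1)
})

test_that("static and 90-degree phantoms carry no Doppler signal", {
  # no flow at all
  cfg0 <- small_phantom(v_peak_mm_s = 0, snr_db = Inf, seed = 3,
                        duration_s = 2.2)
  seq0 <- simulate_complex_sequence(cfg0)[[1]]$sequence
  d0 <- phase_difference_tomogram(seq0$frames[[1]], seq0$tau_s)
  expect_lt(max(abs(d0$dphi)), 1e-8)
  # flow perpendicular to the beam
  cfg90 <- small_phantom(doppler_angle_deg = 90, snr_db = Inf, seed = 3,
                         m_lat = 0, m_ax = 0, duration_s = 2.2)
  seq90 <- simulate_complex_sequence(cfg90)[[1]]$sequence
  d90 <- phase_difference_tomogram(seq90$frames[[1]], seq90$tau_s)
  expect_lt(max(abs(d90$dphi)), 1e-8)
})

test_that("Doppler angles theta and 180-theta give opposite-sign signals", {
  mean_lumen_dphi <- function(theta) {
    cfg <- small_phantom(doppler_angle_deg = theta, snr_db = Inf, seed = 4,
                         m_lat = 0, m_ax = 0, duration_s = 2.2)
    s <- simulate_complex_sequence(cfg)[[1]]$sequence
    d <- phase_difference_tomogram(s$frames[[1]], s$tau_s)
    v <- cfg$vessel
    X <- outer(rep(1, cfg$depth_px), seq_len(cfg$n_ascans - 1)) - v$center_x_px
    Z <- outer(seq_len(cfg$depth_px), rep(1, cfg$n_ascans - 1)) - v$center_z_px
    lum <- (X * cfg$lateral_px_um / (0.8 * v$a0_um))^2 +
      (Z * cfg$axial_px_um / (0.8 * v$b0_um))^2 < 1
    mean(d$dphi[lum])
  }
  m70 <- mean_lumen_dphi(70)
  m110 <- mean_lumen_dphi(110)
  expect_gt(m70, 0)
  expect_lt(m110, 0)
  expect_equal(m70, -m110, tolerance = 1e-6)
})

test_that("per-channel A-scan period doubles in double-channel mode", {
  cfg1 <- small_phantom(seed = 6, snr_db = Inf, m_lat = 0, m_ax = 0,
                        duration_s = 2.2)
  cfg2 <- small_phantom(seed = 6, snr_db = Inf, m_lat = 0, m_ax = 0,
                        duration_s = 2.2, n_channels = 2,
                        pwv_mm_s = Inf)
  s1 <- simulate_complex_sequence(cfg1)[[1]]$sequence
  s2 <- simulate_complex_sequence(cfg2)[[1]]$sequence
  expect_equal(s2$tau_s, 2 * s1$tau_s)
  d1 <- phase_difference_tomogram(s1$frames[[1]], s1$tau_s)
  d2 <- phase_difference_tomogram(s2$frames[[1]], s2$tau_s)
  # same physical velocity, doubled tau: lumen phase difference doubles
  lum1 <- abs(d1$dphi) > 0.05
  lum2 <- abs(d2$dphi) > 0.05
  expect_equal(max(d2$dphi[lum2]), 2 * max(d1$dphi[lum1]), tolerance = 0.02)
})

test_that("a phantom beyond the unambiguous velocity range warns", {
  expect_warning(
    simulate_complex_sequence(small_phantom(v_peak_mm_s = 80, snr_db = Inf,
                                            seed = 2, duration_s = 2.2,
                                            conserve_flow = FALSE)),
    "phase wrapping")
})

test_that("SLO video has the configured frame count and width modulation", {
  cfg <- small_phantom(seed = 8, duration_s = 3.2, m_lat = 0.2, m_ax = 0.4)
  slo <- simulate_slo_sequence(cfg, noise_sd = 0.002)
  expect_equal(length(slo$frames), round(cfg$duration_s * 10))
  widths <- vapply(seq_along(slo$frames), function(f) slo_band_width(slo, f),
                   numeric(1))
  mod <- (max(widths) - min(widths)) / max(widths)
  true_mod <- (max(slo$truth$true_band_width_um) -
                 min(slo$truth$true_band_width_um)) /
    max(slo$truth$true_band_width_um)
  expect_equal(mod, true_mod, tolerance = 0.25)
  expect_equal(true_mod, 0.2 * max(slo$truth$collapse), tolerance = 1e-6)
})
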