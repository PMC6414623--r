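test_that("segmentation and measurement recover simple geometric masks", {
  n <- 64
  # disc of radius 10 px, uniform dphi = 0.5, isotropic 5 um pitch
  X <- outer(rep(1, n), seq_len(n)) - 32
  Z <- outer(seq_len(n), rep(1, n)) - 32
  dphi <- ifelse(X^2 + Z^2 < 10^2, 0.5, 0)
  d <- synthetic_doppler_frame(dphi)
  seg <- segment_flow_region(d, axial_px_um = 5, lateral_px_um = 5)
  m <- measure_frame(seg, d)
  # the 3x3 median prefilter erodes a hard binary edge by up to 1 px per
  # side (smooth flow profiles are not affected), so the geometric oracle
  # is exact to 2 px
  expect_lt(abs(m$lat_diameter_um - 100), 2 * 5)
  expect_lt(abs(m$ax_diameter_um - 100), 2 * 5)
  expect_equal(m$area_um2, pi * 50^2, tolerance = 0.1)
  expect_equal(m$mean_dphi_rad, 0.5, tolerance = 1e-6)
  expect_equal(m$flow_au, 0.5 * m$area_um2, tolerance = 1e-4)

  # ellipse with 12 x 6 px semi-axes
  dphi2 <- ifelse((X / 12)^2 + (Z / 6)^2 < 1, 0.4, 0)
  d2 <- synthetic_doppler_frame(dphi2)
  seg2 <- segment_flow_region(d2, axial_px_um = 5, lateral_px_um = 5)
  m2 <- measure_frame(seg2, d2)
  expect_lt(abs(m2$lat_diameter_um - 120), 2 * 5)
  expect_lt(abs(m2$ax_diameter_um - 60), 2 * 5)

  # static frame: empty mask, zero measures, flagged
  d0 <- synthetic_doppler_frame(matrix(0, n, n))
  seg0 <- segment_flow_region(d0, axial_px_um = 5, lateral_px_um = 5)
  expect_true(seg0$empty)
  m0 <- measure_frame(seg0, d0)
  expect_equal(m0$area_um2, 0)
  expect_equal(m0$flow_au, 0)
})

test_that("flow proxy is the signed product of phase and area", {
  expect_equal(flow_proxy(0.5, 2000), 1000)
  expect_equal(flow_proxy(0.7, 0), 0)
  expect_equal(flow_proxy(0, 1500), 0)
  expect_equal(flow_proxy(-0.5, 2000), -1000)  # direction preserved
  expect_error(flow_proxy(0.5, -1))
})

test_that("normalization to the window maximum behaves and is idempotent", {
  expect_equal(normalize_series(c(2, 4, 3)), c(0.5, 1, 0.75))
  expect_equal(normalize_series(rep(5, 4)), rep(1, 4))
  x <- c(0.2, 1, 0.6)
  expect_equal(normalize_series(x), x)
  expect_error(normalize_series(c(0, 0, 0)), "degenerate")
})

test_that("cycle detection finds the synthetic cardiac periodicity", {
  cm <- cardiac_model(heart_rate_bpm = 60, hrv_frac = 0)
  t <- (seq_len(76) - 1) / 24  # 3.2 s at 24 fps
  w <- make_cardiac_waveforms(cm, t, seed = 1)
  cyc <- detect_cycles(w$series$arterial, 24)
  expect_equal(nrow(cyc), 3)
  expect_true(all(abs((cyc$end_idx - cyc$start_idx) - 24) <= 1))
  expect_error(detect_cycles(rep(1, 80), 24), "no cycles detected")
})

test_that("cycle boundaries track ground truth under heart-rate jitter", {
  cfg <- small_phantom(seed = 14, duration_s = 3.2)
  cfg$cardiac$hrv_frac <- 0.1
  q <- quantify_phantom(cfg)
  cyc <- detect_cycles(max(q$measurements$area_um2) - q$measurements$area_um2,
                       24)
  # detected boundaries should sit on the true collapse peaks
  truth_peaks <- sort(pracma::findpeaks(q$truth$collapse,
                                        minpeakheight = 0.5)[, 2])
  for (s in cyc$start_idx)
    expect_lte(min(abs(truth_peaks - s)), 1)
  # and the recovered periods match the true ones within a frame
  expect_true(all(abs(diff(cyc$start_idx) - diff(truth_peaks)) <= 1))
})

test_that("pulsation amplitude is the relative max-min excursion", {
  x <- rep(c(100, 90, 80, 90), 5)
  windows <- tibble::tibble(cycle = 1:4, start_idx = c(1, 5, 9, 13),
                            end_idx = c(5, 9, 13, 17))
  a <- pulsation_amplitude(x, windows, smooth_k = 1)
  expect_equal(a$median, 0.20)
  expect_equal(a$sequence, 0.20)
  const <- pulsation_amplitude(rep(3, 17), windows, smooth_k = 1)
  expect_equal(const$median, 0)
})

test_that("sensitivity ratio arithmetic and degenerate input", {
  expect_equal(sensitivity_ratio(0.60, 0.20), 3.0)
  expect_equal(sensitivity_ratio(0.37, 0.37), 1.0)
  expect_equal(sensitivity_ratio(0.50, 0.20), 2.5)
  expect_error(sensitivity_ratio(0.5, 0), "no lateral pulsation")
})

test_that("noise-free phantom recovery is exact to discretisation", {
  cfg <- small_phantom(snr_db = Inf, seed = 5, m_lat = 0.2, m_ax = 0.4,
                       duration_s = 3.2)
  q <- quantify_phantom(cfg)
  a <- q$pulsatility$amplitudes
  diam_amp <- a$sequence_amplitude[a$trace == "lat_diameter"]
  area_amp <- a$sequence_amplitude[a$trace == "area"]
  # 2 px discretisation bounds on the resting diameter (in relative terms)
  px_tol_lat <- 2 * cfg$lateral_px_um / (2 * cfg$vessel$a0_um)
  expect_lt(abs(diam_amp - 0.2), px_tol_lat)
  expect_lt(abs(area_amp - (1 - 0.8 * 0.6)), 2.5 * px_tol_lat)
})

test_that("segmented area tracks ground truth on the calibrated phantom", {
  rep1 <- s1_report()
  ch <- rep1$channels[[1]]
  tr <- ch$truth
  rest <- which.max(tr$true_area_um2)
  coll <- which.min(tr$true_area_um2)
  expect_lt(abs(ch$measurements$area_um2[rest] - tr$true_area_um2[rest]) /
              tr$true_area_um2[rest], 0.10)
  expect_lt(abs(ch$measurements$area_um2[coll] - tr$true_area_um2[coll]) /
              tr$true_area_um2[coll], 0.15)
  expect_gt(stats::cor(ch$measurements$area_um2, tr$true_area_um2), 0.95)
})

test_that("phase and area pulsate in opposition under conserved flow", {
  rep1 <- s1_report()
  s <- rep1$channels[[1]]$pulsatility$series
  expect_lt(stats::cor(s$norm_mean_dphi, s$norm_area), -0.5)
})

test_that("amplitudes are stable across segmentation thresholds", {
  rep1 <- s1_report()
  ds <- rep1$channels[[1]]$doppler
  roi <- srvpulse:::default_roi(phantom_preset("phantom_S1"))
  amps <- vapply(c(2.5, 3, 3.5), function(k) {
    m <- measure_sequence(ds, roi = roi, k = k)
    p <- pulsatility(m, fps = 24)
    p$amplitudes$sequence_amplitude[p$amplitudes$trace == "area"]
  }, numeric(1))
  expect_lt((max(amps) - min(amps)) / amps[2], 0.10)
})

test_that("amplitude estimation degrades monotonically with noise", {
  true_amp <- 1 - 0.8 * 0.6
  roi <- small_roi()
  err_at <- function(snr_db) {
    errs <- vapply(1:20, function(seed) {
      cfg <- small_phantom(snr_db = snr_db, seed = seed, v_peak_mm_s = 6,
                           duration_s = 2.2)
      q <- quantify_phantom(cfg, roi = roi)
      a <- q$pulsatility$amplitudes
      abs(a$sequence_amplitude[a$trace == "area"] - true_amp)
    }, numeric(1))
    stats::median(errs)
  }
  errs <- vapply(c(30, 25, 20, 15), err_at, numeric(1))
  expect_true(all(diff(errs) >= 0))
})
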