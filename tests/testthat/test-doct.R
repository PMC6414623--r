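test_that("phase wrapping maps onto the half-open principal interval", {
  expect_equal(wrap_phase(0), 0)
  expect_equal(wrap_phase(pi), -pi)       # half-open convention
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  # closure under 2*pi*k shifts, and idempotence
  set.seed(42)
  x <- stats::runif(200, -20, 20)
  for (k in c(-3L, 1L, 5L)) {
    expect_equal(wrap_phase(x + 2 * pi * k), wrap_phase(x), tolerance = 1e-9)
  }
  expect_equal(wrap_phase(wrap_phase(x)), wrap_phase(x))
  expect_true(all(wrap_phase(x) >= -pi & wrap_phase(x) < pi))
})

test_that("intensity tomogram obeys the log law and its floor", {
  fr <- matrix(complex(modulus = 2, argument = 0.3), 4, 5)
  expect_equal(intensity_tomogram(fr, ref = 2),
               matrix(0, 4, 5))
  expect_equal(intensity_tomogram(fr, ref = 0.2),
               matrix(20, 4, 5))
  fr[1, 1] <- 0 + 0i
  expect_equal(intensity_tomogram(fr, ref = 2)[1, 1], -60)
  expect_error(intensity_tomogram(matrix(0i, 3, 3)), "empty frame")
})

test_that("phase-difference tomogram matches the brute-force oracle", {
  set.seed(7)
  for (dims in list(c(4, 4), c(8, 8), c(5, 7))) {
    fr <- matrix(complex(real = stats::rnorm(prod(dims)),
                         imaginary = stats::rnorm(prod(dims))),
                 dims[1], dims[2])
    d <- phase_difference_tomogram(fr, tau_s = 1e-5)
    ref <- matrix(NA_real_, dims[1], dims[2] - 1)
    for (z in seq_len(dims[1])) {
      for (j in seq_len(dims[2] - 1)) {
        ref[z, j] <- Arg(fr[z, j + 1] * Conj(fr[z, j]))
      }
    }
    ref[ref >= pi] <- -pi
    expect_equal(d$dphi, ref, tolerance = 1e-12)
    expect_equal(dim(d$intensity_db), dim(d$dphi))
  }
  expect_error(phase_difference_tomogram(matrix(1 + 0i, 4, 1), 1e-5),
               "at least 2 A-scans")
})

test_that("demux splits interleaved channels and restores their timing", {
  cfg <- small_phantom(seed = 10, n_channels = 2, duration_s = 2.2,
                       pwv_mm_s = 1000)
  chans <- simulate_complex_sequence(cfg)
  inter <- interleave_channels(lapply(chans, `[[`, "sequence"))
  expect_equal(ncol(inter$frames[[1]]), cfg$n_ascans)
  out <- demux_channels(inter, 2)
  expect_length(out, 2)
  expect_identical(out[[1]]$frames, chans[[1]]$sequence$frames)
  expect_identical(out[[2]]$frames, chans[[2]]$sequence$frames)
  expect_equal(out[[1]]$tau_s, inter$tau_s * 2)
  expect_equal(out[[1]]$lateral_px_um, inter$lateral_px_um * 2)
  # identity for a single channel; indivisible count rejected
  expect_identical(demux_channels(out[[1]], 1)[[1]], out[[1]])
  bad <- out[[1]]
  bad$frames <- lapply(bad$frames, function(f) f[, 1:79])
  expect_error(demux_channels(bad, 2), "divisible")
})

test_that("bulk-motion correction removes a constant phase offset", {
  set.seed(3)
  dphi <- matrix(stats::rnorm(60 * 50, sd = 0.02), 60, 50)
  d <- synthetic_doppler_frame(dphi)
  # constant offset restored to zero-median tissue
  d_off <- d
  d_off$dphi <- wrap_phase(d$dphi + 0.3)
  corr <- bulk_motion_correct(d_off)
  expect_lt(abs(stats::median(corr$dphi)), 0.01)
  # near-idempotence without offset
  corr0 <- bulk_motion_correct(d)
  expect_lt(max(abs(corr0$dphi - d$dphi)), 0.05)
  # too few tissue pixels: passed through with a flag
  tiny <- synthetic_doppler_frame(matrix(0.1, 5, 5))
  out <- bulk_motion_correct(tiny)
  expect_true(isTRUE(out$bulk_warning))
  expect_equal(out$dphi, tiny$dphi)
})

test_that("bulk correction leaves the lumen-tissue contrast intact", {
  cfg <- small_phantom(seed = 12, duration_s = 2.2)
  s <- simulate_complex_sequence(cfg)[[1]]$sequence
  roi <- small_roi()
  d <- phase_difference_tomogram(s$frames[[1]], s$tau_s)
  d_off <- d
  d_off$dphi <- wrap_phase(d$dphi + 0.3)
  corr <- bulk_motion_correct(d_off, lumen_roi = roi)
  seg_ref <- segment_flow_region(bulk_motion_correct(d, lumen_roi = roi),
                                 roi = roi)
  seg_off <- segment_flow_region(corr, roi = roi)
  m_ref <- mean(d$dphi[seg_ref$mask])
  m_off <- mean(corr$dphi[seg_off$mask])
  expect_equal(m_off, m_ref, tolerance = 0.05)
})

test_that("the Doppler velocity relation is evaluated correctly", {
  # lambda0 * dphi / (4 pi n tau): 1045 nm, pi/2, 10 us, n = 1.38
  v <- phase_to_velocity(pi / 2, lambda0_nm = 1045, tau_s = 1e-5,
                         n_index = 1.38, theta_deg = 70)
  expect_equal(v$v_axial_mm_s, 9.4656, tolerance = 1e-4)
  expect_equal(v$v_abs_mm_s, v$v_axial_mm_s / cos(70 * pi / 180))
  expect_equal(phase_to_velocity(0, 1045, 1e-5)$v_axial_mm_s, 0)
  # geometry unsuitable near 90 degrees
  v90 <- phase_to_velocity(0.5, 1045, 1e-5, theta_deg = 90)
  expect_true(v90$undetermined)
  expect_true(is.na(v90$v_abs_mm_s))
  expect_false(phase_to_velocity(0.5, 1045, 1e-5, theta_deg = 80)$undetermined)
})

test_that("mean lumen phase difference scales linearly with velocity", {
  mean_lumen <- function(v_peak) {
    cfg <- small_phantom(v_peak_mm_s = v_peak, snr_db = Inf, seed = 4,
                         m_lat = 0, m_ax = 0, duration_s = 2.2)
    s <- simulate_complex_sequence(cfg)[[1]]$sequence
    d <- phase_difference_tomogram(s$frames[[1]], s$tau_s)
    mean(d$dphi[abs(d$dphi) > 1e-9])
  }
  expect_equal(mean_lumen(10), 2 * mean_lumen(5), tolerance = 1e-3)
})

test_that("a pure-noise sequence yields no spurious flow detections", {
  set.seed(31)
  n_z <- 60; n_x <- 120
  frames <- lapply(1:3, function(i)
    matrix(complex(real = stats::rnorm(n_z * n_x, sd = 0.01),
                   imaginary = stats::rnorm(n_z * n_x, sd = 0.01)),
           n_z, n_x))
  d <- phase_difference_tomogram(frames[[1]], 1e-5)
  sig <- srvpulse:::circ_sd(d$dphi[d$mask_valid])
  frac <- mean(abs(d$dphi[d$mask_valid]) > 3 * sig)
  expect_lte(frac, 0.01)
})
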