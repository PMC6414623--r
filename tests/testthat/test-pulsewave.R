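# waveform sampled with an arbitrary (possibly fractional-frame) delay
delayed_trace <- function(delay_frames, fps = 24, n = 77, seed = 2) {
  cm <- cardiac_model(hrv_frac = 0.05)
  t <- (seq_len(n) - 1 + 20) / fps  # offset so delayed times stay positive
  starts <- srvpulse:::cardiac_cycle_starts(cm, max(t) + 2, seed)
  srvpulse:::arterial_eval(t - delay_frames / fps, starts, cm$arterial_shape)
}

test_that("self-delay is zero and below the detectability threshold", {
  a <- delayed_trace(0)
  d <- estimate_delay(a, a, fps = 24)
  expect_equal(d$delay_frames, 0, tolerance = 1e-6)
  expect_false(d$detectable)
})

test_that("an integer two-frame shift is recovered exactly", {
  a <- delayed_trace(0)
  b <- delayed_trace(2)
  d <- estimate_delay(a, b, fps = 24)
  expect_equal(round(d$delay_frames), 2)
  expect_lt(abs(d$delay_frames - 2), 0.1)
  expect_true(d$detectable)
})

test_that("the one-frame detectability threshold is exact", {
  a <- delayed_trace(0)
  d_low <- estimate_delay(a, delayed_trace(0.9), fps = 24)
  d_high <- estimate_delay(a, delayed_trace(1.1), fps = 24)
  expect_false(d_low$detectable)
  expect_true(d_high$detectable)
})

test_that("delay estimation is antisymmetric", {
  a <- delayed_trace(0)
  b <- delayed_trace(3)
  dab <- estimate_delay(a, b, fps = 24)
  dba <- estimate_delay(b, a, fps = 24)
  expect_equal(dab$delay_frames, -dba$delay_frames, tolerance = 0.1)
  expect_error(estimate_delay(rep(1, 50), rep(1, 50), 24),
               "no pulsatile content")
})

test_that("PWV conversion and the resolvability bound", {
  d <- tibble::tibble(delay_s = 0.05, delay_frames = 1.2, detectable = TRUE)
  p <- pwv_from_delay(d, separation_mm = 0.9, fps = 24)
  expect_equal(p$pwv_mm_s, 18)
  d2 <- tibble::tibble(delay_s = 0.009, delay_frames = 0.22,
                       detectable = FALSE)
  p2 <- pwv_from_delay(d2, separation_mm = 0.9, fps = 24)
  expect_true(is.na(p2$pwv_mm_s))
  expect_equal(p2$max_resolvable_pwv_mm_s, 21.6)
  # limit case: one-frame delay at 24 fps over 0.9 mm
  d3 <- tibble::tibble(delay_s = 1 / 24, delay_frames = 1, detectable = TRUE)
  expect_equal(pwv_from_delay(d3, 0.9, 24)$pwv_mm_s, 21.6)
  expect_error(pwv_from_delay(d3, 0, 24), "zero separation")
})

test_that("flow conservation metrics behave on known inputs", {
  a <- delayed_trace(0)
  c0 <- check_flow_conservation(a, a, 0, 24)
  expect_equal(c0$rmsd, 0)
  expect_equal(c0$r, 1)
  set.seed(99)
  n1 <- stats::rnorm(80)
  n2 <- stats::rnorm(80)
  cn <- check_flow_conservation(n1, n2, 0, 24)
  expect_lt(abs(cn$r), 0.3)
})

test_that("flow is conserved across the collapse site on dual phantoms", {
  rs <- vapply(1:20, function(seed) {
    cfg <- small_phantom(seed = seed, n_channels = 2, pwv_mm_s = 1000,
                         duration_s = 2.2, m_lat = 0.1, m_ax = 0.3,
                         v_peak_mm_s = 8)
    roi <- list(z = c(22, 66), x = c(15, 65))
    qa <- quantify_phantom(cfg, roi = roi, channel = 1)
    qb <- quantify_phantom(cfg, roi = roi, channel = 2)
    check_flow_conservation(qa$pulsatility$series$norm_flow,
                            qb$pulsatility$series$norm_flow, 0, 24)$r
  }, numeric(1))
  expect_gt(stats::median(rs), 0.8)
  expect_gt(min(rs), 0.5)
})

test_that("arterial pulsation exceeds venous flow pulsation on phantoms", {
  repf <- flow_report()
  cfgf <- phantom_preset("phantom_flow")
  art <- cfgf$artery
  roi_art <- list(z = c(art$center_z_px - 14, art$center_z_px + 14),
                  x = c(art$center_x_px - 14, art$center_x_px + 14))
  ds <- repf$channels[[2]]$doppler
  m_art <- measure_sequence(ds, roi = roi_art)
  p_art <- pulsatility(m_art, fps = 24,
                       reference = repf$channels[[2]]$truth$arterial)
  amp <- function(p) p$amplitudes$sequence_amplitude[
    p$amplitudes$trace == "flow"]
  expect_gt(amp(p_art), amp(repf$channels[[2]]$pulsatility))
})
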