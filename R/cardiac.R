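#' Cardiac driver model
#'
#' Parameterises the cardiac waveforms that drive the phantom: an arterial
#' pulse (sharp systolic peak plus dicrotic notch), a venous flow profile
#' (the arterial profile low-pass filtered, giving the washed-out venous
#' pulse shape), and the venous collapse waveform that modulates the lumen
#' geometry. Cycle-to-cycle period jitter models heart-rate variability.
#'
#' @param heart_rate_bpm Mean heart rate in beats per minute.
#' @param hrv_frac Fractional per-cycle period jitter, in `[0, 0.3)`; each
#'   cycle period is drawn uniformly from
#'   `60/heart_rate_bpm * (1 +/- hrv_frac)`.
#' @param arterial_shape List with elements `peak_frac` (systolic peak time
#'   as fraction of the cycle), `width_frac` (Gaussian peak width, fraction
#'   of cycle), `dicrotic_amp` (relative amplitude of the dicrotic bump) and
#'   `dicrotic_frac` (its timing, fraction of cycle).
#' @param venous_smoothing_s Standard deviation (seconds) of the Gaussian
#'   kernel that turns the arterial profile into the venous one.
#' @param collapse_phase_offset_s Lag (seconds) of the venous collapse peak
#'   relative to the arterial peak; 0 means the collapse peaks coincide with
#'   the arterial systolic peaks.
#' @return An object of class `cardiac_model`.
#' @export
cardiac_model <- function(heart_rate_bpm = 60,
                          hrv_frac = 0.05,
                          arterial_shape = list(peak_frac = 0.15,
                                                width_frac = 0.055,
                                                dicrotic_amp = 0.25,
                                                dicrotic_frac = 0.45),
                          venous_smoothing_s = 0.08,
                          collapse_phase_offset_s = 0) {
  stopifnot(heart_rate_bpm > 0, hrv_frac >= 0, hrv_frac < 0.3,
            venous_smoothing_s >= 0)
  shp <- utils::modifyList(
    list(peak_frac = 0.15, width_frac = 0.055,
         dicrotic_amp = 0.25, dicrotic_frac = 0.45),
    arterial_shape)
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 hrv_frac = hrv_frac,
                 arterial_shape = shp,
                 venous_smoothing_s = venous_smoothing_s,
                 collapse_phase_offset_s = collapse_phase_offset_s),
            class = "cardiac_model")
}

# Draw the cycle start times covering [0, duration_s] (plus one spare cycle),
# deterministically from `seed`. Returns numeric vector of starts beginning
# at 0; successive differences are the per-cycle periods.
cardiac_cycle_starts <- function(cardiac, duration_s, seed) {
  t0 <- 60 / cardiac$heart_rate_bpm
  n_max <- ceiling(duration_s / (t0 * (1 - cardiac$hrv_frac))) + 2L
  periods <- withr::with_seed(seed, {
    t0 * (1 + cardiac$hrv_frac * stats::runif(n_max, -1, 1))
  })
  cumsum(c(0, periods))
}

# Evaluate the raw (unnormalised) arterial waveform at times t_s given the
# cycle start grid. Each cycle is a unit-amplitude Gaussian systolic peak
# plus a dicrotic bump, expressed in cycle-phase coordinates.
arterial_eval <- function(t_s, starts, shape) {
  idx <- findInterval(t_s, starts)
  idx[idx < 1L] <- 1L
  idx[idx >= length(starts)] <- length(starts) - 1L
  period <- starts[idx + 1L] - starts[idx]
  phi <- (t_s - starts[idx]) / period
  exp(-(phi - shape$peak_frac)^2 / (2 * shape$width_frac^2)) +
    shape$dicrotic_amp *
      exp(-(phi - shape$dicrotic_frac)^2 / (2 * (2 * shape$width_frac)^2))
}

# Gaussian smoothing on a uniform grid with edge padding; sigma in seconds.
gauss_smooth <- function(x, dt, sigma_s) {
  if (sigma_s <= 0 || sigma_s < dt / 20) return(x)
  half <- max(1L, ceiling(3 * sigma_s / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = sigma_s)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + length(x))]
}

rescale01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Generate cardiac waveforms on a time grid
#'
#' Produces the arterial, venous and collapse driver series used by the
#' phantom, together with the true cycle boundaries. All series are scaled
#' to `[0, 1]`. The venous series is the arterial series convolved with a
#' Gaussian kernel of width `venous_smoothing_s`; the collapse series is the
#' venous series delayed by `collapse_phase_offset_s`, so with the default
#' zero offset its per-cycle peaks coincide with the arterial peaks.
#'
#' @param cardiac A [cardiac_model()].
#' @param t_s Uniform, increasing time grid (seconds) spanning at least two
#'   cardiac periods.
#' @param seed Integer seed for the heart-rate-variability draw.
#' @return A list with `series` (tibble: `t_s`, `arterial`, `venous`,
#'   `collapse`) and `cycle_starts_s` (starts falling inside the grid span).
#' @export
make_cardiac_waveforms <- function(cardiac, t_s, seed = 1045L) {
  stopifnot(inherits(cardiac, "cardiac_model"), length(t_s) >= 2)
  dt <- diff(t_s)
  if (any(abs(dt / dt[1] - 1) > 0.01)) stop("time grid must be uniform")
  dt <- dt[1]
  span <- t_s[length(t_s)] - t_s[1] + dt
  period <- 60 / cardiac$heart_rate_bpm
  if (span < period) stop("insufficient duration")
  starts <- cardiac_cycle_starts(cardiac, t_s[length(t_s)] + 2 * period, seed)

  # evaluate on a padded grid so the smoothing kernel sees complete cycles
  pad <- max(1L, ceiling(3 * cardiac$venous_smoothing_s / dt)) +
    ceiling(period / dt)
  tp <- seq(t_s[1] - pad * dt, by = dt, length.out = length(t_s) + 2L * pad)
  art_p <- arterial_eval(pmax(tp, 0), starts, cardiac$arterial_shape)
  ven_p <- gauss_smooth(art_p, dt, cardiac$venous_smoothing_s)
  col_t <- pmax(tp - cardiac$collapse_phase_offset_s, 0)
  col_p <- gauss_smooth(arterial_eval(col_t, starts, cardiac$arterial_shape),
                        dt, cardiac$venous_smoothing_s)
  keep <- (pad + 1L):(pad + length(t_s))
  series <- tibble::tibble(
    t_s = t_s,
    arterial = rescale01(art_p[keep]),
    venous = rescale01(ven_p[keep]),
    collapse = rescale01(col_p[keep]))
  list(series = series,
       cycle_starts_s = starts[starts >= t_s[1] - 1e-9 &
                                 starts <= t_s[length(t_s)] + 1e-9])
}
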