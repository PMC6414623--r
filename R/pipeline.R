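# Polynomial rolling hash over the serialised scientific configuration
# (output locations excluded): a stable fingerprint for provenance logging
# without external hashing dependencies.
config_fingerprint <- function(x) {
  x$output_dir <- NULL
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Default search ROI around the configured vessel centre, spanning 1.6 x
# the resting semi-axes.
default_roi <- function(cfg) {
  v <- cfg$vessel
  nx <- cfg$n_ascans / cfg$n_channels
  hw_x <- ceiling(1.6 * v$a0_um / cfg$lateral_px_um)
  hw_z <- ceiling(1.6 * v$b0_um / cfg$axial_px_um)
  list(z = c(max(1, round(v$center_z_px) - hw_z),
             min(cfg$depth_px, round(v$center_z_px) + hw_z)),
       x = c(max(1, round(v$center_x_px) - hw_x),
             min(nx - 1, round(v$center_x_px) + hw_x)))
}

#' Assemble a pipeline run configuration
#'
#' @param preset Optional phantom preset name (see [phantom_preset()]).
#' @param phantom Optional explicit [phantom_config()].
#' @param input_path Optional path to a stored `oct_sequence` container
#'   (exclusive with `preset`/`phantom`).
#' @param processing List: `bulk_correction` (default TRUE), `threshold_k`
#'   (default 3).
#' @param quantify List: `roi` (default derived from the phantom geometry),
#'   `bpm_range`, `smooth_k`.
#' @param pulsewave List: `separation_mm` (default from the phantom), `fps`.
#' @param intensity List: `roi` (default centred on the lumen), `slo`
#'   (simulate and compare the SLO-like video; default TRUE for phantoms).
#' @param output_dir Output directory (created if needed); `NULL` disables
#'   file output.
#' @param seed Seed overriding the phantom seed.
#' @return List of class `srvp_run_config`.
#' @export
run_config <- function(preset = NULL, phantom = NULL, input_path = NULL,
                       processing = list(), quantify = list(),
                       pulsewave = list(), intensity = list(),
                       output_dir = NULL, seed = NULL) {
  n_src <- (!is.null(preset) || !is.null(phantom)) + !is.null(input_path)
  if (n_src != 1)
    stop("exactly one of preset/phantom or input_path must be given")
  if (!is.null(preset) && !is.null(phantom))
    stop("give either a preset name or an explicit phantom config")
  if (!is.null(input_path) && !file.exists(input_path))
    stop("input_path does not exist: ", input_path)
  structure(list(preset = preset, phantom = phantom, input_path = input_path,
                 processing = utils::modifyList(
                   list(bulk_correction = TRUE, threshold_k = 3), processing),
                 quantify = utils::modifyList(
                   list(roi = NULL, bpm_range = c(40, 120), smooth_k = 3),
                   quantify),
                 pulsewave = utils::modifyList(
                   list(separation_mm = NULL, fps = NULL), pulsewave),
                 intensity = utils::modifyList(
                   list(roi = NULL, slo = TRUE), intensity),
                 output_dir = output_dir, seed = seed),
            class = "srvp_run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [run_config()] fields; the `phantom`
#'   block, if present, is passed to [phantom_config()] (with nested
#'   `vessel`/`artery`/`cardiac` blocks).
#' @return A `srvp_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  phantom <- NULL
  if (!is.null(y$phantom)) {
    ph <- y$phantom
    if (!is.null(ph$vessel)) ph$vessel <- do.call(vessel_model, ph$vessel)
    if (!is.null(ph$artery)) ph$artery <- do.call(vessel_model, ph$artery)
    if (!is.null(ph$cardiac)) ph$cardiac <- do.call(cardiac_model, ph$cardiac)
    phantom <- do.call(phantom_config, ph)
  }
  run_config(preset = y$preset, phantom = phantom, input_path = y$input_path,
             processing = if (is.null(y$processing)) list() else y$processing,
             quantify = if (is.null(y$quantify)) list() else y$quantify,
             pulsewave = if (is.null(y$pulsewave)) list() else y$pulsewave,
             intensity = if (is.null(y$intensity)) list() else y$intensity,
             output_dir = y$output_dir, seed = y$seed)
}

#' Run the full SRVP analysis pipeline
#'
#' Orchestrates simulate (or load), Doppler processing, lumen
#' quantification, dual-site pulse-wave analysis (when two channels are
#' present) and ROI intensity tracking (OCT and, for phantom input, the
#' SLO-like video) from a single configuration. All randomness derives from
#' the single seed, so re-running an identical configuration reproduces all
#' numeric outputs exactly.
#'
#' @param cfg A `srvp_run_config` (or a YAML path accepted by
#'   [read_run_config()]).
#' @return Object of class `srvp_report`: list with per-channel
#'   `measurements` and `pulsatility`, `pulse_wave`, `intensity`,
#'   `summary` (named list of headline metrics) and `log` (stage timings).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "srvp_run_config"))
  out_dir <- cfg$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      if (!is.null(out_dir))
        writeLines(c(name, conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  # --- simulate / load -------------------------------------------------
  phantom_cfg <- NULL
  if (is.null(cfg$input_path)) {
    phantom_cfg <- if (!is.null(cfg$phantom)) cfg$phantom else
      phantom_preset(cfg$preset,
                     seed = if (is.null(cfg$seed)) 1045L else cfg$seed)
    if (!is.null(cfg$seed)) phantom_cfg$seed <- as.integer(cfg$seed)
  }
  sim <- stage("simulate", {
    if (!is.null(cfg$input_path)) {
      list(list(sequence = read_oct_sequence(cfg$input_path), truth = NULL))
    } else {
      simulate_complex_sequence(phantom_cfg)
    }
  })

  roi <- cfg$quantify$roi
  if (is.null(roi) && !is.null(phantom_cfg)) roi <- default_roi(phantom_cfg)

  # --- process + quantify ---------------------------------------------
  fps <- if (!is.null(phantom_cfg)) phantom_cfg$frame_rate_fps else
    1 / stats::median(diff(sim[[1]]$sequence$t_s))
  channels <- stage("quantify", lapply(sim, function(ch) {
    ds <- process_sequence(ch$sequence,
                           bulk_correction = cfg$processing$bulk_correction,
                           lumen_roi = roi)
    m <- measure_sequence(ds, roi = roi, k = cfg$processing$threshold_k)
    p <- pulsatility(m, fps = fps, bpm_range = cfg$quantify$bpm_range,
                     smooth_k = cfg$quantify$smooth_k)
    list(doppler = ds, measurements = m, pulsatility = p, truth = ch$truth)
  }))

  # --- pulse wave (dual site) -----------------------------------------
  pw <- NULL
  if (length(channels) >= 2) {
    sep <- cfg$pulsewave$separation_mm
    if (is.null(sep)) sep <- phantom_cfg$channel_separation_mm
    pw_fps <- if (is.null(cfg$pulsewave$fps)) fps else cfg$pulsewave$fps
    pw <- stage("pulse_wave", pulse_wave_analysis(
      channels[[1]]$pulsatility$series$norm_flow,
      channels[[2]]$pulsatility$series$norm_flow,
      fps = pw_fps, separation_mm = sep))
  }

  # --- intensity pulsatility ------------------------------------------
  intens <- NULL
  iroi <- cfg$intensity$roi
  if (is.null(iroi) && !is.null(phantom_cfg)) {
    v <- phantom_cfg$vessel
    hw_x <- ceiling(0.6 * v$a0_um / phantom_cfg$lateral_px_um)
    hw_z <- ceiling(0.6 * v$b0_um / phantom_cfg$axial_px_um)
    iroi <- list(z = c(round(v$center_z_px) - hw_z,
                       round(v$center_z_px) + hw_z),
                 x = c(round(v$center_x_px) - hw_x,
                       round(v$center_x_px) + hw_x))
  }
  if (!is.null(iroi)) {
    intens <- stage("intensity", {
      oct_i <- roi_mean_intensity(channels[[1]]$doppler, iroi)
      slo_cmp <- NULL
      if (isTRUE(cfg$intensity$slo) && !is.null(phantom_cfg)) {
        slo <- simulate_slo_sequence(phantom_cfg)
        xc_um <- phantom_cfg$vessel$center_x_px * phantom_cfg$lateral_px_um
        sx <- round(xc_um / slo$px_um)
        sroi <- list(z = c(1, nrow(slo$frames[[1]])),
                     x = c(max(1, sx - 6), sx + 6))
        slo_i <- roi_mean_intensity(slo, sroi)
        slo_cmp <- compare_modalities(oct_i, slo_i)
      }
      list(oct = oct_i, slo_comparison = slo_cmp)
    })
  }

  # --- summary ---------------------------------------------------------
  p1 <- channels[[1]]$pulsatility
  a1 <- p1$amplitudes
  seq_amp <- function(trace)
    a1$sequence_amplitude[a1$trace == trace]
  summary <- list(
    preset = if (is.null(cfg$preset)) NA_character_ else cfg$preset,
    seed = if (!is.null(phantom_cfg)) phantom_cfg$seed else NA_integer_,
    config_fingerprint = config_fingerprint(cfg),
    n_channels = length(channels),
    diameter_amplitude_pct = 100 * seq_amp("lat_diameter"),
    area_amplitude_pct = 100 * seq_amp("area"),
    sensitivity_ratio = p1$sensitivity_ratio,
    flow_oscillation_pct = 100 * p1$flow_deviation,
    delay_s = if (is.null(pw)) NA_real_ else pw$delay_s,
    delay_detectable = if (is.null(pw)) NA else pw$detectable,
    pwv_mm_s = if (is.null(pw)) NA_real_ else pw$pwv_mm_s,
    max_resolvable_pwv_mm_s = if (is.null(pw)) NA_real_
      else pw$max_resolvable_pwv_mm_s,
    conservation_r = if (is.null(pw)) NA_real_ else pw$r,
    intensity_modality_r = if (is.null(intens) ||
                                 is.null(intens$slo_comparison)) NA_real_
      else intens$slo_comparison$r)

  if (!is.null(out_dir)) {
    for (k in seq_along(channels)) {
      mm <- dplyr::left_join(channels[[k]]$measurements,
                             channels[[k]]$pulsatility$series[
                               , c("frame", "cycle")], by = "frame")
      write_measurements_csv(mm, file.path(out_dir,
                                           sprintf("measurements_ch%d.csv", k)))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE)
  }

  structure(list(channels = channels, pulse_wave = pw, intensity = intens,
                 summary = summary, log = log, config = cfg),
            class = "srvp_report")
}

#' @export
print.srvp_report <- function(x, ...) {
  s <- x$summary
  cat("<srvp_report>\n")
  cat(sprintf("  diameter change: %.1f%%  area change: %.1f%%  ratio: %.2f\n",
              s$diameter_amplitude_pct, s$area_amplitude_pct,
              s$sensitivity_ratio))
  cat(sprintf("  flow oscillation: +/-%.1f%%\n", s$flow_oscillation_pct))
  if (!is.na(s$delay_s))
    cat(sprintf("  inter-site delay: %.4f s (%s), conservation r = %.2f\n",
                s$delay_s,
                if (isTRUE(s$delay_detectable)) "detectable"
                else "not detectable",
                s$conservation_r))
  if (!is.na(s$intensity_modality_r))
    cat(sprintf("  OCT/SLO intensity correlation: %.2f\n",
                s$intensity_modality_r))
  invisible(x)
}

#' Validate a pipeline summary against the shipped schema
#'
#' Checks the summary produced by [run_pipeline()] against the JSON schema
#' description in `inst/extdata/summary-schema.json` (required field names
#' and types).
#'
#' @param summary Named list (or path to a `summary.json`).
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  schema <- jsonlite::read_json(system.file("extdata", "summary-schema.json",
                                            package = "srvpulse"),
                                simplifyVector = TRUE)
  missing <- setdiff(schema$required, names(summary))
  if (length(missing) > 0)
    stop("summary missing fields: ", paste(missing, collapse = ", "))
  for (nm in names(schema$properties)) {
    if (!nm %in% names(summary)) next
    v <- summary[[nm]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    ok <- switch(schema$properties[[nm]],
                 number = is.numeric(v),
                 integer = is.numeric(v) && v == round(v),
                 string = is.character(v),
                 boolean = is.logical(v),
                 TRUE)
    if (!ok) stop(sprintf("summary field '%s' is not of type '%s'",
                          nm, schema$properties[[nm]]))
  }
  invisible(TRUE)
}
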