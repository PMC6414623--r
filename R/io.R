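#' Write / read a complex tomogram sequence
#'
#' Serialises an `oct_sequence` (frames, timestamps and all acquisition
#' metadata) to a single container file using R's native serialisation.
#'
#' @param seq An `oct_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oct_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "oct_sequence"))
  saveRDS(seq, path)
  invisible(path)
}

#' @rdname write_oct_sequence
#' @export
read_oct_sequence <- function(path) {
  seq <- readRDS(path)
  if (!inherits(seq, "oct_sequence")) stop("not an oct_sequence container")
  seq
}

#' Write an SLO sequence as multi-page 16-bit TIFF
#'
#' Frames are scaled to the common maximum and written as grayscale 16-bit
#' pages; a JSON sidecar (`<path>.json`) records timestamps, pixel pitch and
#' the intensity scale needed to restore linear units.
#'
#' @param slo An `slo_sequence`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slo_tiff <- function(slo, path) {
  stopifnot(inherits(slo, "slo_sequence"))
  scale <- max(vapply(slo$frames, max, numeric(1)))
  pages <- lapply(slo$frames, function(fr) pmin(pmax(fr / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(t_s = slo$t_s, px_um = slo$px_um,
               frame_rate_fps = slo$frame_rate_fps, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_slo_tiff
#' @export
read_slo_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) p * meta$intensity_scale)
  structure(list(frames = frames, t_s = meta$t_s, px_um = meta$px_um,
                 frame_rate_fps = meta$frame_rate_fps, truth = NULL),
            class = "slo_sequence")
}

#' Write per-frame measurements to CSV
#'
#' @param measurements Tibble from [measure_sequence()], optionally with a
#'   `cycle` column merged in.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  utils::write.csv(as.data.frame(measurements), path, row.names = FALSE)
  invisible(path)
}
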