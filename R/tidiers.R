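#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pulsatility analysis
#'
#' One row per trace and cycle with the relative pulsation amplitude.
#'
#' @param x A `srvp_pulsatility`.
#' @param ... Unused.
#' @return Tibble: `trace`, `cycle`, `amplitude`.
#' @method tidy srvp_pulsatility
#' @export
tidy.srvp_pulsatility <- function(x, ...) {
  cols <- c(lat_diameter = "norm_lat_diameter", area = "norm_area",
            mean_dphi = "norm_mean_dphi", flow = "norm_flow")
  purrr::imap_dfr(cols, function(col, nm) {
    dplyr::transmute(
      dplyr::filter(x$series, !is.na(.data$cycle)),
      trace = nm, cycle = .data$cycle, value = .data[[col]]) |>
      dplyr::group_by(.data$trace, .data$cycle) |>
      dplyr::summarise(amplitude = (max(.data$value) - min(.data$value)) /
                         max(.data$value), .groups = "drop")
  })
}

#' One-row summary of a pulsatility analysis
#'
#' @param x A `srvp_pulsatility`.
#' @param ... Unused.
#' @return One-row tibble with the per-sequence amplitudes, sensitivity
#'   ratio, flow deviation and cycle count.
#' @method glance srvp_pulsatility
#' @export
glance.srvp_pulsatility <- function(x, ...) {
  a <- x$amplitudes
  g <- function(tr) a$sequence_amplitude[a$trace == tr]
  tibble::tibble(diameter_amplitude = g("lat_diameter"),
                 area_amplitude = g("area"),
                 mean_dphi_amplitude = g("mean_dphi"),
                 flow_amplitude = g("flow"),
                 sensitivity_ratio = x$sensitivity_ratio,
                 flow_deviation = x$flow_deviation,
                 n_cycles = nrow(x$cycles))
}

#' @rdname tidy.srvp_pulsatility
#' @method tidy srvp_pulsewave
#' @export
tidy.srvp_pulsewave <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname glance.srvp_pulsatility
#' @method glance srvp_report
#' @export
glance.srvp_report <- function(x, ...) {
  tibble::as_tibble(x$summary[!vapply(x$summary, is.null, logical(1))])
}
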