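#' Probe geometry
#'
#' Describes the optical probe: a single effective source-detector
#' separation shared by the TD-NIRS and DCS channels, the TD-NIRS emission
#' wavelengths, the DCS wavelength, and the pulsed-laser repetition rate.
#' The DCS dual-injection arc is retained for bookkeeping only; both
#' injection points sit at the same effective separation, so the forward
#' models use `rho` alone and the doubled detected intensity enters as a
#' count-rate factor.
#'
#' @param rho source-detector separation in cm (default 2.5).
#' @param wavelengths TD-NIRS wavelengths in nm (default c(685, 828)).
#' @param dcs_wavelength DCS wavelength in nm (default 785).
#' @param rep_rate laser repetition rate in MHz (default 53).
#' @param dual_source_arc arc between the two DCS injection points, mm.
#' @return an object of class `probe_geometry`.
#' @export
probe_geometry <- function(rho = 2.5, wavelengths = c(685, 828),
                           dcs_wavelength = 785, rep_rate = 53,
                           dual_source_arc = 3.5) {
  stop_if_not_scalar_pos(rho, "rho")
  stop_if_not_scalar_pos(rep_rate, "rep_rate")
  stopifnot(all(wavelengths > 0), dcs_wavelength > 0)
  structure(list(rho = rho, wavelengths = wavelengths,
                 dcs_wavelength = dcs_wavelength, rep_rate = rep_rate,
                 dual_source_arc = dual_source_arc),
            class = "probe_geometry")
}

#' Forward-model specification
#'
#' Numerical grids and medium constants for the diffusion forward models.
#' The default time grid spans one full laser period (1/53 MHz = 18.868 ns)
#' in 2048 bins, matching a photon-counting histogrammer synchronised to
#' the pulse train; the DTOF simulator convolves circularly over this
#' period. The lag grid is logarithmic, the standard layout of hardware
#' correlators.
#'
#' @param n_bins number of time bins (default 2048).
#' @param span_ns histogram span in ns; default one period at `rep_rate`.
#' @param rep_rate repetition rate in MHz used for the default span.
#' @param refractive_index tissue refractive index (default 1.4).
#' @param lag_min,lag_max,n_lags logarithmic lag grid in seconds.
#' @return an object of class `forward_model_spec` with elements
#'   `time_edges` (ns), `time_centers` (ns), `lag_grid` (s), `v`
#'   (speed of light in tissue, cm/ns), and `refractive_index`.
#' @export
forward_model_spec <- function(n_bins = 2048, span_ns = NULL, rep_rate = 53,
                               refractive_index = 1.4,
                               lag_min = 1e-7, lag_max = 1e-2, n_lags = 64) {
  if (is.null(span_ns)) span_ns <- 1e3 / rep_rate
  stop_if_not_scalar_pos(span_ns, "span_ns")
  stop_if_not_scalar_pos(refractive_index, "refractive_index")
  stopifnot(n_bins >= 8, lag_min > 0, lag_max > lag_min, n_lags >= 2)
  edges <- seq(0, span_ns, length.out = n_bins + 1L)
  lags <- exp(seq(log(lag_min), log(lag_max), length.out = n_lags))
  structure(list(time_edges = edges, time_centers = bin_centers(edges),
                 span_ns = span_ns, lag_grid = lags,
                 refractive_index = refractive_index,
                 v = .C_VACUUM / refractive_index,
                 boundary_condition = "extrapolated_boundary"),
            class = "forward_model_spec")
}

#' Optical properties of a homogeneous medium
#'
#' @param mua absorption coefficient, cm^-1.
#' @param musp reduced scattering coefficient, cm^-1.
#' @param wavelength wavelength in nm.
#' @return an object of class `optical_properties`.
#' @export
optical_properties <- function(mua, musp, wavelength = NA_real_) {
  stop_if_not_scalar_pos(mua, "mua")
  stop_if_not_scalar_pos(musp, "musp")
  structure(list(mua = mua, musp = musp, wavelength = wavelength),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("Optical properties%s: mua = %.4g cm^-1, musp = %.4g cm^-1\n",
              if (is.na(x$wavelength)) "" else sprintf(" (%g nm)", x$wavelength),
              x$mua, x$musp))
  invisible(x)
}

#' Solid-phantom and tissue presets
#'
#' Nominal optical properties of the solid quality-control phantom
#' (685 nm: mua 0.23, musp 12.8; 828 nm: mua 0.19, musp 9.5 cm^-1) and a
#' healthy-muscle baseline preset.
#'
#' @param wavelength 685 or 828 nm.
#' @return an `optical_properties` object.
#' @export
phantom_preset <- function(wavelength) {
  w <- match.arg(as.character(wavelength), c("685", "828"))
  switch(w,
    "685" = optical_properties(0.23, 12.8, 685),
    "828" = optical_properties(0.19, 9.5, 828))
}

#' @rdname phantom_preset
#' @export
healthy_muscle_preset <- function(wavelength) {
  w <- match.arg(as.character(wavelength), c("685", "785", "828"))
  switch(w,
    "685" = optical_properties(0.22, 8.62, 685),
    "828" = optical_properties(0.23, 8.18, 828),
    "785" = interp_props(optical_properties(0.22, 8.62, 685),
                         optical_properties(0.23, 8.18, 828), 785))
}
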