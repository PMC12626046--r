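# Chromophore spectra (version 1).
#
# Molar extinction coefficients of oxy- and deoxy-hemoglobin in
# cm^-1 / (mol/L), decadic (base-10) convention: mua = ln(10) * eps * C.
# Values interpolated at the device wavelengths from the widely used
# OMLC (Prahl) compilation of the Hb/HbO2 spectra. Water absorption
# coefficients (cm^-1) at the same wavelengths are in the Hale-Querry
# range. Constraint: only the 2x2 ratio structure at 685/828 nm matters
# for the inversion; the table is versioned so results are reproducible
# if the compilation is ever swapped.

.EXTINCTION_VERSION <- "1"

.EXTINCTION <- data.frame(
  wavelength = c(685, 785, 828),
  eps_hbo = c(288.0, 735.4, 974.0),    # cm^-1/M
  eps_hbr = c(2407.9, 1058.0, 693.0),  # cm^-1/M
  mua_water = c(0.0045, 0.0236, 0.0295) # cm^-1
)

#' Hemoglobin extinction and water absorption table
#'
#' Returns the bundled chromophore table used by the 685/828 nm
#' inversion: molar (decadic) extinction coefficients of HbO and HbR in
#' cm^-1/M and the water absorption coefficient in cm^-1 at 685, 785 and
#' 828 nm.
#'
#' @return a data.frame with columns `wavelength`, `eps_hbo`, `eps_hbr`,
#'   `mua_water`, and attribute `version`.
#' @export
extinction_table <- function() {
  structure(.EXTINCTION, version = .EXTINCTION_VERSION)
}

extinction_row <- function(wavelength, table = extinction_table()) {
  i <- match(wavelength, table$wavelength)
  if (is.na(i)) {
    stop(sprintf("no extinction entry at %g nm", wavelength), call. = FALSE)
  }
  table[i, ]
}

#' Interpolate optical properties in wavelength
#'
#' Linear interpolation of mua and musp between two wavelengths; used to
#' supply 785 nm properties to the DCS fit from the fitted 685/828 nm
#' values.
#'
#' @param props_a,props_b `optical_properties` at two wavelengths.
#' @param wavelength target wavelength, nm (must lie between the two).
#' @return an `optical_properties` object at `wavelength`.
#' @export
interp_props <- function(props_a, props_b, wavelength = 785) {
  stopifnot(inherits(props_a, "optical_properties"),
            inherits(props_b, "optical_properties"))
  w <- sort(c(props_a$wavelength, props_b$wavelength))
  if (wavelength < w[1] || wavelength > w[2]) {
    stop("target wavelength outside the bracketing pair", call. = FALSE)
  }
  f <- (wavelength - props_a$wavelength) /
    (props_b$wavelength - props_a$wavelength)
  optical_properties(
    mua = (1 - f) * props_a$mua + f * props_b$mua,
    musp = (1 - f) * props_a$musp + f * props_b$musp,
    wavelength = wavelength
  )
}
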