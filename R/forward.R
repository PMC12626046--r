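# Diffusion-theory forward models for a semi-infinite homogeneous medium.
#
# Both models use the extrapolated-boundary condition: an isotropic source
# at depth z0 = 1/musp and its negative image mirrored about the
# extrapolated boundary z = -zb, zb = 2*A*D, with A = (1+Reff)/(1-Reff)
# and Reff from the Egan-Shu polynomial in the refractive index.

effective_reflection <- function(n) {
  -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
}

boundary_coeff <- function(n) {
  reff <- effective_reflection(n)
  (1 + reff) / (1 - reff)
}

#' Time-resolved diffuse reflectance (semi-infinite medium)
#'
#' Analytic time-domain reflectance of a homogeneous semi-infinite medium
#' under the diffusion approximation with an extrapolated boundary,
#' sampled at the bin centers of the time grid. The overall scale is
#' arbitrary (the DTOF simulator normalises to a target photon count);
#' the shape carries the optical information: the late-time log-slope
#' approaches -mua*v and the width is set by musp and rho.
#'
#' @param props [optical_properties()]: mua, musp in cm^-1.
#' @param geom [probe_geometry()]: rho in cm.
#' @param spec [forward_model_spec()]: time grid (ns) and refractive index.
#' @param t optional vector of times (ns) overriding the grid.
#' @return numeric vector of nonnegative reflectance values per bin.
#' @export
simulate_reflectance_curve <- function(props, geom, spec = forward_model_spec(),
                                       t = NULL) {
  stopifnot(inherits(props, "optical_properties"))
  stop_if_not_scalar_pos(geom$rho, "rho")
  if (is.null(t)) t <- spec$time_centers
  v <- spec$v                          # cm/ns
  D <- 1 / (3 * props$musp)            # cm
  z0 <- 1 / props$musp
  zb <- 2 * boundary_coeff(spec$refractive_index) * D
  zp <- z0 + 2 * zb
  rho2 <- geom$rho^2
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  fourDvt <- 4 * D * v * tt
  pref <- 0.5 * (pi * fourDvt)^(-1.5) * tt^(-1) *
    exp(-props$mua * v * tt - rho2 / fourDvt)
  out[pos] <- pref * (z0 * exp(-z0^2 / fourDvt) + zp * exp(-zp^2 / fourDvt))
  pmax(out, 0)
}

#' Field autocorrelation g1 of the correlation-diffusion model
#'
#' Normalised field autocorrelation for a semi-infinite medium with
#' Brownian-motion dynamics, where the blood-flow index BFI = alpha*Db
#' (cm^2/s) scales the decay. Uses the standard continuous-wave
#' correlation-diffusion Green's function with the extrapolated boundary.
#'
#' @param tau lag times, s.
#' @param props `optical_properties` at the DCS wavelength.
#' @param bfi blood-flow index, cm^2/s.
#' @param geom [probe_geometry()].
#' @param wavelength_nm DCS wavelength (defaults to `geom$dcs_wavelength`).
#' @param refractive_index medium refractive index.
#' @return numeric vector, g1(tau) in (0, 1], g1(0) = 1.
#' @export
g1_semiinf <- function(tau, props, bfi, geom,
                       wavelength_nm = geom$dcs_wavelength,
                       refractive_index = 1.4) {
  stopifnot(inherits(props, "optical_properties"), all(tau >= 0))
  stop_if_not_scalar_pos(bfi, "bfi")
  musp <- props$musp
  mua <- props$mua
  n <- refractive_index
  k0 <- 2 * pi * n / (wavelength_nm * 1e-7)   # cm^-1
  z0 <- 1 / musp
  zb <- 2 * boundary_coeff(n) / (3 * musp)
  r1 <- sqrt(geom$rho^2 + z0^2)
  r2 <- sqrt(geom$rho^2 + (z0 + 2 * zb)^2)
  kd <- function(tt) sqrt(3 * mua * musp + 6 * musp^2 * k0^2 * bfi * tt)
  gfun <- function(tt) {
    k <- kd(tt)
    exp(-k * r1) / r1 - exp(-k * r2) / r2
  }
  gfun(tau) / gfun(0)
}

#' Noiseless intensity autocorrelation via the Siegert relation
#'
#' g2(tau) = 1 + beta * |g1(tau)|^2, beta being the coherence (detection
#' mode) factor, 0.5 for ideal single-mode detection of unpolarised light.
#'
#' @inheritParams g1_semiinf
#' @param beta coherence factor in (0, 1].
#' @return numeric vector of g2 values in [1, 1 + beta].
#' @export
g2_model <- function(tau, props, bfi, beta, geom, ...) {
  stopifnot(beta > 0, beta <= 1)
  1 + beta * g1_semiinf(tau, props, bfi, geom, ...)^2
}
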