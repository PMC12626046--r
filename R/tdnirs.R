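# DTOF preprocessing, IRF characterization, convolution fitting for
# absolute mua/musp, and chromophore / StO2 computation.

#' IRF barycenter and FWHM
#'
#' Characterises an instrument response function histogram by the
#' temporal position of its barycenter (count-weighted mean time after
#' background subtraction) and its FWHM (linear interpolation at half of
#' the peak value on both edges). The FWHM is the temporal resolution of
#' the chain; barycenter drift tracks the stability of laser, detection
#' and acquisition.
#'
#' @param irf an `irf_record` (or anything with `bin_edges` and
#'   `histogram`).
#' @param bg_bins number of leading (pre-peak) bins used to estimate the
#'   background level (default 100).
#' @return the `irf_record` with `barycenter` (ns) and `fwhm` (ps) set.
#' @export
compute_irf_metrics <- function(irf, bg_bins = 100) {
  h <- irf$histogram
  if (all(h == 0)) stop("all-zero IRF histogram", call. = FALSE)
  tt <- bin_centers(irf$bin_edges)
  bg <- mean(h[seq_len(min(bg_bins, which.max(h) - 1))])
  if (!is.finite(bg)) bg <- 0
  hs <- pmax(h - bg, 0)
  bary <- sum(hs * tt) / sum(hs)
  ipk <- which.max(hs)
  half <- hs[ipk] / 2
  # half-maximum crossings by linear interpolation
  left <- max(which(hs[seq_len(ipk)] < half), 0)
  right <- ipk - 1 + min(which(hs[ipk:length(hs)] < half), length(hs) - ipk + 1)
  t_left <- if (left == 0) tt[1] else {
    tt[left] + (half - hs[left]) / (hs[left + 1] - hs[left]) *
      (tt[left + 1] - tt[left])
  }
  t_right <- if (right > length(hs)) tt[length(hs)] else {
    tt[right - 1] + (hs[right - 1] - half) / (hs[right - 1] - hs[right]) *
      (tt[right] - tt[right - 1])
  }
  irf$barycenter <- bary
  irf$fwhm <- (t_right - t_left) * 1000   # ps
  irf
}

# background mean/sd over a pre-peak window; also the dynamic range
# (max counts over background sd) used as the TD-NIRS signal-quality index
estimate_background <- function(counts, bg_bins = 100) {
  onset <- which(counts > 0.01 * max(counts))[1]
  # stay clear of the rising edge: only the first half of the pre-onset
  # region counts as dark
  n_av <- min(bg_bins, (onset - 1) %/% 2)
  if (is.na(n_av) || n_av < 5) {
    return(list(mean = 0, sd = 0, dynamic_range = Inf))
  }
  idx <- seq_len(n_av)
  m <- mean(counts[idx])
  s <- stats::sd(counts[idx])
  list(mean = m, sd = if (is.na(s)) 0 else s,
       dynamic_range = if (!is.na(s) && s > 0) max(counts) / s else Inf)
}

# forward model on the DTOF grid: (diffusion reflectance (*) IRF), with
# the amplitude profiled out by Poisson-weighted least squares
dtof_model_shape <- function(mua, musp, dtof, irf, geom, refractive_index) {
  spec <- list(v = .C_VACUUM / refractive_index,
               refractive_index = refractive_index)
  theo <- simulate_reflectance_curve(
    optical_properties(mua, musp, dtof$wavelength), geom,
    structure(spec, class = "forward_model_spec"),
    t = bin_centers(dtof$bin_edges))
  kern <- irf$histogram / sum(irf$histogram)
  circular_convolve(theo, kern)
}

#' Poisson-weighted DTOF fit objective
#'
#' The weighted sum of squares minimised by [fit_dtof()] at fixed
#' (mua, musp), with the amplitude profiled out analytically. Exposed so
#' that the optimum can be cross-checked against a brute-force grid
#' search over the same objective.
#'
#' @param mua,musp trial optical properties, cm^-1.
#' @param dtof a `dtof_histogram`.
#' @param irf an `irf_record` on the same grid.
#' @param geom [probe_geometry()].
#' @param window integer indices of the fit window.
#' @param bg background estimate from the pre-peak window.
#' @param refractive_index medium refractive index.
#' @return scalar objective value.
#' @export
dtof_objective <- function(mua, musp, dtof, irf, geom, window, bg,
                           refractive_index = 1.4) {
  r <- dtof_fit_residuals(c(log(mua), log(musp)), dtof, irf, geom, window,
                          bg, refractive_index)
  sum(r^2)
}

dtof_fit_residuals <- function(par, dtof, irf, geom, window, bg,
                               refractive_index) {
  s <- dtof_model_shape(exp(par[1]), exp(par[2]), dtof, irf, geom,
                        refractive_index)[window]
  y <- (dtof$counts - bg$mean)[window]
  w <- 1 / pmax(dtof$counts[window], 1)   # Poisson weights
  amp <- sum(w * y * s) / sum(w * s^2)
  (amp * s - y) * sqrt(w)
}

#' Fit a DTOF for absolute optical properties
#'
#' Convolution fit of the semi-infinite diffusion-model reflectance with
#' the measured IRF against a DTOF histogram: damped (Levenberg-
#' Marquardt) least squares with Poisson weights over amplitude, mua and
#' musp, the amplitude profiled analytically. The background is estimated
#' from a pre-peak window, subtracted, and used for the dynamic range
#' (max of the DTOF over the standard deviation of the background). The
#' default fit window runs from 80% of the peak on the rising edge to 1%
#' of the peak on the falling edge.
#'
#' @param dtof a `dtof_histogram`.
#' @param irf an `irf_record` on the same time grid.
#' @param geom [probe_geometry()].
#' @param refractive_index medium refractive index (default 1.4).
#' @param window_frac c(rising, falling) peak fractions delimiting the
#'   fit window.
#' @param bg_bins pre-peak background window length in bins.
#' @param init initial c(mua, musp) in cm^-1.
#' @param max_iter maximum LM iterations.
#' @param ftol relative objective-change convergence tolerance.
#' @return an object of class `dtof_fit` with the recovered
#'   [optical_properties()], amplitude and `diagnostics` (reduced
#'   chi-square, dynamic range, fit window, iterations, convergence
#'   flag). Non-convergence is flagged, not raised.
#' @export
fit_dtof <- function(dtof, irf, geom = probe_geometry(),
                     refractive_index = 1.4, window_frac = c(0.8, 0.01),
                     bg_bins = 100, init = c(0.1, 10), max_iter = 200,
                     ftol = 1e-10) {
  stopifnot(inherits(dtof, "dtof_histogram"), inherits(irf, "irf_record"))
  if (!isTRUE(all.equal(dtof$bin_edges, irf$bin_edges))) {
    stop("DTOF and IRF must share the time grid", call. = FALSE)
  }
  y <- dtof$counts
  if (sum(y) == 0) stop("empty DTOF histogram", call. = FALSE)
  bg <- estimate_background(y, bg_bins)
  ys <- y - bg$mean
  ipk <- which.max(ys)
  if (ipk <= 1 || ipk >= length(ys)) {
    stop("degenerate DTOF: peak at the grid edge", call. = FALSE)
  }
  rise <- which(ys[seq_len(ipk)] >= window_frac[1] * ys[ipk])[1]
  after <- ys[ipk:length(ys)]
  fall <- ipk - 1 + max(which(after >= window_frac[2] * ys[ipk]))
  window <- rise:fall

  fit <- minpack.lm::nls.lm(
    par = log(init), fn = dtof_fit_residuals, dtof = dtof, irf = irf,
    geom = geom, window = window, bg = bg,
    refractive_index = refractive_index,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol,
                                         ptol = 1e-10))
  mua <- exp(fit$par[1]); musp <- exp(fit$par[2])
  s <- dtof_model_shape(mua, musp, dtof, irf, geom, refractive_index)
  w <- 1 / pmax(y[window], 1)
  amp <- sum(w * ys[window] * s[window]) / sum(w * s[window]^2)
  res <- (amp * s[window] - ys[window]) * sqrt(w)
  structure(list(
    props = optical_properties(mua, musp, dtof$wavelength),
    amplitude = amp,
    fitted = amp * s + bg$mean,
    dtof = dtof, irf = irf, geom = geom,
    refractive_index = refractive_index,
    diagnostics = list(
      reduced_chi2 = sum(res^2) / max(length(window) - 3, 1),
      dynamic_range = bg$dynamic_range,
      fit_window = range(window),
      iterations = fit$niter,
      converged = fit$info %in% 1:3,
      background = bg$mean)),
    class = "dtof_fit")
}

#' @export
print.dtof_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "DTOF convolution fit%s\n  mua  = %.4f cm^-1\n  musp = %.3f cm^-1\n",
    if (is.na(x$props$wavelength)) "" else
      sprintf(" (%g nm)", x$props$wavelength),
    x$props$mua, x$props$musp))
  cat(sprintf("  reduced chi2 = %.3f, DR = %.3g, %s in %d iterations\n",
              d$reduced_chi2, d$dynamic_range,
              if (d$converged) "converged" else "NOT converged",
              d$iterations))
  invisible(x)
}

#' @export
coef.dtof_fit <- function(object, ...) {
  c(mua = object$props$mua, musp = object$props$musp,
    amplitude = object$amplitude)
}

#' @export
summary.dtof_fit <- function(object, ...) {
  c(coef(object), unlist(object$diagnostics[c("reduced_chi2",
                                              "dynamic_range")]))
}

#' @export
residuals.dtof_fit <- function(object, ...) {
  object$dtof$counts - object$fitted
}

#' @export
plot.dtof_fit <- function(x, ...) {
  tt <- bin_centers(x$dtof$bin_edges)
  graphics::plot(tt, pmax(x$dtof$counts, 0.5), log = "y", type = "l",
                 xlab = "time (ns)", ylab = "counts/bin",
                 main = "DTOF and convolution fit", ...)
  graphics::lines(tt, pmax(x$fitted, 0.5), col = 2, lwd = 2)
  w <- x$diagnostics$fit_window
  graphics::abline(v = tt[w], lty = 3)
  invisible(x)
}

#' Hemoglobin concentrations and StO2 from two-wavelength absorption
#'
#' Solves the 2x2 linear system
#' mua(lambda) - wf * mua_water(lambda) = ln(10) * (eps_HbO * HbO +
#' eps_HbR * HbR) at 685 and 828 nm for the oxy- and deoxy-hemoglobin
#' concentrations, then StO2 = 100 * HbO / tHb.
#'
#' @param props_685,props_828 `optical_properties` at the two wavelengths.
#' @param table extinction table (see [extinction_table()]).
#' @param water_fraction water volume fraction whose absorption is
#'   subtracted first (0 for the solid phantom, ~0.7 for muscle).
#' @return an object of class `chromophore_state`: `hbo`, `hbr`, `thb`
#'   (uM), `sto2` (%), and `negative` flag set when a concentration came
#'   out negative (returned with a warning, not an error).
#' @export
compute_chromophores <- function(props_685, props_828,
                                 table = extinction_table(),
                                 water_fraction = 0) {
  stopifnot(inherits(props_685, "optical_properties"),
            inherits(props_828, "optical_properties"))
  r1 <- extinction_row(685, table)
  r2 <- extinction_row(828, table)
  E <- log(10) * matrix(c(r1$eps_hbo, r1$eps_hbr,
                          r2$eps_hbo, r2$eps_hbr), 2, byrow = TRUE)
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix", call. = FALSE)
  b <- c(props_685$mua - water_fraction * r1$mua_water,
         props_828$mua - water_fraction * r2$mua_water)
  conc <- solve(E, b) * 1e6   # mol/L -> uM
  hbo <- conc[1]; hbr <- conc[2]
  neg <- hbo < -1e-9 || hbr < -1e-9   # uM; exact zeros are not negative
  if (neg) warning("negative chromophore concentration", call. = FALSE)
  thb <- hbo + hbr
  structure(list(hbo = hbo, hbr = hbr, thb = thb,
                 sto2 = 100 * hbo / thb, negative = neg),
            class = "chromophore_state")
}

#' @export
print.chromophore_state <- function(x, ...) {
  cat(sprintf("HbO %.2f uM, HbR %.2f uM, tHb %.2f uM, StO2 %.1f%%%s\n",
              x$hbo, x$hbr, x$thb, x$sto2,
              if (x$negative) " [negative concentration]" else ""))
  invisible(x)
}

#' Effective phantom hemoglobin values over a repetition series
#'
#' Applies the chromophore inversion (water term zero) to each
#' repetition's (685 nm, 828 nm) absorption pair of a phantom session,
#' yielding the session's effective tHbph and StO2ph with their
#' intra-phantom coefficients of variation. The solid phantom contains no
#' hemoglobin; these "effective" values are a sensitive day-to-day
#' stability metric for the whole TD-NIRS chain.
#'
#' @param props_685,props_828 lists of per-repetition
#'   [optical_properties()] (equal length, >= 2).
#' @param table extinction table.
#' @param session_date optional session date carried in the record.
#' @return a `phantom_qc_record`: per-repetition values, means, and
#'   intra-phantom CVs (%).
#' @export
compute_phantom_effective <- function(props_685, props_828,
                                      table = extinction_table(),
                                      session_date = NA) {
  if (length(props_685) != length(props_828)) {
    stop("mismatched repetition counts across wavelengths", call. = FALSE)
  }
  if (length(props_685) < 2) stop("need >= 2 repetitions", call. = FALSE)
  chrom <- mapply(function(a, b) {
    cs <- compute_chromophores(a, b, table, water_fraction = 0)
    c(thb = cs$thb, sto2 = cs$sto2)
  }, props_685, props_828)
  thb <- chrom["thb", ]; sto2 <- chrom["sto2", ]
  structure(list(
    thb_ph = mean(thb), sto2_ph = mean(sto2),
    thb_rep = thb, sto2_rep = sto2,
    cv_thb = cv_series(thb)$cv, cv_sto2 = cv_series(sto2)$cv,
    mua_685 = vapply(props_685, `[[`, 0, "mua"),
    mua_828 = vapply(props_828, `[[`, 0, "mua"),
    n_rep = length(thb), session_date = session_date),
    class = "phantom_qc_record")
}

#' @export
print.phantom_qc_record <- function(x, ...) {
  cat(sprintf(
    "Phantom QC (%d reps): tHbph %.2f uM (CV %.2f%%), StO2ph %.2f%% (CV %.2f%%)\n",
    x$n_rep, x$thb_ph, x$cv_thb, x$sto2_ph, x$cv_sto2))
  invisible(x)
}
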