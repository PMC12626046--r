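# g2 curve handling, block averaging, and inversion to blood-flow index
# and coherence factor.

#' Block-average g2 curves to a slower rate
#'
#' Unweighted mean of all curves whose timestamp falls in each window
#' [t, t + 1/target_rate), windows anchored at t = 0; count rates are
#' averaged likewise and windows containing no curves are omitted. Used
#' to bring the 26 ms correlator cadence to the 1 Hz TD-NIRS rate.
#'
#' @param curves list of `g2_curve` objects sharing one lag grid,
#'   timestamps sorted.
#' @param target_rate output rate, Hz (default 1).
#' @return list of averaged `g2_curve` objects.
#' @export
block_average_g2 <- function(curves, target_rate = 1) {
  stopifnot(length(curves) > 0, target_rate > 0)
  lag <- curves[[1]]$lag
  for (c in curves) {
    if (!isTRUE(all.equal(c$lag, lag))) {
      stop("curves do not share a lag grid", call. = FALSE)
    }
  }
  ts <- vapply(curves, `[[`, 0, "timestamp")
  win <- floor(ts * target_rate)
  out <- lapply(sort(unique(win)), function(w) {
    sel <- curves[win == w]
    g2 <- rowMeans(vapply(sel, `[[`, numeric(length(lag)), "g2"))
    cr <- mean(vapply(sel, `[[`, 0, "count_rate"))
    at <- sum(vapply(sel, `[[`, 0, "avg_time"))
    new_g2_curve(lag, g2, cr, timestamp = w / target_rate, avg_time = at)
  })
  out
}

g2_fit_residuals <- function(par, curve, props, geom, idx) {
  bfi <- exp(par[1]); beta <- par[2]
  g1 <- g1_semiinf(curve$lag[idx], props, bfi, geom)
  (1 + beta * g1^2) - curve$g2[idx]
}

#' Fit a g2 curve for blood-flow index and coherence factor
#'
#' Least-squares fit of the Siegert model 1 + beta*|g1(tau; BFI)|^2 with
#' beta and BFI jointly free, g1 being the semi-infinite
#' correlation-diffusion field autocorrelation with Brownian dynamics
#' (BFI = alpha*Db). After a first pass over all lags the fit is
#' restricted to lags where the noiseless model retains more than
#' `decay_floor` of its decay, then refit.
#'
#' @param curve a `g2_curve`.
#' @param props_785 `optical_properties` at the DCS wavelength (e.g.
#'   interpolated from the fitted 685/828 nm values with
#'   [interp_props()]).
#' @param geom [probe_geometry()].
#' @param decay_floor keep lags with model (g2-1)/beta above this
#'   (default 0.01).
#' @param init_bfi initial BFI, cm^2/s.
#' @param max_iter,ftol LM controls.
#' @return an object of class `g2_fit`: `bfi` (cm^2/s), `beta`,
#'   `reduced_chi2`, `converged`. A flat (no-decay) curve returns
#'   `converged = FALSE` rather than raising.
#' @export
fit_g2 <- function(curve, props_785, geom = probe_geometry(),
                   decay_floor = 0.01, init_bfi = 1e-8,
                   max_iter = 200, ftol = 1e-10) {
  stopifnot(inherits(curve, "g2_curve"))
  if (length(curve$lag) < 20) {
    stop("need >= 20 lags spanning the decay", call. = FALSE)
  }
  if (diff(range(curve$g2)) < 1e-4) {
    return(structure(list(bfi = NA_real_, beta = NA_real_,
                          reduced_chi2 = NA_real_, converged = FALSE,
                          curve = curve, fitted = NULL,
                          model = "semi-infinite correlation-diffusion g1"),
                     class = "g2_fit"))
  }
  init_beta <- min(max(mean(curve$g2[1:3]) - 1, 0.1), 1)
  do_fit <- function(idx) {
    minpack.lm::nls.lm(
      par = c(log(init_bfi), init_beta), fn = g2_fit_residuals,
      curve = curve, props = props_785, geom = geom, idx = idx,
      lower = c(-60, 1e-3), upper = c(10, 1),
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol))
  }
  fit <- do_fit(seq_along(curve$lag))
  bfi <- exp(fit$par[1])
  g1 <- g1_semiinf(curve$lag, props_785, bfi, geom)
  idx <- which(g1^2 > decay_floor)
  if (length(idx) >= 20) fit <- do_fit(idx) else idx <- seq_along(curve$lag)
  bfi <- exp(fit$par[1]); beta <- fit$par[2]
  res <- g2_fit_residuals(fit$par, curve, props_785, geom, idx)
  structure(list(bfi = bfi, beta = beta,
                 reduced_chi2 = sum(res^2) / max(length(idx) - 2, 1),
                 converged = fit$info %in% 1:3,
                 fit_lags = idx, curve = curve, props = props_785,
                 fitted = 1 + beta *
                   g1_semiinf(curve$lag, props_785, bfi, geom)^2,
                 model = "semi-infinite correlation-diffusion g1"),
            class = "g2_fit")
}

#' @export
print.g2_fit <- function(x, ...) {
  if (!x$converged && is.na(x$bfi)) {
    cat("g2 fit: not converged (flat curve)\n")
    return(invisible(x))
  }
  cat(sprintf("g2 fit: BFI = %.3e cm^2/s, beta = %.3f (chi2_r %.3g, %s)\n",
              x$bfi, x$beta, x$reduced_chi2,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.g2_fit <- function(object, ...) c(bfi = object$bfi, beta = object$beta)

#' @export
residuals.g2_fit <- function(object, ...) {
  if (is.null(object$fitted)) return(NULL)
  object$curve$g2 - object$fitted
}

#' @export
plot.g2_fit <- function(x, ...) {
  graphics::plot(x$curve$lag, x$curve$g2, log = "x", xlab = "lag (s)",
                 ylab = "g2", main = "Intensity autocorrelation fit", ...)
  if (!is.null(x$fitted)) graphics::lines(x$curve$lag, x$fitted, col = 2,
                                          lwd = 2)
  invisible(x)
}

#' DCS baseline quality report
#'
#' Integrates the raw g2 stream into `integration_s`-second blocks over a
#' baseline window, fits each block, and reports the median and standard
#' deviation of the coherence factor beta together with count-rate
#' statistics in kHz. Flags are raised when any block's beta drops below
#' `beta_floor` or the median count rate leaves `count_band`.
#'
#' @param curves list of raw `g2_curve` objects (timestamps in s).
#' @param props_785 `optical_properties` for the block fits.
#' @param geom [probe_geometry()].
#' @param baseline_window_s length of the baseline window, s (default 60).
#' @param integration_s integration per block, s (default 10).
#' @param beta_floor beta drop threshold (default 0.4).
#' @param count_band acceptable count-rate band, kHz (default c(10, 200)).
#' @return a `dcs_quality_report` list: beta median/sd, count-rate
#'   median/sd, per-block betas, and `flags`.
#' @export
dcs_quality <- function(curves, props_785, geom = probe_geometry(),
                        baseline_window_s = 60, integration_s = 10,
                        beta_floor = 0.4, count_band = c(10, 200)) {
  if (baseline_window_s < integration_s) {
    stop("baseline window shorter than one integration block",
         call. = FALSE)
  }
  ts <- vapply(curves, `[[`, 0, "timestamp")
  base <- curves[ts < min(ts) + baseline_window_s]
  blocks <- block_average_g2(base, target_rate = 1 / integration_s)
  betas <- vapply(blocks, function(b) fit_g2(b, props_785, geom)$beta, 0)
  cr <- vapply(base, `[[`, 0, "count_rate")
  flags <- character(0)
  if (any(betas < beta_floor, na.rm = TRUE)) flags <- c(flags, "beta_drop")
  md_cr <- stats::median(cr)
  if (md_cr < count_band[1] || md_cr > count_band[2]) {
    flags <- c(flags, "count_rate_out_of_band")
  }
  structure(list(beta_median = stats::median(betas),
                 beta_sd = stats::sd(betas), betas = betas,
                 count_rate_median = md_cr, count_rate_sd = stats::sd(cr),
                 window_s = baseline_window_s, flags = flags),
            class = "dcs_quality_report")
}

#' @export
print.dcs_quality_report <- function(x, ...) {
  cat(sprintf(
    "DCS baseline quality (%g s): beta %.3f +/- %.3f, count rate %.1f +/- %.1f kHz%s\n",
    x$window_s, x$beta_median, x$beta_sd, x$count_rate_median,
    x$count_rate_sd,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}
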