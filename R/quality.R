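# Quality-assessment-phase evaluation, optical interference analysis,
# and longitudinal IRF/phantom trending.

#' Quality-phase thresholds
#'
#' Count-level thresholds of the quality-assessment phase. One-sided
#' dark/cross-talk maxima are compared strictly (pass requires value <
#' threshold); signal bands are pass-inclusive at their edges.
#'
#' @param dcs_dark_max DCS dark counts, kHz (default 2).
#' @param dcs_signal_min,dcs_signal_max DCS signal band, kHz (10-200).
#' @param dcs_crosstalk_dark_max DCS dark counts while the TD-NIRS laser
#'   is active, kHz (default 3).
#' @param tdnirs_count_min,tdnirs_count_max TD-NIRS per-wavelength signal
#'   band, Mcps (0.8-1.2).
#' @param tdnirs_dark_max TD-NIRS dark counts, kcps (default 30).
#' @param segment_s segment duration, s (default 10).
#' @return an object of class `qp_thresholds`.
#' @export
qp_thresholds <- function(dcs_dark_max = 2, dcs_signal_min = 10,
                          dcs_signal_max = 200, dcs_crosstalk_dark_max = 3,
                          tdnirs_count_min = 0.8, tdnirs_count_max = 1.2,
                          tdnirs_dark_max = 30, segment_s = 10) {
  stopifnot(dcs_signal_min < dcs_signal_max,
            tdnirs_count_min < tdnirs_count_max,
            dcs_dark_max > 0, tdnirs_dark_max > 0)
  structure(as.list(environment()), class = "qp_thresholds")
}

# per-segment mean over the central part (switching transients at the
# segment edges excluded: first and last second dropped)
segment_means <- function(qp, cols) {
  segs <- split(qp, qp$segment)
  do.call(rbind, lapply(segs, function(s) {
    s <- s[order(s$timestamp), ]
    if (nrow(s) > 2) s <- s[-c(1, nrow(s)), ]
    out <- data.frame(segment = s$segment[1], dcs_laser = s$dcs_laser[1],
                      tdnirs_laser = s$tdnirs_laser[1], n = nrow(s))
    for (cc in cols) out[[cc]] <- mean(s[[cc]])
    out
  }))
}

#' Evaluate a quality-assessment phase
#'
#' Applies the count-level thresholds to the per-segment mean light
#' levels of a QP session. DCS passes when dark, signal and cross-talk
#' conditions are all met; TD-NIRS (TRS) passes when both wavelengths sit
#' in the signal band and the dark level is below threshold; the oximeter
#' verdict mirrors the manufacturer validity flag. Any failed indicator
#' sets `blocking`.
#'
#' @param qp either a session directory (read with [read_session()]) or
#'   the qp channel data.frame (columns `timestamp`, `segment`,
#'   `dcs_laser`, `tdnirs_laser`, `dcs_khz`, `tdnirs_685_cps`,
#'   `tdnirs_828_cps`, `oxi_valid`).
#' @param thresholds [qp_thresholds()].
#' @return a `qp_result`: `verdicts` (TRS/DCS/Oxi logical), per-check
#'   table `measured`, and `blocking` flag.
#' @export
evaluate_qp <- function(qp, thresholds = qp_thresholds()) {
  if (is.character(qp)) qp <- read_session(qp)$channels$qp
  need <- c("segment", "dcs_laser", "tdnirs_laser", "dcs_khz",
            "tdnirs_685_cps", "tdnirs_828_cps", "oxi_valid")
  if (!all(need %in% names(qp))) {
    stop("qp table lacks labeled ON/OFF segment columns", call. = FALSE)
  }
  sm <- segment_means(qp, c("dcs_khz", "tdnirs_685_cps", "tdnirs_828_cps"))
  th <- thresholds
  both_off <- sm$dcs_laser == "off" & sm$tdnirs_laser == "off"
  dcs_on <- sm$dcs_laser == "on"
  td_on <- sm$tdnirs_laser == "on"

  checks <- rbind(
    data.frame(module = "DCS", check = "dark",
               value = mean(sm$dcs_khz[both_off]),
               pass = all(sm$dcs_khz[both_off] < th$dcs_dark_max)),
    data.frame(module = "DCS", check = "signal",
               value = mean(sm$dcs_khz[dcs_on]),
               pass = all(sm$dcs_khz[dcs_on] >= th$dcs_signal_min &
                            sm$dcs_khz[dcs_on] <= th$dcs_signal_max)),
    data.frame(module = "DCS", check = "crosstalk_dark",
               value = mean(sm$dcs_khz[td_on & !dcs_on]),
               pass = all(sm$dcs_khz[td_on & !dcs_on] <
                            th$dcs_crosstalk_dark_max)),
    data.frame(module = "TRS", check = "signal_685",
               value = mean(sm$tdnirs_685_cps[td_on]) / 1e6,
               pass = all(sm$tdnirs_685_cps[td_on] / 1e6 >=
                            th$tdnirs_count_min &
                          sm$tdnirs_685_cps[td_on] / 1e6 <=
                            th$tdnirs_count_max)),
    data.frame(module = "TRS", check = "signal_828",
               value = mean(sm$tdnirs_828_cps[td_on]) / 1e6,
               pass = all(sm$tdnirs_828_cps[td_on] / 1e6 >=
                            th$tdnirs_count_min &
                          sm$tdnirs_828_cps[td_on] / 1e6 <=
                            th$tdnirs_count_max)),
    data.frame(module = "TRS", check = "dark",
               value = mean(c(sm$tdnirs_685_cps[!td_on],
                              sm$tdnirs_828_cps[!td_on])) / 1e3,
               pass = all(c(sm$tdnirs_685_cps[!td_on],
                            sm$tdnirs_828_cps[!td_on]) / 1e3 <
                            th$tdnirs_dark_max)),
    data.frame(module = "Oxi", check = "valid_flag",
               value = mean(as.logical(qp$oxi_valid)),
               pass = all(as.logical(qp$oxi_valid))))
  verdicts <- c(TRS = all(checks$pass[checks$module == "TRS"]),
                DCS = all(checks$pass[checks$module == "DCS"]),
                Oxi = all(checks$pass[checks$module == "Oxi"]))
  structure(list(verdicts = verdicts, measured = checks,
                 blocking = !all(verdicts)),
            class = "qp_result")
}

#' @export
print.qp_result <- function(x, ...) {
  cat("Quality-assessment phase:",
      paste(sprintf("%s=%s", names(x$verdicts),
                    ifelse(x$verdicts, "PASS", "FAIL")), collapse = " "),
      if (x$blocking) "[measurement blocked]\n" else "\n")
  invisible(x)
}

#' Optical interference rank test
#'
#' Mann-Whitney (Wilcoxon rank-sum) comparison of background count
#' levels with the counterpart laser ON vs OFF.
#'
#' @param on,off numeric count levels with the counterpart laser on/off
#'   (>= 3 observations each).
#' @param alpha significance level (default 0.05).
#' @return list `statistic`, `p`, `significant`.
#' @export
interference_test <- function(on, off, alpha = 0.05) {
  if (length(on) < 3 || length(off) < 3) {
    stop("need >= 3 observations per group", call. = FALSE)
  }
  w <- stats::wilcox.test(on, off, exact = FALSE, correct = TRUE)
  list(statistic = unname(w$statistic), p = w$p.value,
       significant = w$p.value < alpha)
}

#' Per-module interference analysis of a QP session
#'
#' For each module and wavelength, compares the per-second background
#' counts with the counterpart laser ON vs OFF.
#'
#' @param qp qp channel data.frame (see [evaluate_qp()]).
#' @param alpha significance level.
#' @return data.frame of comparisons with statistic, p and flag.
#' @export
qp_interference <- function(qp, alpha = 0.05) {
  td_off <- qp$tdnirs_laser == "off"
  dcs_off <- qp$dcs_laser == "off"
  cmp <- list(
    tdnirs_685_bg_dcs = list(x = qp$tdnirs_685_cps[td_off & !dcs_off],
                             y = qp$tdnirs_685_cps[td_off & dcs_off]),
    tdnirs_828_bg_dcs = list(x = qp$tdnirs_828_cps[td_off & !dcs_off],
                             y = qp$tdnirs_828_cps[td_off & dcs_off]),
    dcs_bg_tdnirs = list(x = qp$dcs_khz[dcs_off & !td_off],
                         y = qp$dcs_khz[dcs_off & td_off]))
  do.call(rbind, lapply(names(cmp), function(nm) {
    r <- interference_test(cmp[[nm]]$x, cmp[[nm]]$y, alpha)
    data.frame(comparison = nm, statistic = r$statistic, p = r$p,
               significant = r$significant)
  }))
}

#' Longitudinal IRF and phantom trending
#'
#' Across repeated phantom/IRF sessions, computes the coefficients of
#' variation of the IRF FWHM, the standard deviation of the barycenter,
#' the CVs of mua and musp per wavelength, and the CVs of the effective
#' tHbph and StO2ph. When a second record set (e.g. the same sessions
#' re-processed with the first-of-month IRF instead of the daily one) is
#' supplied, paired Wilcoxon signed-rank comparisons are reported.
#'
#' @param records data.frame, one row per session x wavelength:
#'   `session`, `wavelength`, `mua`, `musp`, and optionally `fwhm_ps`,
#'   `barycenter_ns`.
#' @param records_alt optional second data.frame with the same sessions
#'   (e.g. monthly-first calibration) for the paired comparison.
#' @param table extinction table for the effective hemoglobin values.
#' @return a `trend_report` list: per-wavelength CV table, tHbph/StO2ph
#'   CVs, and optional paired-comparison table.
#' @export
phantom_trending <- function(records, records_alt = NULL,
                             table = extinction_table()) {
  if (length(unique(records$session)) < 2) {
    stop("need >= 2 sessions to trend", call. = FALSE)
  }
  per_wl <- do.call(rbind, lapply(split(records, records$wavelength),
    function(r) {
      data.frame(wavelength = r$wavelength[1],
                 cv_mua = cv_series(r$mua)$cv,
                 cv_musp = cv_series(r$musp)$cv,
                 cv_fwhm = if (!is.null(r$fwhm_ps))
                   cv_series(r$fwhm_ps)$cv else NA_real_,
                 sd_barycenter = if (!is.null(r$barycenter_ns))
                   stats::sd(r$barycenter_ns) else NA_real_)
    }))
  eff <- effective_hb_by_session(records, table)
  paired <- NULL
  if (!is.null(records_alt)) {
    eff_alt <- effective_hb_by_session(records_alt, table)
    common <- intersect(eff$session, eff_alt$session)
    if (length(common) != nrow(eff) || length(common) != nrow(eff_alt)) {
      stop("unmatched session pairs in the paired comparison",
           call. = FALSE)
    }
    a <- eff[match(common, eff$session), ]
    b <- eff_alt[match(common, eff_alt$session), ]
    pw <- function(x, y) {
      if (isTRUE(all.equal(x, y))) return(1)
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
    }
    paired <- data.frame(
      quantity = c("thb_ph", "sto2_ph"),
      p = c(pw(a$thb, b$thb), pw(a$sto2, b$sto2)))
  }
  structure(list(per_wavelength = per_wl,
                 cv_thb_ph = cv_series(eff$thb)$cv,
                 cv_sto2_ph = cv_series(eff$sto2)$cv,
                 effective = eff, paired = paired),
            class = "trend_report")
}

effective_hb_by_session <- function(records, table) {
  wls <- sort(unique(records$wavelength))
  if (!all(c(685, 828) %in% wls)) {
    stop("trending needs both 685 and 828 nm per session", call. = FALSE)
  }
  sess <- unique(records$session)
  do.call(rbind, lapply(sess, function(s) {
    r685 <- records[records$session == s & records$wavelength == 685, ]
    r828 <- records[records$session == s & records$wavelength == 828, ]
    if (nrow(r685) != 1 || nrow(r828) != 1) {
      stop(sprintf("session %s lacks a unique 685/828 pair", s),
           call. = FALSE)
    }
    cs <- compute_chromophores(optical_properties(r685$mua, r685$musp, 685),
                               optical_properties(r828$mua, r828$musp, 828),
                               table, water_fraction = 0)
    data.frame(session = s, thb = cs$thb, sto2 = cs$sto2)
  }))
}
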