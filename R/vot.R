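# Vascular-occlusion-test segmentation, biomarker extraction, and
# Fick-law metabolism indices.

#' VOT protocol definition
#'
#' Standard protocol: 3 min baseline, 3 min arterial occlusion at a cuff
#' pressure 50 mmHg above systolic, 5 min recovery; the recovery may be
#' extended in 30 s increments when parameters have not returned to
#' baseline.
#'
#' @param baseline_s,occlusion_s,recovery_s phase durations, s.
#' @param pressure_over_systolic cuff overpressure, mmHg.
#' @param extension_step_s recovery extension increment, s.
#' @return an object of class `vot_protocol`.
#' @export
vot_protocol <- function(baseline_s = 180, occlusion_s = 180,
                         recovery_s = 300, pressure_over_systolic = 50,
                         extension_step_s = 30) {
  stopifnot(baseline_s > 0, occlusion_s > 0, recovery_s > 0)
  structure(list(baseline_s = baseline_s, occlusion_s = occlusion_s,
                 recovery_s = recovery_s,
                 pressure_over_systolic = pressure_over_systolic,
                 extension_step_s = extension_step_s),
            class = "vot_protocol")
}

#' Graded-occlusion (LOP) precision protocol
#'
#' Inflation/deflation steps of `step_s` seconds at fractions of the limb
#' occlusion pressure; per-step precision is evaluated over the last
#' `eval_window_s` seconds of each interval.
#'
#' @param steps LOP fractions (default c(0.4, 0.6, 0.8, 1.0)).
#' @param step_s step duration, s.
#' @param eval_window_s evaluation window, s.
#' @param lop limb occlusion pressure, mmHg.
#' @return an object of class `lop_protocol`.
#' @export
lop_protocol <- function(steps = c(0.4, 0.6, 0.8, 1.0), step_s = 60,
                         eval_window_s = 15, lop = 160) {
  stopifnot(all(steps > 0), all(steps <= 1), eval_window_s <= step_s)
  structure(list(steps = steps, step_s = step_s,
                 eval_window_s = eval_window_s, lop = lop),
            class = "lop_protocol")
}

infer_markers_from_pressure <- function(t, pressure) {
  half <- max(pressure) / 2
  above <- pressure > half
  if (!any(above) || all(above)) {
    stop("cannot infer inflation/deflation from the pressure channel",
         call. = FALSE)
  }
  up <- which(diff(above) == 1)[1]
  down <- which(diff(above) == -1)[1]
  data.frame(label = c("inflation", "deflation", "end"),
             t = c((t[up] + t[up + 1]) / 2, (t[down] + t[down + 1]) / 2,
                   t[length(t)]),
             stringsAsFactors = FALSE)
}

#' Segment a VOT trace and compute baselines
#'
#' Delimits the baseline / occlusion / recovery phases from the event
#' markers (or, when absent, from threshold crossings of the cuff
#' pressure channel) and computes the pre-occlusion baseline (mean over
#' the 30 s immediately preceding inflation) and the recovery ("second")
#' baseline (mean over the final 60 s of recovery).
#'
#' @param trace a `vot_trace` (data.frame with `t`, `sto2`, `bfi`,
#'   optionally `cuff_pressure`; markers in the `markers` attribute).
#' @param protocol [vot_protocol()].
#' @param baseline_window_s pre-inflation averaging window, s.
#' @param recovery_window_s end-of-recovery averaging window, s.
#' @return list with `t_inflation`, `t_deflation`, `t_end`, phase table,
#'   `baseline_sto2`, `baseline_bfi`, `recovery_baseline_sto2`,
#'   `recovery_baseline_bfi`.
#' @export
segment_and_baseline <- function(trace, protocol = vot_protocol(),
                                 baseline_window_s = 30,
                                 recovery_window_s = 60) {
  mk <- attr(trace, "markers")
  if (is.null(mk) || !all(c("inflation", "deflation") %in% mk$label)) {
    if (is.null(trace$cuff_pressure)) {
      stop("no markers and no cuff-pressure channel to infer them from",
           call. = FALSE)
    }
    mk <- infer_markers_from_pressure(trace$t, trace$cuff_pressure)
  }
  t_inf <- mk$t[mk$label == "inflation"][1]
  t_def <- mk$t[mk$label == "deflation"][1]
  t_end <- if ("end" %in% mk$label) mk$t[mk$label == "end"][1] else
    max(trace$t)
  if (!(t_inf < t_def && t_def < t_end)) {
    stop("markers are misordered", call. = FALSE)
  }
  pre <- trace$t >= t_inf - baseline_window_s & trace$t < t_inf
  tail_w <- trace$t > t_end - recovery_window_s & trace$t <= t_end
  list(t_inflation = t_inf, t_deflation = t_def, t_end = t_end,
       phases = data.frame(
         phase = c("baseline", "occlusion", "recovery"),
         start = c(min(trace$t), t_inf, t_def),
         end = c(t_inf, t_def, t_end)),
       baseline_sto2 = mean(trace$sto2[pre]),
       baseline_bfi = mean(trace$bfi[pre]),
       recovery_baseline_sto2 = mean(trace$sto2[tail_w]),
       recovery_baseline_bfi = mean(trace$bfi[tail_w]))
}

#' Deoxygenation rate DeO2
#'
#' Ordinary least-squares slope of StO2 over the first minute of
#' occlusion, reported in %/min regardless of the sampling rate.
#'
#' @param trace a `vot_trace`.
#' @param t_inflation inflation time, s.
#' @param window_s fitting window after inflation, s (default 60).
#' @return slope in %/min.
#' @export
compute_deo2 <- function(trace, t_inflation, window_s = 60) {
  sel <- trace$t >= t_inflation & trace$t <= t_inflation + window_s
  if (sum(sel) < 10) stop("fewer than 10 samples in the DeO2 window",
                          call. = FALSE)
  unname(stats::coef(stats::lm(sto2 ~ t, trace[sel, ]))[2] * 60)
}

#' Reoxygenation rate ReO2
#'
#' OLS slope of StO2 from the minimum-StO2 sample (the last minimizing
#' sample up to deflation) to the first sample at or above the recovery
#' baseline, in %/s. When StO2 never regains the recovery baseline the
#' result is flagged excluded rather than raised.
#'
#' @param trace a `vot_trace`.
#' @param t_inflation,t_deflation phase markers, s.
#' @param recovery_baseline recovery ("second") baseline StO2, %.
#' @return list `reo2` (%/s or NA), `valid_recovery`, `t_min`,
#'   `min_sto2`.
#' @export
compute_reo2 <- function(trace, t_inflation, t_deflation,
                         recovery_baseline) {
  occl <- which(trace$t >= t_inflation & trace$t <= t_deflation)
  if (length(occl) < 2) stop("occlusion window empty", call. = FALSE)
  mn <- min(trace$sto2[occl])
  i_min <- occl[max(which(trace$sto2[occl] == mn))]   # latest minimiser
  after <- which(trace$t > trace$t[i_min])
  i_cross <- after[which(trace$sto2[after] >= recovery_baseline)[1]]
  if (is.na(i_cross) || length(i_cross) == 0) {
    return(list(reo2 = NA_real_, valid_recovery = FALSE,
                t_min = trace$t[i_min], min_sto2 = mn))
  }
  seg <- trace[i_min:i_cross, ]
  list(reo2 = unname(stats::coef(stats::lm(sto2 ~ t, seg))[2]),
       valid_recovery = TRUE, t_min = trace$t[i_min], min_sto2 = mn)
}

# first linear-interpolated crossing of y through 0 between successive
# samples, searching for the given sign change, at index >= from
interp_crossing <- function(t, y, from, direction = c("up", "down")) {
  direction <- match.arg(direction)
  n <- length(y)
  for (i in seq(max(from, 1), n - 1)) {
    hit <- if (direction == "up") y[i] <= 0 && y[i + 1] > 0 else
      y[i] > 0 && y[i + 1] <= 0
    if (hit) {
      f <- y[i] / (y[i] - y[i + 1])
      return(list(t = t[i] + f * (t[i + 1] - t[i]), i = i))
    }
  }
  NULL
}

#' Hyperemic area under the curve
#'
#' Trapezoidal integral of (signal - recovery baseline) between the first
#' upward and the subsequent downward crossing of the recovery baseline
#' after deflation, crossings located by linear interpolation. StO2 areas
#' are reported in %.min, BFI areas in cm^2.
#'
#' @param trace a `vot_trace`.
#' @param t_deflation deflation time, s.
#' @param recovery_baseline recovery baseline for the chosen channel.
#' @param channel "sto2" or "bfi".
#' @return list `auc`, `valid`, `t_up`, `t_down`; `valid = FALSE` with NA
#'   area when the excursion never closes (missing second crossing).
#' @export
compute_auc <- function(trace, t_deflation, recovery_baseline,
                        channel = c("sto2", "bfi")) {
  channel <- match.arg(channel)
  sel <- trace$t >= t_deflation
  t <- trace$t[sel]
  d <- trace[[channel]][sel] - recovery_baseline
  if (max(d) <= 0) {   # no excursion above baseline: zero area
    return(list(auc = 0, valid = TRUE, t_up = NA, t_down = NA))
  }
  # anchor the crossings around the excursion peak so that channel noise
  # near the baseline cannot truncate the hyperemic lobe
  i_peak <- which.max(d)
  up <- NULL
  if (i_peak > 1) {
    for (i in seq(i_peak - 1, 1)) {
      if (d[i] <= 0 && d[i + 1] > 0) {
        f <- d[i] / (d[i] - d[i + 1])
        up <- list(t = t[i] + f * (t[i + 1] - t[i]), i = i)
        break
      }
    }
  }
  if (is.null(up) && d[1] > 0) up <- list(t = t[1], i = 0L)
  if (is.null(up)) {
    return(list(auc = NA_real_, valid = FALSE, t_up = NA, t_down = NA))
  }
  down <- interp_crossing(t, d, i_peak, "down")
  if (is.null(down)) {
    return(list(auc = NA_real_, valid = FALSE, t_up = up$t, t_down = NA))
  }
  keep <- which(t > up$t & t <= down$t)
  tt <- c(up$t, t[keep[-length(keep)]], down$t)
  dd <- c(0, d[keep[-length(keep)]], 0)
  area <- sum(diff(tt) * (head_(dd) + tail_(dd)) / 2)
  if (channel == "sto2") area <- area / 60   # %.s -> %.min
  list(auc = area, valid = TRUE, t_up = up$t, t_down = down$t)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1]

#' Fick-law baseline metabolism indices
#'
#' MMRO2 = Hb * (SpO2 - StO2) / (gamma * SpO2) * BFI and the oxygen
#' extraction fraction OEF = 100 * (SpO2 - StO2) / (gamma * SpO2), with
#' gamma the venous blood fraction. SpO2 below StO2 yields a negative
#' index, returned with a warning flag.
#'
#' @param baseline_sto2 baseline StO2, %.
#' @param baseline_bfi baseline BFI, cm^2/s.
#' @param spo2 arterial saturation, %.
#' @param hb_gdl hemoglobin concentration, g/dL.
#' @param gamma venous blood fraction in (0, 1] (default 0.75).
#' @return a `metabolism_indices` list: `mmro2` (%.cm^2/s), `oef` (%),
#'   `gamma`, `hb_gdl`, `negative` flag.
#' @export
compute_metabolism <- function(baseline_sto2, baseline_bfi, spo2, hb_gdl,
                               gamma = 0.75) {
  stopifnot(spo2 > 0, gamma > 0, gamma <= 1)
  extraction <- (spo2 - baseline_sto2) / (gamma * spo2)
  neg <- extraction < 0
  if (neg) warning("SpO2 below StO2: negative extraction", call. = FALSE)
  structure(list(mmro2 = hb_gdl * extraction * baseline_bfi,
                 oef = 100 * extraction, gamma = gamma, hb_gdl = hb_gdl,
                 negative = neg),
            class = "metabolism_indices")
}

#' Extract all VOT biomarkers from a trace
#'
#' Convenience wrapper: segmentation and baselines, DeO2, ReO2, hyperemic
#' AUCs for StO2 and BFI, and (when SpO2 and hemoglobin are supplied) the
#' Fick-law metabolism indices. ReO2 and the AUCs are excluded (NA with
#' `valid_recovery = FALSE`) when StO2 does not regain the recovery
#' baseline.
#'
#' @param trace a `vot_trace`.
#' @param protocol [vot_protocol()].
#' @param spo2,hb_gdl,gamma metabolism inputs (optional).
#' @param recovery_tol relative shortfall of the recovery baseline below
#'   the pre-occlusion baseline beyond which the recovery is considered
#'   incomplete and ReO2/AUC are excluded (default 0.05).
#' @return an object of class `vot_biomarkers`.
#' @export
vot_biomarkers <- function(trace, protocol = vot_protocol(), spo2 = NULL,
                           hb_gdl = NULL, gamma = 0.75,
                           recovery_tol = 0.05) {
  seg <- segment_and_baseline(trace, protocol)
  deo2 <- compute_deo2(trace, seg$t_inflation)
  incomplete <- seg$recovery_baseline_sto2 <
    seg$baseline_sto2 * (1 - recovery_tol)
  re <- compute_reo2(trace, seg$t_inflation, seg$t_deflation,
                     seg$recovery_baseline_sto2)
  if (incomplete) {
    re$valid_recovery <- FALSE
    re$reo2 <- NA_real_
  }
  if (re$valid_recovery) {
    auc_s <- compute_auc(trace, seg$t_deflation,
                         seg$recovery_baseline_sto2, "sto2")
    auc_b <- compute_auc(trace, seg$t_deflation,
                         seg$recovery_baseline_bfi, "bfi")
  } else {
    auc_s <- auc_b <- list(auc = NA_real_, valid = FALSE)
  }
  metab <- if (!is.null(spo2) && !is.null(hb_gdl)) {
    compute_metabolism(seg$baseline_sto2, seg$baseline_bfi, spo2, hb_gdl,
                       gamma)
  }
  structure(list(
    baseline_sto2 = seg$baseline_sto2, baseline_bfi = seg$baseline_bfi,
    recovery_baseline_sto2 = seg$recovery_baseline_sto2,
    deo2 = deo2, reo2 = re$reo2, min_sto2 = re$min_sto2,
    auc_sto2 = auc_s$auc, auc_bfi = auc_b$auc,
    valid_recovery = re$valid_recovery && auc_s$valid,
    metabolism = metab, segmentation = seg),
    class = "vot_biomarkers")
}

#' @export
print.vot_biomarkers <- function(x, ...) {
  cat("VOT biomarkers\n")
  cat(sprintf("  baseline StO2 %.1f%%, baseline BFI %.3e cm^2/s\n",
              x$baseline_sto2, x$baseline_bfi))
  cat(sprintf("  DeO2 %.2f %%/min, min StO2 %.1f%%\n", x$deo2, x$min_sto2))
  if (x$valid_recovery) {
    cat(sprintf("  ReO2 %.2f %%/s, AUC StO2 %.2f %%.min, AUC BFI %.3e cm^2\n",
                x$reo2, x$auc_sto2, x$auc_bfi))
  } else {
    cat("  recovery did not regain baseline: ReO2/AUC excluded\n")
  }
  if (!is.null(x$metabolism)) {
    cat(sprintf("  OEF %.1f%%, MMRO2 %.3e %%.cm^2/s (gamma %.2f)\n",
                x$metabolism$oef, x$metabolism$mmro2, x$metabolism$gamma))
  }
  invisible(x)
}
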