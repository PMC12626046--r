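# Precision and agreement analytics: coefficient of variation,
# test-retest, graded-occlusion precision, resampling to a slower
# device, Bland-Altman agreement, and rank-based group comparison.

#' Coefficient of variation
#'
#' CV = 100 * sd(x) / mean(x) with the sample (n-1) standard deviation.
#' A zero mean leaves the CV undefined (flagged, NA).
#'
#' @param x numeric vector, length >= 2.
#' @return a `cv_result` list: `mean`, `sd`, `cv` (%), `n`, `undefined`.
#' @export
cv_series <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  undef <- m == 0
  structure(list(mean = m, sd = s,
                 cv = if (undef) NA_real_ else 100 * s / abs(m),
                 n = length(x), undefined = undef),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV = %s%% (mean %.4g, sd %.4g, n %d)\n",
              if (x$undefined) "undefined" else sprintf("%.3f", x$cv),
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Test-retest variability over probe repositionings
#'
#' Intra-block CV (per repositioning, and its maximum) and inter-block
#' CV (CV of the block means) for a repositioning experiment.
#'
#' @param blocks list of numeric vectors, one per repositioning (>= 2
#'   blocks, each with >= 2 samples).
#' @return list `intra` (per-block CVs, %), `intra_max`, `inter`
#'   (`cv_result` of the block means), `block_means`.
#' @export
test_retest <- function(blocks) {
  if (length(blocks) < 2) stop("need >= 2 blocks", call. = FALSE)
  if (any(vapply(blocks, length, 0L) < 2)) {
    stop("every block needs >= 2 samples", call. = FALSE)
  }
  intra <- vapply(blocks, function(b) cv_series(b)$cv, 0)
  means <- vapply(blocks, mean, 0)
  list(intra = intra, intra_max = max(intra), inter = cv_series(means),
       block_means = means)
}

spearman_test <- function(x, y) {
  n <- length(x)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 10))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Graded-occlusion (LOP step) precision analysis
#'
#' For each inflation/deflation step of the limb-occlusion-pressure
#' protocol, computes the CV of StO2 and BFI over the final evaluation
#' window, then Spearman correlations of those CVs against the step mean
#' values and the signal-quality indices (DCS count rate for BFI,
#' TD-NIRS dynamic range for StO2).
#'
#' @param trace data.frame with columns `timestamp`, `step`, `fraction`,
#'   `phase`, `sto2`, `bfi`, `count_rate`, `dynamic_range` (the `lop`
#'   channel of a simulated session).
#' @param protocol [lop_protocol()].
#' @return list `per_step` (CVs and means per step/phase) and
#'   `correlations` (Spearman rho and p per pairing).
#' @export
lop_precision <- function(trace, protocol = lop_protocol()) {
  need <- expand.grid(fraction = protocol$steps,
                      phase = c("inflation", "deflation"))
  have <- unique(trace[trace$phase != "baseline", c("fraction", "phase")])
  miss <- !apply(need, 1, function(r) {
    any(abs(have$fraction - as.numeric(r["fraction"])) < 1e-9 &
          have$phase == r["phase"])
  })
  if (any(miss)) stop("missing LOP step(s) in the trace", call. = FALSE)
  steps <- split(trace[trace$phase != "baseline", ],
                 interaction(trace$fraction[trace$phase != "baseline"],
                             trace$phase[trace$phase != "baseline"],
                             drop = TRUE))
  per_step <- do.call(rbind, lapply(steps, function(s) {
    s <- s[order(s$timestamp), ]
    w <- s[s$timestamp > max(s$timestamp) - protocol$eval_window_s, ]
    data.frame(fraction = s$fraction[1], phase = s$phase[1],
               mean_sto2 = mean(w$sto2), cv_sto2 = cv_series(w$sto2)$cv,
               mean_bfi = mean(w$bfi), cv_bfi = cv_series(w$bfi)$cv,
               count_rate = mean(w$count_rate),
               dynamic_range = mean(w$dynamic_range))
  }))
  rownames(per_step) <- NULL
  pair <- function(a, b) {
    s <- spearman_test(per_step[[a]], per_step[[b]])
    data.frame(x = a, y = b, rho = s$rho, p = s$p)
  }
  correlations <- rbind(pair("cv_sto2", "mean_sto2"),
                        pair("cv_sto2", "dynamic_range"),
                        pair("cv_bfi", "mean_bfi"),
                        pair("cv_bfi", "count_rate"))
  list(per_step = per_step, correlations = correlations)
}

#' Bland-Altman agreement analysis
#'
#' Differences (a - b) against means (a + b)/2: bias, +/-1.96 sd limits
#' of agreement, and the OLS slope of the difference on the mean with
#' its correlation and p value (proportional-bias test).
#'
#' @param a,b paired numeric series of equal length, n >= 3.
#' @return a `bland_altman_result`: `bias`, `loa_low`, `loa_high`,
#'   `slope`, `slope_r`, `slope_p`, plus the differences and means.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  if (stats::sd(m) == 0 || stats::sd(d) == 0) {
    slope <- 0; r <- 0; p <- 1
  } else {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    ct <- stats::cor.test(d, m)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, slope = slope, slope_r = r,
                 slope_p = p, differences = d, means = m),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.3f [LoA %.3f, %.3f], slope %.3f (r %.2f, p %.3g)\n",
    x$bias, x$loa_low, x$loa_high, x$slope, x$slope_r, x$slope_p))
  invisible(x)
}

#' @export
plot.bland_altman_result <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean of devices",
                 ylab = "difference", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Resample a series to a slower device's timestamps
#'
#' Sample-and-hold (nearest-preceding-sample) resampling by default,
#' mimicking a slow display device; linear interpolation by flag. Values
#' at coincident timestamps are preserved exactly. Target times outside
#' the source span raise an error.
#'
#' @param t_src,x_src source timestamps and values.
#' @param t_target target timestamps (within the source span).
#' @param method "hold" (default) or "linear".
#' @return numeric vector of resampled values at `t_target`.
#' @export
resample_to_device <- function(t_src, x_src, t_target,
                               method = c("hold", "linear")) {
  method <- match.arg(method)
  stopifnot(length(t_src) == length(x_src))
  if (any(t_target < min(t_src)) || any(t_target > max(t_src))) {
    stop("extrapolation outside the source span requested", call. = FALSE)
  }
  if (method == "hold") {
    idx <- findInterval(t_target, t_src)
    x_src[idx]
  } else {
    stats::approx(t_src, x_src, xout = t_target)$y
  }
}

#' Rank-based group comparison
#'
#' Mann-Whitney U (unpaired) or Wilcoxon signed-rank (paired) comparison
#' with a configurable significance level.
#'
#' @param group_a,group_b numeric vectors.
#' @param paired paired comparison? (equal lengths required).
#' @param alpha significance level (default 0.05).
#' @return list `statistic`, `p`, `significant`, `method`.
#' @export
group_compare <- function(group_a, group_b, paired = FALSE, alpha = 0.05) {
  if (paired && length(group_a) != length(group_b)) {
    stop("paired comparison with unequal lengths", call. = FALSE)
  }
  w <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, paired = paired))
  list(statistic = unname(w$statistic), p = w$p.value,
       significant = w$p.value < alpha,
       method = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u")
}
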