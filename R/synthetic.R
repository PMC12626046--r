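# Synthetic-data generators: every input the inverse pipeline consumes,
# with the statistical structure the analysis assumes (Poisson counting
# noise on histograms, count-rate-dependent g2 noise, Gaussian channel
# noise on physiological traces).

#' Gaussian instrument response function
#'
#' Builds an IRF histogram on the shared time grid: a Gaussian of given
#' FWHM centered at `center_ns`, scaled to `total_counts`, optionally with
#' Poisson counting noise. The default (FWHM 200 ps, center 3.9 ns)
#' matches the scale of a pulsed-diode TD-NIRS chain whose barycenter
#' sits near 3.9 ns.
#'
#' @param spec [forward_model_spec()].
#' @param center_ns Gaussian center, ns.
#' @param fwhm_ps full width at half maximum, ps.
#' @param total_counts total photons in the histogram.
#' @param wavelength nm, carried as metadata.
#' @param noise draw Poisson counts per bin?
#' @param seed optional seed for the Poisson draw.
#' @return an `irf_record` (see [compute_irf_metrics()] for the metrics).
#' @export
gaussian_irf <- function(spec = forward_model_spec(), center_ns = 3.9,
                         fwhm_ps = 200, total_counts = 1e6,
                         wavelength = NA_real_, noise = FALSE, seed = NULL) {
  sigma <- fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))   # ns
  shape <- stats::dnorm(spec$time_centers, center_ns, sigma)
  shape <- shape / sum(shape) * total_counts
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    shape <- stats::rpois(length(shape), shape)
  }
  new_irf_record(spec$time_edges, shape, wavelength)
}

#' Ideal (delta-function) IRF
#'
#' All counts in the first bin; the identity element of the circular
#' convolution used by [generate_dtof()].
#'
#' @inheritParams gaussian_irf
#' @export
delta_irf <- function(spec = forward_model_spec(), wavelength = NA_real_) {
  h <- numeric(length(spec$time_centers))
  h[1] <- 1
  new_irf_record(spec$time_edges, h, wavelength)
}

new_irf_record <- function(bin_edges, histogram, wavelength = NA_real_,
                           acquisition_date = NA) {
  structure(list(bin_edges = bin_edges, histogram = histogram,
                 wavelength = wavelength, acquisition_date = acquisition_date),
            class = "irf_record")
}

new_dtof_histogram <- function(bin_edges, counts, wavelength,
                               timestamp = 0, integration_time = 1) {
  stopifnot(length(counts) == length(bin_edges) - 1L, all(counts >= 0))
  structure(list(bin_edges = bin_edges, counts = counts,
                 wavelength = wavelength, timestamp = timestamp,
                 integration_time = integration_time),
            class = "dtof_histogram")
}

# circular convolution over the laser period, both vectors on one grid
circular_convolve <- function(x, kernel) {
  n <- length(x)
  if (length(kernel) != n) {
    stop("IRF histogram does not cover the DTOF time grid", call. = FALSE)
  }
  out <- Re(stats::fft(stats::fft(x) * stats::fft(kernel), inverse = TRUE)) / n
  pmax(out, 0)
}

#' Simulate a measured DTOF histogram
#'
#' Convolves the diffusion-theory reflectance with the IRF (circularly
#' over the laser period, as a repetition-rate-synchronised histogrammer
#' does), scales the signal to `total_counts` expected photons, adds a
#' uniform dark floor of `dark_rate * integration_time` counts, and draws
#' Poisson counts per bin.
#'
#' @param props [optical_properties()] of the medium.
#' @param irf `irf_record` on the same time grid (normalised internally).
#' @param geom [probe_geometry()].
#' @param spec [forward_model_spec()].
#' @param total_counts expected total signal photons (default 1e6).
#' @param dark_rate dark counts per second (default 0).
#' @param integration_time acquisition time, s.
#' @param noise draw Poisson noise? `FALSE` returns the expectation.
#' @param seed optional seed.
#' @param timestamp acquisition timestamp, s.
#' @return a `dtof_histogram`.
#' @export
generate_dtof <- function(props, irf, geom = probe_geometry(),
                          spec = forward_model_spec(), total_counts = 1e6,
                          dark_rate = 0, integration_time = 1,
                          noise = TRUE, seed = NULL, timestamp = 0) {
  stopifnot(inherits(irf, "irf_record"))
  stop_if_not_scalar_pos(total_counts, "total_counts")
  theo <- simulate_reflectance_curve(props, geom, spec)
  kern <- irf$histogram / sum(irf$histogram)
  sig <- circular_convolve(theo, kern)
  sig <- sig / sum(sig) * total_counts
  expected <- sig + dark_rate * integration_time / length(sig)
  counts <- if (noise) {
    if (!is.null(seed)) set.seed(seed)
    stats::rpois(length(expected), expected)
  } else expected
  new_dtof_histogram(spec$time_edges, counts, props$wavelength,
                     timestamp, integration_time)
}

#' Simulate a measured g2 curve
#'
#' Noiseless mean 1 + beta*|g1|^2 with the semi-infinite
#' correlation-diffusion g1, plus zero-mean Gaussian noise whose per-lag
#' standard deviation is `noise_scale * (1 + beta*g1^2) /
#' sqrt(count_rate_kHz * 1000 * avg_time)` — larger where the curve sits
#' higher and shrinking with the number of detected photons, the leading
#' behaviour of correlator noise. Values are not clipped; noise may take
#' g2 slightly outside [1, 1+beta].
#'
#' @param props_785 `optical_properties` at the DCS wavelength.
#' @param bfi blood-flow index, cm^2/s.
#' @param beta coherence factor in (0, 1]; 0.5 for ideal single-mode
#'   detection of unpolarised light (the generator's default).
#' @param geom [probe_geometry()].
#' @param spec [forward_model_spec()] supplying the lag grid.
#' @param count_rate detected count rate, kHz.
#' @param avg_time correlator averaging time, s (26 ms for the raw
#'   hardware cadence; 1 s after block averaging).
#' @param noise add noise? @param seed optional seed.
#' @param noise_scale dimensionless noise amplitude (default 3).
#' @param timestamp acquisition timestamp, s.
#' @return a `g2_curve`: list with `lag` (s), `g2`, `count_rate` (kHz),
#'   `timestamp` (s), `avg_time` (s).
#' @export
generate_g2 <- function(props_785, bfi, beta = 0.5, geom = probe_geometry(),
                        spec = forward_model_spec(), count_rate = 50,
                        avg_time = 1, noise = TRUE, seed = NULL,
                        noise_scale = 3, timestamp = 0) {
  stopifnot(beta > 0, beta <= 1)
  stop_if_not_scalar_pos(avg_time, "avg_time")
  if (length(spec$lag_grid) == 0) stop("empty lag grid", call. = FALSE)
  g1 <- g1_semiinf(spec$lag_grid, props_785, bfi, geom)
  g2 <- 1 + beta * g1^2
  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    sd <- noise_scale * (1 + beta * g1^2) /
      sqrt(count_rate * 1000 * avg_time)
    g2 <- g2 + stats::rnorm(length(g2), 0, sd)
  }
  new_g2_curve(spec$lag_grid, g2, count_rate, timestamp, avg_time)
}

new_g2_curve <- function(lag, g2, count_rate, timestamp = 0, avg_time = 1) {
  stopifnot(length(lag) == length(g2), all(diff(lag) > 0))
  structure(list(lag = lag, g2 = g2, count_rate = count_rate,
                 timestamp = timestamp, avg_time = avg_time),
            class = "g2_curve")
}

#' VOT physiology parameters
#'
#' Parameterises the schematic StO2/BFI response to a vascular occlusion
#' test: a baseline plateau, linear desaturation during occlusion, linear
#' reoxygenation to a hyperemic peak on cuff release, and exponential
#' relaxation back to baseline (a shifted exponential that reaches
#' baseline exactly at the end of the recovery window, so the analytic
#' trace admits the two baseline crossings the AUC definition requires).
#' Defaults follow healthy-adult forearm-muscle values.
#'
#' @param baseline_sto2 baseline StO2, %.
#' @param baseline_bfi baseline blood-flow index, cm^2/s.
#' @param desat_rate desaturation slope during occlusion, %/min (< 0).
#' @param min_sto2 floor StO2 during occlusion, %.
#' @param reo2_rate reoxygenation slope on release, %/s.
#' @param hyperemia_peak_sto2 hyperemic StO2 peak, %.
#' @param hyperemia_peak_bfi_ratio peak BFI as multiple of baseline.
#' @param recovery_tau relaxation time constant, s.
#' @param occlusion_bfi_frac residual BFI during occlusion (fraction).
#' @param noise_sd_sto2 Gaussian noise sd on StO2, %.
#' @param noise_sd_bfi_relative Gaussian noise sd on BFI, fraction.
#' @param spo2,hr,systolic oximeter and pressure context values.
#' @return an object of class `vot_physiology`.
#' @export
vot_physiology <- function(baseline_sto2 = 70.3, baseline_bfi = 0.53e-8,
                           desat_rate = -4.1, min_sto2 = 40,
                           reo2_rate = 1.1, hyperemia_peak_sto2 = 78.3,
                           hyperemia_peak_bfi_ratio = 5, recovery_tau = 55,
                           occlusion_bfi_frac = 0.05,
                           noise_sd_sto2 = 0.5, noise_sd_bfi_relative = 0.12,
                           spo2 = 99, hr = 64, systolic = 120) {
  stopifnot(baseline_sto2 > 0, baseline_sto2 < 100, desat_rate < 0,
            hyperemia_peak_sto2 > baseline_sto2, reo2_rate > 0,
            noise_sd_sto2 >= 0, noise_sd_bfi_relative >= 0,
            recovery_tau > 0, occlusion_bfi_frac >= 0)
  structure(as.list(environment()), class = "vot_physiology")
}

# shifted exponential from `peak` to `base`, hitting base exactly at t = Tend
shifted_exp <- function(t, peak, base, tau, t_end) {
  q <- exp(-t_end / tau)
  base + (peak - base) * (exp(-t / tau) - q) / (1 - q)
}

#' Simulate a vascular-occlusion-test time course
#'
#' Emits the synchronised multichannel trace of a VOT session: StO2 and
#' BFI following the physiological trajectory of [vot_physiology()], a
#' rectangular cuff-pressure channel at systolic + 50 mmHg, constant
#' SpO2/HR oximeter channels, and inflation/deflation/end markers.
#'
#' @param protocol [vot_protocol()] phase durations.
#' @param phys [vot_physiology()].
#' @param fs sampling rate, Hz (default 1).
#' @param noise add per-channel Gaussian noise?
#' @param seed optional seed.
#' @return a `vot_trace`: data.frame `t`, `sto2`, `bfi`, `spo2`, `hr`,
#'   `cuff_pressure` with a `markers` attribute (data.frame label, t).
#' @export
simulate_vot_timecourse <- function(protocol = vot_protocol(),
                                    phys = vot_physiology(), fs = 1,
                                    noise = TRUE, seed = NULL) {
  stopifnot(inherits(phys, "vot_physiology"))
  if (phys$min_sto2 >= phys$baseline_sto2) {
    stop("min_sto2 must be below baseline_sto2", call. = FALSE)
  }
  t_inf <- protocol$baseline_s
  t_def <- t_inf + protocol$occlusion_s
  t_end <- t_def + protocol$recovery_s
  t <- seq(0, t_end, by = 1 / fs)

  b <- phys$baseline_sto2
  sto2 <- rep(b, length(t))
  occl <- t >= t_inf & t < t_def
  sto2[occl] <- pmax(b + phys$desat_rate * (t[occl] - t_inf) / 60,
                     phys$min_sto2)
  s_def <- max(b + phys$desat_rate * protocol$occlusion_s / 60, phys$min_sto2)
  p <- phys$hyperemia_peak_sto2
  t_rise <- (p - s_def) / phys$reo2_rate
  rec <- t >= t_def
  tr <- t[rec] - t_def
  sto2[rec] <- ifelse(tr <= t_rise, s_def + phys$reo2_rate * tr,
                      shifted_exp(tr - t_rise, p, b, phys$recovery_tau,
                                  protocol$recovery_s - t_rise))

  bb <- phys$baseline_bfi
  bfi <- rep(bb, length(t))
  bfi[occl] <- phys$occlusion_bfi_frac * bb
  bp <- phys$hyperemia_peak_bfi_ratio * bb
  bfi_rise <- 5   # s, rapid hyperemic inrush
  bfi[rec] <- ifelse(tr <= bfi_rise,
                     phys$occlusion_bfi_frac * bb +
                       (bp - phys$occlusion_bfi_frac * bb) * tr / bfi_rise,
                     shifted_exp(tr - bfi_rise, bp, bb, phys$recovery_tau,
                                 protocol$recovery_s - bfi_rise))

  cuff <- ifelse(occl, phys$systolic + 50, 0)
  spo2 <- rep(phys$spo2, length(t))
  hr <- rep(phys$hr, length(t))

  if (noise) {
    if (!is.null(seed)) set.seed(seed)
    sto2 <- sto2 + stats::rnorm(length(t), 0, phys$noise_sd_sto2)
    bfi <- bfi * (1 + stats::rnorm(length(t), 0, phys$noise_sd_bfi_relative))
    spo2 <- spo2 + stats::rnorm(length(t), 0, 0.3)
    hr <- hr + stats::rnorm(length(t), 0, 1)
  }

  out <- data.frame(t = t, sto2 = sto2, bfi = bfi, spo2 = spo2, hr = hr,
                    cuff_pressure = cuff)
  attr(out, "markers") <- data.frame(
    label = c("inflation", "deflation", "end"),
    t = c(t_inf, t_def, t_end), stringsAsFactors = FALSE)
  attr(out, "protocol") <- protocol
  class(out) <- c("vot_trace", "data.frame")
  out
}

#' Simulate a complete on-disk session
#'
#' Writes a session directory (manifest + channel tables, see
#' [write_session()]) of the requested kind:
#' \describe{
#'   \item{phantom}{IRF plus exactly 20 one-second DTOF repetitions per
#'     wavelength at the solid-phantom preset, 1e6 counts each.}
#'   \item{irf}{a single IRF histogram per wavelength.}
#'   \item{vot}{fitted-parameter trace (StO2, BFI) plus oximeter, cuff
#'     and marker channels from [simulate_vot_timecourse()].}
#'   \item{test_retest}{5 probe repositionings of ~200 s at 1 Hz with a
#'     between-repositioning variability term on the block means.}
#'   \item{lop}{graded-occlusion precision protocol: 60 s baseline then
#'     inflation/deflation steps of 60 s at 40/60/80/100% of the limb
#'     occlusion pressure, with noise scaling inversely with the
#'     signal level.}
#'   \item{qp}{quality-assessment phase: 60 s equalisation then
#'     alternating 10 s laser ON/OFF segments cycling both modules, with
#'     configurable dark, signal and cross-talk count levels.}
#' }
#'
#' @param kind one of "phantom", "irf", "vot", "test_retest", "lop", "qp".
#' @param out_dir directory to create.
#' @param seed session seed; all sub-streams derive from it via
#'   [split_seed()].
#' @param config named list of overrides (see details of each kind in the
#'   package vignette).
#' @return the session directory path, invisibly.
#' @export
simulate_session <- function(kind, out_dir, seed = 1L, config = list()) {
  kind <- match.arg(kind, c("phantom", "irf", "vot", "test_retest",
                            "lop", "qp"))
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  spec <- cfg("spec", forward_model_spec())
  geom <- cfg("geom", probe_geometry())
  channels <- list()
  protocol <- list()

  if (kind %in% c("phantom", "irf")) {
    k <- 0L
    for (wl in geom$wavelengths) {
      irf <- gaussian_irf(spec, center_ns = cfg("irf_center_ns", 3.9),
                          fwhm_ps = cfg("irf_fwhm_ps", 200),
                          total_counts = cfg("irf_counts", 1e6),
                          wavelength = wl, noise = TRUE,
                          seed = split_seed(seed, k <- k + 1L))
      channels[[paste0("irf_", wl)]] <- list(
        data = histogram_to_row(irf$histogram, 0),
        units = c(timestamp = "s", bins = "photons/bin"),
        cadence = NA_real_)
      if (kind == "phantom") {
        props <- cfg(paste0("props_", wl), phantom_preset(wl))
        n_rep <- cfg("n_rep", 20L)
        rows <- lapply(seq_len(n_rep), function(i) {
          d <- generate_dtof(props, irf, geom, spec,
                             total_counts = cfg("total_counts", 1e6),
                             dark_rate = cfg("dark_rate", 1000),
                             seed = split_seed(seed, 100L * match(wl, geom$wavelengths) + i),
                             timestamp = i - 1)
          histogram_to_row(d$counts, d$timestamp)
        })
        channels[[paste0("dtof_", wl)]] <- list(
          data = do.call(rbind, rows),
          units = c(timestamp = "s", bins = "photons/bin"),
          cadence = 1)
      }
    }
    protocol <- list(n_rep = if (kind == "phantom") cfg("n_rep", 20L) else NULL)
  } else if (kind == "vot") {
    proto <- cfg("protocol", vot_protocol())
    phys <- cfg("phys", vot_physiology())
    trace <- simulate_vot_timecourse(proto, phys, fs = cfg("fs", 1),
                                     noise = cfg("noise", TRUE),
                                     seed = split_seed(seed, 1L))
    channels$hemo <- list(
      data = data.frame(timestamp = trace$t, sto2 = trace$sto2,
                        bfi = trace$bfi),
      units = c(timestamp = "s", sto2 = "%", bfi = "cm^2/s"), cadence = 1)
    channels$oximeter <- list(
      data = data.frame(timestamp = trace$t, spo2 = trace$spo2,
                        hr = trace$hr, ppg = 1),
      units = c(timestamp = "s", spo2 = "%", hr = "beats/min", ppg = "a.u."),
      cadence = 1)
    channels$cuff <- list(
      data = data.frame(timestamp = trace$t,
                        pressure = trace$cuff_pressure),
      units = c(timestamp = "s", pressure = "mmHg"), cadence = 1)
    mk <- attr(trace, "markers")
    channels$markers <- list(
      data = data.frame(timestamp = mk$t, label = mk$label),
      units = c(timestamp = "s", label = "event"), cadence = NA_real_)
    protocol <- unclass(proto)
  } else if (kind == "test_retest") {
    n_blocks <- cfg("n_blocks", 5L)
    block_s <- cfg("block_s", 200)
    sto2_mean <- cfg("sto2_mean", 70.3)
    bfi_mean <- cfg("bfi_mean", 0.53e-8)
    between_sd_sto2 <- cfg("between_sd_sto2", 0.012 * sto2_mean)
    between_rel_sd_bfi <- cfg("between_rel_sd_bfi", 0.126)
    within_sd_sto2 <- cfg("within_sd_sto2", 0.5)
    within_rel_sd_bfi <- cfg("within_rel_sd_bfi", 0.12)
    set.seed(split_seed(seed, 1L))
    mu_s <- stats::rnorm(n_blocks, sto2_mean, between_sd_sto2)
    mu_b <- bfi_mean * (1 + stats::rnorm(n_blocks, 0, between_rel_sd_bfi))
    rows <- lapply(seq_len(n_blocks), function(b) {
      set.seed(split_seed(seed, 10L + b))
      tt <- seq(0, block_s - 1)
      data.frame(timestamp = (b - 1) * block_s + tt, block = b,
                 sto2 = mu_s[b] + stats::rnorm(block_s, 0, within_sd_sto2),
                 bfi = mu_b[b] * (1 + stats::rnorm(block_s, 0, within_rel_sd_bfi)))
    })
    channels$retest <- list(
      data = do.call(rbind, rows),
      units = c(timestamp = "s", block = "index", sto2 = "%",
                bfi = "cm^2/s"), cadence = 1)
    protocol <- list(n_blocks = n_blocks, block_s = block_s)
  } else if (kind == "lop") {
    proto <- cfg("protocol", lop_protocol())
    rows <- simulate_lop_trace(proto, seed, config)
    channels$lop <- list(
      data = rows,
      units = c(timestamp = "s", step = "index", fraction = "of LOP",
                phase = "label", sto2 = "%", bfi = "cm^2/s",
                count_rate = "kHz", dynamic_range = "ratio"),
      cadence = 1)
    protocol <- unclass(proto)
  } else if (kind == "qp") {
    rows <- simulate_qp_segments(seed, config)
    channels$qp <- list(
      data = rows,
      units = c(timestamp = "s", segment = "index", dcs_laser = "on/off",
                tdnirs_laser = "on/off", dcs_khz = "kHz",
                tdnirs_685_cps = "counts/s", tdnirs_828_cps = "counts/s",
                oxi_valid = "flag"),
      cadence = 1)
    protocol <- list(segment_s = cfg("segment_s", 10),
                     equalization_s = cfg("equalization_s", 60))
  }

  manifest <- list(session_id = cfg("session_id", paste0(kind, "-", seed)),
                   kind = kind, seed = seed,
                   created = cfg("created", "1970-01-01T00:00:00Z"),
                   protocol = protocol)
  write_session(out_dir, manifest, channels)
  invisible(out_dir)
}

histogram_to_row <- function(counts, timestamp) {
  row <- as.data.frame(t(counts))
  names(row) <- sprintf("bin_%04d", seq_along(counts))
  cbind(data.frame(timestamp = timestamp), row)
}

# graded-occlusion (LOP fraction) trace used by the lop session kind
simulate_lop_trace <- function(proto, seed, config = list()) {
  cfg <- function(name, default)
    if (!is.null(config[[name]])) config[[name]] else default
  base_sto2 <- cfg("sto2_mean", 70.3)
  base_bfi <- cfg("bfi_mean", 0.53e-8)
  base_count <- cfg("count_rate_khz", 50)
  base_dr <- cfg("dynamic_range", 3000)
  noise0_sto2 <- cfg("noise_sd_sto2", 0.5)
  noise0_bfi <- cfg("noise_rel_bfi", 0.10)
  set.seed(split_seed(seed, 3L))
  steps <- data.frame(step = 0L, fraction = 0, phase = "baseline")
  for (i in seq_along(proto$steps)) {
    steps <- rbind(steps,
      data.frame(step = i, fraction = proto$steps[i], phase = "inflation"),
      data.frame(step = i, fraction = proto$steps[i], phase = "deflation"))
  }
  rows <- list()
  t0 <- 0
  for (i in seq_len(nrow(steps))) {
    f <- steps$fraction[i]
    infl <- steps$phase[i] == "inflation"
    dur <- if (steps$phase[i] == "baseline") cfg("baseline_s", 60) else proto$step_s
    # occlusion depresses StO2/BFI and the detected light level in step
    m_sto2 <- base_sto2 - if (infl) 12 * f else 2 * f
    m_bfi <- base_bfi * if (infl) (1 - 0.9 * f) else 1
    count <- base_count * (1 - cfg("light_drop", 0.5) * f * infl)
    dr <- base_dr * (1 - cfg("light_drop", 0.5) * f * infl)
    sd_s <- noise0_sto2 * base_count / count
    sd_b <- noise0_bfi * base_count / count
    tt <- seq(t0, t0 + dur - 1)
    rows[[i]] <- data.frame(
      timestamp = tt, step = steps$step[i], fraction = f,
      phase = steps$phase[i],
      sto2 = m_sto2 + stats::rnorm(dur, 0, sd_s),
      bfi = m_bfi * (1 + stats::rnorm(dur, 0, sd_b)),
      count_rate = count, dynamic_range = dr)
    t0 <- t0 + dur
  }
  do.call(rbind, rows)
}

# quality-phase ON/OFF segment counts used by the qp session kind
simulate_qp_segments <- function(seed, config = list()) {
  cfg <- function(name, default)
    if (!is.null(config[[name]])) config[[name]] else default
  segment_s <- cfg("segment_s", 10)
  eq_s <- cfg("equalization_s", 60)
  n_cycles <- cfg("n_cycles", 2L)
  lv <- list(dcs_dark_khz = cfg("dcs_dark_khz", 1.0),
             dcs_signal_khz = cfg("dcs_signal_khz", 50),
             dcs_crosstalk_khz = cfg("dcs_crosstalk_khz", 1.0),
             tdnirs_signal_cps = cfg("tdnirs_signal_cps", 1.0e6),
             tdnirs_dark_cps = cfg("tdnirs_dark_cps", 1.0e4),
             tdnirs_crosstalk_cps = cfg("tdnirs_crosstalk_cps", 1.5e4))
  combos <- data.frame(dcs = c("on", "off", "off", "on", "off"),
                       td = c("off", "off", "on", "on", "off"))
  set.seed(split_seed(seed, 4L))
  rows <- list()
  seg_id <- 0L
  t0 <- 0
  add_segment <- function(dcs, td, dur) {
    seg_id <<- seg_id + 1L
    dcs_mean <- if (dcs == "on") lv$dcs_signal_khz else
      if (td == "on") lv$dcs_crosstalk_khz else lv$dcs_dark_khz
    td_mean <- if (td == "on") lv$tdnirs_signal_cps else
      if (dcs == "on") lv$tdnirs_crosstalk_cps else lv$tdnirs_dark_cps
    tt <- seq(t0, t0 + dur - 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      timestamp = tt, segment = seg_id, dcs_laser = dcs, tdnirs_laser = td,
      dcs_khz = stats::rpois(dur, dcs_mean * 1000) / 1000,
      tdnirs_685_cps = stats::rpois(dur, td_mean),
      tdnirs_828_cps = stats::rpois(dur, td_mean),
      oxi_valid = cfg("oxi_valid", TRUE))
    t0 <<- t0 + dur
  }
  add_segment("off", "on", eq_s)                 # TD-NIRS equalization
  for (c in seq_len(n_cycles)) {
    for (i in seq_len(nrow(combos))) {
      add_segment(combos$dcs[i], combos$td[i], segment_s)
    }
  }
  do.call(rbind, rows)
}
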