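# VOT segmentation, biomarker extraction, and metabolism indices.

test_that("segmentation baselines average constant channels exactly", {
  mk <- data.frame(label = c("inflation", "deflation", "end"),
                   t = c(180, 360, 660))
  tr <- make_trace(0:660, rep(70, 661), rep(1e-8, 661), markers = mk)
  seg <- segment_and_baseline(tr)
  expect_equal(seg$baseline_sto2, 70)
  expect_equal(seg$recovery_baseline_bfi, 1e-8)
  expect_equal(seg$t_inflation, 180)
})

test_that("markers are inferred from a rectangular pressure channel", {
  t <- 0:660
  cuff <- ifelse(t >= 180 & t < 360, 170, 0)
  tr <- make_trace(t, rep(70, 661), cuff = cuff)
  seg <- segment_and_baseline(tr)
  expect_lt(abs(seg$t_inflation - 180), 1)
  expect_lt(abs(seg$t_deflation - 360), 1)
  tr2 <- make_trace(t, rep(70, 661))
  expect_error(segment_and_baseline(tr2), "markers")
})

test_that("DeO2 recovers exact and noisy slopes in %/min", {
  t <- 0:660
  sto2 <- ifelse(t < 180, 70, 70 - 5 * (t - 180) / 60)   # -5 %/min
  tr <- make_trace(t, sto2)
  expect_equal(compute_deo2(tr, 180), -5, tolerance = 1e-10)
  # noisy line stays within the closed-form OLS standard error
  set.seed(7)
  trn <- make_trace(t, sto2 + rnorm(length(t), 0, 0.5))
  se_slope <- 0.5 / sqrt(sum((0:60 - 30)^2)) * 60   # %/min
  expect_lt(abs(compute_deo2(trn, 180) + 5), 4 * se_slope)
  expect_error(compute_deo2(make_trace(0:5, rep(70, 6)), 0), "10 samples")
})

test_that("ReO2 is an exact slope in %/s and respects the exclusion rule", {
  t <- 0:500
  sto2 <- rep(70, 501)
  sto2[t >= 100 & t <= 300] <- 40                     # occlusion floor
  rise <- t > 300 & t <= 330
  sto2[rise] <- 40 + 1 * (t[rise] - 300)              # 1 %/s
  r <- compute_reo2(make_trace(t, sto2), 100, 300, 70)
  expect_true(r$valid_recovery)
  expect_equal(r$reo2, 1, tolerance = 1e-10)
  expect_equal(r$min_sto2, 40)
  # plateau below baseline is excluded, not raised
  sto2b <- sto2; sto2b[t > 300] <- pmin(sto2[t > 300], 60)
  rb <- compute_reo2(make_trace(t, sto2b), 100, 300, 70)
  expect_false(rb$valid_recovery)
  expect_true(is.na(rb$reo2))
})

test_that("slope units are rate-independent", {
  for (fs in c(0.5, 2)) {
    phys <- vot_physiology(desat_rate = -4.6)
    tr <- simulate_vot_timecourse(phys = phys, fs = fs, noise = FALSE)
    seg <- segment_and_baseline(tr)
    expect_equal(compute_deo2(tr, seg$t_inflation), -4.6,
                 tolerance = 1e-8)
    r <- compute_reo2(tr, seg$t_inflation, seg$t_deflation,
                      seg$recovery_baseline_sto2)
    expect_equal(r$reo2, 1.1, tolerance = 0.05)
  }
})

test_that("AUC handles triangles, zero excursions, and half-sines", {
  t <- 0:600
  # triangular excursion: +10% peak over a 60 s base -> 5 %.min
  tri <- rep(70, 601)
  up <- t >= 100 & t <= 130; dn <- t > 130 & t <= 160
  tri[up] <- 70 + 10 * (t[up] - 100) / 30
  tri[dn] <- 80 - 10 * (t[dn] - 130) / 30
  a <- compute_auc(make_trace(t, tri), 50, 70, "sto2")
  expect_true(a$valid)
  expect_equal(a$auc, 5, tolerance = 1e-10)
  # identically-at-baseline signal has zero area
  a0 <- compute_auc(make_trace(t, rep(70, 601)), 50, 70, "sto2")
  expect_true(a0$valid)
  expect_equal(a0$auc, 0)
  # half-sine amplitude A, duration T -> (2/pi) A T
  hs <- rep(70, 601); idx <- t >= 100 & t <= 160
  hs[idx] <- 70 + 10 * sin(pi * (t[idx] - 100) / 60)
  ah <- compute_auc(make_trace(t, hs), 50, 70, "sto2")
  expect_equal(ah$auc * 60, 2 / pi * 10 * 60, tolerance = 0.01)
  # missing second crossing is excluded
  open_ended <- rep(70, 601); open_ended[t > 100] <- 75
  ao <- compute_auc(make_trace(t, open_ended), 50, 70, "sto2")
  expect_false(ao$valid)
})

test_that("noiseless biomarker extraction closes on the generator", {
  phys <- vot_physiology()
  tr <- simulate_vot_timecourse(phys = phys, noise = FALSE)
  b <- vot_biomarkers(tr)
  expect_equal(b$baseline_sto2, phys$baseline_sto2, tolerance = 0.01)
  expect_equal(b$deo2, phys$desat_rate, tolerance = 0.01)
  expect_equal(b$reo2, phys$reo2_rate, tolerance = 0.01)
  expect_true(b$valid_recovery)
  # AUC against the same excursion sampled 100x finer
  fine <- simulate_vot_timecourse(phys = phys, fs = 100, noise = FALSE)
  seg <- segment_and_baseline(tr)
  af <- compute_auc(fine, seg$t_deflation, seg$recovery_baseline_sto2,
                    "sto2")
  expect_equal(b$auc_sto2, af$auc, tolerance = 0.02)
})

test_that("non-recovering traces are excluded end to end", {
  phys <- vot_physiology()
  tr <- simulate_vot_timecourse(phys = phys, noise = FALSE)
  rec <- tr$t > 360
  tr$sto2[rec] <- pmin(tr$sto2[rec], phys$baseline_sto2 - 5)
  b <- vot_biomarkers(tr)
  expect_false(b$valid_recovery)
  expect_true(is.na(b$reo2))
  expect_true(is.na(b$auc_sto2))
})

test_that("metabolism indices follow the Fick-law arithmetic", {
  m0 <- compute_metabolism(97, 0.49e-8, spo2 = 97, hb_gdl = 10.1,
                           gamma = 1)
  expect_equal(m0$mmro2, 0)
  expect_equal(m0$oef, 0)
  # hand arithmetic with ICU-like group values
  m <- compute_metabolism(67.05, 0.49e-8, spo2 = 97, hb_gdl = 10.1,
                          gamma = 1)
  expect_equal(m$mmro2, 10.1 * (97 - 67.05) / 97 * 0.49e-8,
               tolerance = 1e-12)
  # halving gamma doubles the index exactly
  m2 <- compute_metabolism(67.05, 0.49e-8, 97, 10.1, gamma = 0.5)
  expect_equal(m2$mmro2, 2 * m$mmro2, tolerance = 1e-12)
  expect_warning(compute_metabolism(99, 1e-8, spo2 = 90, hb_gdl = 12),
                 "negative")
})
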