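# IRF metrics, DTOF convolution fitting, chromophore inversion, and
# phantom effective hemoglobin values.

test_that("IRF metrics: symmetry, closed-form FWHM, translation", {
  # symmetric Gaussian centered at 3.9 ns
  irf <- compute_irf_metrics(gaussian_irf(default_spec, center_ns = 3.9,
                                          fwhm_ps = 200, noise = FALSE))
  expect_equal(irf$barycenter, 3.9, tolerance = 1e-3)
  # sigma = 100 ps -> FWHM = 2*sqrt(2 ln 2)*100 = 235.48 ps, within one
  # interpolation step (bin width ~9.2 ps)
  irf2 <- compute_irf_metrics(
    gaussian_irf(default_spec, fwhm_ps = 100 * 2 * sqrt(2 * log(2)),
                 noise = FALSE))
  expect_equal(irf2$fwhm, 235.482, tolerance = 10 / 235)
  # translation equivariance
  irf3 <- compute_irf_metrics(gaussian_irf(default_spec, center_ns = 4.4,
                                           noise = FALSE))
  expect_equal(irf3$barycenter - irf$barycenter, 0.5, tolerance = 1e-3)
  z <- delta_irf(default_spec)
  z$histogram[] <- 0
  expect_error(compute_irf_metrics(z), "all-zero")
})

test_that("noiseless self-generated DTOF is recovered exactly", {
  props <- phantom_preset(685)
  d <- generate_dtof(props, delta_irf(default_spec), default_geom,
                     default_spec, noise = FALSE)
  f <- fit_dtof(d, delta_irf(default_spec), default_geom)
  expect_true(f$diagnostics$converged)
  expect_equal(f$props$mua, props$mua, tolerance = 1e-3)
  expect_equal(f$props$musp, props$musp, tolerance = 1e-3)
})

test_that("fit optimum agrees with a brute-force grid search", {
  set.seed(101)
  for (k in 1:5) {
    props <- optical_properties(runif(1, 0.12, 0.3), runif(1, 6, 14), 685)
    d <- generate_dtof(props, fixture_irf, default_geom, default_spec,
                       total_counts = 1e5, dark_rate = 500,
                       seed = 500 + k)
    f <- fit_dtof(d, fixture_irf, default_geom)
    bg <- list(mean = f$diagnostics$background,
               sd = 0, dynamic_range = f$diagnostics$dynamic_range)
    win <- f$diagnostics$fit_window[1]:f$diagnostics$fit_window[2]
    # 9x9 grid spanning +/-6% around the fitted optimum, one cell = 1.5%
    gmua <- f$props$mua * seq(0.94, 1.06, length.out = 9)
    gmusp <- f$props$musp * seq(0.94, 1.06, length.out = 9)
    obj <- outer(gmua, gmusp, Vectorize(function(a, s)
      dtof_objective(a, s, d, fixture_irf, default_geom, win, bg)))
    best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(best - c(5, 5))), 1)
  }
})

test_that("recovery dispersion shrinks as counts increase", {
  props <- phantom_preset(685)
  sd_at <- function(counts, seeds) {
    mu <- vapply(seeds, function(s) {
      fit_dtof(generate_dtof(props, fixture_irf, default_geom,
                             default_spec, total_counts = counts,
                             dark_rate = 1000, seed = s),
               fixture_irf, default_geom)$props$mua
    }, 0)
    sd(mu)
  }
  s5 <- sd_at(1e5, 1:8); s6 <- sd_at(1e6, 1:8); s7 <- sd_at(1e7, 1:8)
  expect_lt(s6, s5)
  expect_lt(s7, s6)
})

test_that("chromophore inversion matches the hand 2x2 solve", {
  tab <- extinction_table()
  e685 <- tab[tab$wavelength == 685, ]
  e828 <- tab[tab$wavelength == 828, ]
  # pure HbO at 60 uM
  c_hbo <- 60e-6
  mua685 <- log(10) * e685$eps_hbo * c_hbo
  mua828 <- log(10) * e828$eps_hbo * c_hbo
  cs <- compute_chromophores(optical_properties(mua685, 10, 685),
                             optical_properties(mua828, 10, 828))
  expect_equal(cs$sto2, 100, tolerance = 1e-9)
  expect_equal(cs$hbo, 60, tolerance = 1e-9)
  # round trip with both species present
  hbo <- 45e-6; hbr <- 25e-6
  m685 <- log(10) * (e685$eps_hbo * hbo + e685$eps_hbr * hbr)
  m828 <- log(10) * (e828$eps_hbo * hbo + e828$eps_hbr * hbr)
  cs2 <- compute_chromophores(optical_properties(m685, 10, 685),
                              optical_properties(m828, 10, 828))
  expect_equal(cs2$hbo, 45, tolerance = 1e-9)
  expect_equal(cs2$hbr, 25, tolerance = 1e-9)
  # exact linearity: scaling both mua scales concentrations, fixes StO2
  cs3 <- compute_chromophores(optical_properties(2 * m685, 10, 685),
                              optical_properties(2 * m828, 10, 828))
  expect_equal(cs3$thb, 2 * cs2$thb, tolerance = 1e-12)
  expect_equal(cs3$sto2, cs2$sto2, tolerance = 1e-12)
  # impossible spectrum flags negative concentrations
  expect_warning(
    compute_chromophores(optical_properties(1e-4, 10, 685),
                         optical_properties(0.5, 10, 828)),
    "negative")
})

test_that("healthy group-mean absorption yields a plausible tHb", {
  cs <- compute_chromophores(optical_properties(0.22, 8.62, 685),
                             optical_properties(0.23, 8.18, 828),
                             water_fraction = 0.7)
  expect_equal(cs$thb, 112.88, tolerance = 0.15)
  expect_gt(cs$sto2, 60); expect_lt(cs$sto2, 80)
})

test_that("phantom effective values behave over repetition series", {
  p685 <- replicate(5, phantom_preset(685), simplify = FALSE)
  p828 <- replicate(5, phantom_preset(828), simplify = FALSE)
  rec <- compute_phantom_effective(p685, p828)
  expect_equal(rec$cv_thb, 0, tolerance = 1e-12)
  expect_equal(rec$cv_sto2, 0, tolerance = 1e-12)
  # doubling one repetition's 685 nm absorption moves both effective
  # values in the direction of the hand 2x2 solve
  p685b <- p685
  p685b[[3]] <- optical_properties(2 * p685[[3]]$mua, p685[[3]]$musp, 685)
  rec2 <- compute_phantom_effective(p685b, p828)
  hand0 <- compute_chromophores(p685[[3]], p828[[3]])
  hand1 <- compute_chromophores(p685b[[3]], p828[[3]])
  expect_equal(sign(rec2$thb_ph - rec$thb_ph), sign(hand1$thb - hand0$thb))
  expect_equal(sign(rec2$sto2_ph - rec$sto2_ph),
               sign(hand1$sto2 - hand0$sto2))
  expect_error(compute_phantom_effective(p685, p828[1:3]), "mismatch")
  expect_error(compute_phantom_effective(p685[1], p828[1]), "2 repetitions")
})

test_that("simulated phantom repetitions give percent-level intra CV", {
  fits <- lapply(1:20, function(s) {
    list(
      f685 = fit_dtof(generate_dtof(phantom_preset(685), fixture_irf,
                                    default_geom, default_spec, 1e6, 1000,
                                    seed = 700 + s),
                      fixture_irf, default_geom)$props,
      f828 = fit_dtof(generate_dtof(phantom_preset(828), fixture_irf,
                                    default_geom, default_spec, 1e6, 1000,
                                    seed = 900 + s),
                      fixture_irf, default_geom)$props)
  })
  rec <- compute_phantom_effective(lapply(fits, `[[`, "f685"),
                                   lapply(fits, `[[`, "f828"))
  expect_gt(rec$cv_thb, 0.05)
  expect_lt(rec$cv_thb, 5)
  expect_gt(rec$cv_sto2, 0.02)
  expect_lt(rec$cv_sto2, 5)
})
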