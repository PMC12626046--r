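# Precision and agreement analytics.

test_that("cv_series matches hand arithmetic exactly", {
  expect_equal(cv_series(c(5, 5, 5, 5))$cv, 0)
  expect_equal(cv_series(c(2, 4))$cv, 100 * sqrt(2) / 3,
               tolerance = 1e-12)
  vectors <- list(c(1, 2, 3), c(10, 12, 9, 14), c(0.5, 0.7),
                  c(100, 101, 99, 100.5), c(3, 3, 4, 5, 3))
  for (x in vectors) {
    hand <- 100 * sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
    expect_equal(cv_series(x)$cv, hand, tolerance = 1e-12)
  }
  # scale invariance and the undefined-at-zero-mean flag
  expect_equal(cv_series(7 * c(2, 4))$cv, cv_series(c(2, 4))$cv,
               tolerance = 1e-12)
  z <- cv_series(c(-1, 1))
  expect_true(z$undefined)
  expect_true(is.na(z$cv))
})

test_that("test_retest separates intra- and inter-block variability", {
  blocks <- replicate(5, c(70, 70, 70), simplify = FALSE)
  tt <- test_retest(blocks)
  expect_equal(tt$inter$cv, 0)
  means <- c(70, 71, 70.5, 69.5, 70)
  blocks2 <- lapply(means, function(m) rep(m, 3))
  hand <- 100 * sd(means) / mean(means)
  expect_equal(test_retest(blocks2)$inter$cv, hand, tolerance = 1e-12)
  expect_error(test_retest(blocks[1]), "2 blocks")
  expect_error(test_retest(list(c(1, 2), 3)), "2 samples")
})

test_that("simulated repositioning recovers the generating variability", {
  td <- tempfile()
  simulate_session("test_retest", td, seed = 5)
  r <- read_session(td)$channels$retest
  ts <- test_retest(split(r$sto2, r$block))
  tb <- test_retest(split(r$bfi, r$block))
  # generator targets: StO2 inter CV ~1.2%, BFI ~12.6%; n = 5 blocks
  # leaves the CV-of-CV wide, so the bands are correspondingly loose
  expect_gt(ts$inter$cv, 0.3); expect_lt(ts$inter$cv, 3)
  expect_gt(tb$inter$cv, 4); expect_lt(tb$inter$cv, 30)
  expect_lt(ts$intra_max, 1.5)
})

test_that("lop_precision computes per-step CVs and their correlations", {
  proto <- lop_protocol()
  # constant-signal steps give all-zero CVs
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    rbind(data.frame(timestamp = (2 * i - 2) * 60 + 0:59, step = i,
                     fraction = proto$steps[i], phase = "inflation",
                     sto2 = 70, bfi = 1e-8, count_rate = 50,
                     dynamic_range = 1000),
          data.frame(timestamp = (2 * i - 1) * 60 + 0:59, step = i,
                     fraction = proto$steps[i], phase = "deflation",
                     sto2 = 70, bfi = 1e-8, count_rate = 50,
                     dynamic_range = 1000))
  }))
  lp <- lop_precision(rows, proto)
  expect_true(all(lp$per_step$cv_sto2 == 0))
  expect_error(lop_precision(rows[rows$fraction < 1, ], proto), "missing")
})

test_that("noise inversely scaled with light level yields negative rho", {
  td <- tempfile()
  simulate_session("lop", td, seed = 6)
  lp <- lop_precision(read_session(td)$channels$lop)
  rho_cr <- lp$correlations$rho[lp$correlations$x == "cv_bfi" &
                                  lp$correlations$y == "count_rate"]
  expect_lt(rho_cr, 0)
})

test_that("Spearman rho matches the brute-force rank formula", {
  x <- c(3.1, 0.2, 5.5, 2.2, 9.9, 7.3, 1.1, 4.4)
  y <- c(2.0, 1.0, 8.8, 3.3, 7.7, 9.1, 0.5, 6.6)
  d <- rank(x) - rank(y)
  hand <- 1 - 6 * sum(d^2) / (8 * (8^2 - 1))
  expect_equal(unname(cor(x, y, method = "spearman")), hand,
               tolerance = 1e-12)
  lp <- nirsdcs:::spearman_test(x, y)
  expect_equal(lp$rho, hand, tolerance = 1e-12)
})

test_that("bland_altman reports bias, limits, and proportional bias", {
  a <- c(70, 71, 69, 72, 70.5)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$slope, 0)
  # constant offset: bias = mean(a - b) exactly, symmetric limits
  ba <- bland_altman(a + 2, a)
  expect_equal(ba$bias, 2)
  expect_equal(ba$slope, 0)
  expect_equal(ba$loa_high - ba$bias, ba$bias - ba$loa_low,
               tolerance = 1e-12)
  # proportional bias over a wide range is flagged at n = 50
  set.seed(8)
  base <- seq(40, 90, length.out = 50) + rnorm(50, 0, 0.5)
  bp <- bland_altman(1.1 * base, base)
  expect_gt(bp$slope, 0)
  expect_lt(bp$slope_p, 0.05)
  expect_error(bland_altman(1:5, 1:4), "mismatch")
  expect_error(bland_altman(1:2, 1:2), "n >= 3")
})

test_that("resampling holds the nearest preceding sample", {
  t_src <- 0:100
  x <- sin(t_src / 10)
  expect_equal(resample_to_device(t_src, x, t_src), x)
  # 1 Hz to a 5 s grid is plain decimation
  expect_equal(resample_to_device(t_src, x, seq(0, 100, 5)),
               x[seq(1, 101, 5)])
  # a ramp resampled off-grid stays within one source interval
  ramp <- t_src * 2
  tt <- c(10.4, 33.7, 99.9)
  out <- resample_to_device(t_src, ramp, tt)
  expect_true(all(abs(out - 2 * tt) <= 2))
  expect_equal(resample_to_device(t_src, ramp, tt, method = "linear"),
               2 * tt, tolerance = 1e-12)
  expect_error(resample_to_device(t_src, x, 101), "extrapolation")
})

test_that("group_compare picks the right rank test and detects shifts", {
  x <- c(1, 2, 3, 4, 5)
  expect_false(group_compare(x, x)$significant)
  set.seed(10)
  a <- rnorm(20); b <- rnorm(20) + 2
  g <- group_compare(a, b)
  expect_true(g$significant)
  expect_equal(g$method, "mann_whitney_u")
  # invariance under a strictly monotone transform of both groups
  g2 <- group_compare(exp(a), exp(b))
  expect_equal(g$p, g2$p, tolerance = 1e-12)
  gp <- group_compare(a, a + 0.5, paired = TRUE)
  expect_equal(gp$method, "wilcoxon_signed_rank")
  expect_error(group_compare(a, b[1:5], paired = TRUE), "unequal")
})

test_that("impaired-group biomarker sets are detected as lower", {
  set.seed(21)
  healthy <- list(reo2 = rnorm(20, 1.1, 0.3),
                  auc_sto2 = rnorm(20, 7.7, 2.0))
  icu <- list(reo2 = rnorm(20, 0.8, 0.3),
              auc_sto2 = rnorm(20, 3.8, 2.0))
  for (v in names(healthy)) {
    expect_lt(median(icu[[v]]), median(healthy[[v]]))
    expect_true(group_compare(icu[[v]], healthy[[v]])$significant)
  }
})
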