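# g2 block averaging, BFI/beta inversion, and baseline quality.

test_that("block averaging is the windowed unweighted mean", {
  base <- generate_g2(p785_healthy, 1e-8, noise = FALSE)
  # 38 identical curves within one second collapse to themselves
  curves <- lapply(seq(0, 0.974, by = 0.026), function(ts) {
    c2 <- base; c2$timestamp <- ts; c2
  })
  out <- block_average_g2(curves, 1)
  expect_length(out, 1)
  expect_equal(out[[1]]$g2, base$g2, tolerance = 1e-12)
  # alternating plateaus average arithmetically
  hi <- base; hi$g2 <- rep(1.6, length(base$lag))
  lo <- base; lo$g2 <- rep(1.4, length(base$lag))
  alt <- lapply(0:9, function(i) {
    c2 <- if (i %% 2 == 0) hi else lo
    c2$timestamp <- i * 0.026
    c2
  })
  expect_equal(block_average_g2(alt, 1)[[1]]$g2,
               rep(1.5, length(base$lag)), tolerance = 1e-12)
})

test_that("26 ms cadence block-averaged to 1 Hz gives one curve per second", {
  curves <- lapply(seq(0, 9.984, by = 0.026), function(ts)
    generate_g2(p785_healthy, 1e-8, avg_time = 0.026, timestamp = ts,
                noise = FALSE))
  out <- block_average_g2(curves, 1)
  expect_length(out, 10)
  expect_equal(vapply(out, `[[`, 0, "timestamp"), 0:9)
})

test_that("block averaging conserves the per-lag mean and rejects bad grids", {
  set.seed(20)
  curves <- lapply(0:25, function(i)
    generate_g2(p785_healthy, 1e-8, avg_time = 0.026, timestamp = i * 0.2,
                count_rate = 50, seed = 2000 + i))
  out <- block_average_g2(curves, 1)
  m_in <- rowMeans(vapply(curves, `[[`, numeric(64), "g2"))
  n_per <- table(floor(vapply(curves, `[[`, 0, "timestamp")))
  m_out <- as.numeric(
    vapply(out, `[[`, numeric(64), "g2") %*% as.numeric(n_per) /
      sum(n_per))
  expect_equal(m_out, m_in, tolerance = 1e-12)
  bad <- curves[[1]]
  bad$lag <- bad$lag * 1.01
  expect_error(block_average_g2(c(curves[2:4], list(bad)), 1), "lag grid")
})

test_that("noiseless Siegert plateau 1.5 fits to beta = 0.5", {
  g <- generate_g2(p785_healthy, 1e-8, beta = 0.5, noise = FALSE)
  f <- fit_g2(g, p785_healthy)
  expect_true(f$converged)
  expect_equal(f$beta, 0.5, tolerance = 1e-4)
  expect_equal(f$bfi, 1e-8, tolerance = 1e-4)
})

test_that("recovered BFI is strictly monotone in the generating BFI", {
  bfis <- c(0.3, 0.6, 1, 2, 4) * 1e-8
  rec <- vapply(bfis, function(b)
    fit_g2(generate_g2(p785_healthy, b, noise = FALSE), p785_healthy)$bfi, 0)
  expect_equal(cor(rec, bfis, method = "spearman"), 1, tolerance = 1e-12)
  expect_true(all(diff(rec) > 0))
})

test_that("noisy BFI recovery lands within 10% on average", {
  rec <- vapply(1:20, function(i)
    fit_g2(generate_g2(p785_healthy, 1e-8, count_rate = 50, avg_time = 1,
                       seed = 3000 + i), p785_healthy)$bfi, 0)
  expect_equal(mean(rec), 1e-8, tolerance = 0.1)
})

test_that("fitting with mismatched absorption biases the BFI consistently", {
  # curve generated with mua 20% higher than assumed in the fit
  p_hi <- optical_properties(p785_healthy$mua * 1.2, p785_healthy$musp, 785)
  bias <- vapply(c(1e-8, 2e-8), function(b) {
    f <- fit_g2(generate_g2(p_hi, b, noise = FALSE), p785_healthy)
    f$bfi / b - 1
  }, 0)
  expect_true(all(abs(bias) > 0.02))
  expect_equal(sign(bias[1]), sign(bias[2]))
})

test_that("flat curves flag non-convergence instead of raising", {
  flat <- generate_g2(p785_healthy, 1e-8, noise = FALSE)
  flat$g2 <- rep(1, length(flat$lag))
  f <- fit_g2(flat, p785_healthy)
  expect_false(f$converged)
})

test_that("dcs_quality summarises the baseline and raises drop flags", {
  base <- lapply(seq(0, 59.974, by = 0.026), function(ts)
    generate_g2(p785_healthy, 1e-8, beta = 0.49, count_rate = 50,
                avg_time = 0.026, timestamp = ts, noise = FALSE))
  q <- dcs_quality(base, p785_healthy)
  expect_equal(q$beta_median, 0.49, tolerance = 1e-3)
  expect_lt(q$beta_sd, 1e-2)
  expect_length(q$flags, 0)
  # one 10 s block collapsing to beta 0.1 raises the drop flag
  dropped <- lapply(base, function(c2) {
    if (c2$timestamp >= 30 & c2$timestamp < 40) {
      c2$g2 <- 1 + 0.1 * (c2$g2 - 1) / 0.49
    }
    c2
  })
  qd <- dcs_quality(dropped, p785_healthy)
  expect_true("beta_drop" %in% qd$flags)
  expect_error(dcs_quality(base, p785_healthy, baseline_window_s = 5),
               "shorter")
})

test_that("noisy baseline beta statistics close on the generating value", {
  base <- lapply(seq(0, 59.974, by = 0.026), function(ts)
    generate_g2(p785_healthy, 1e-8, beta = 0.5, count_rate = 50,
                avg_time = 0.026, timestamp = ts,
                seed = split_seed(31, round(ts * 1000))))
  q <- dcs_quality(base, p785_healthy)
  expect_lt(abs(q$beta_median - 0.5), 0.02)
})
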