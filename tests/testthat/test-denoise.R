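test_that("wavelet decomposition reconstructs perfectly and conserves energy", {
  set.seed(11)
  for (w in c("haar", "db2", "db4", "sym4")) {
    for (n in c(64, 1000, 1001)) {        # even, even, odd lengths
      x <- stats::rnorm(n)
      wc <- wavelet_decompose(x, wavelet = w, J = 3)
      expect_length(wc$details, 3)
      err <- max(abs(wavelet_reconstruct(wc) - x)) / max(abs(x))
      expect_lt(err, 1e-8)
    }
  }
  # orthonormal filters: sum h = sqrt(2), energy preserved (even length)
  x <- stats::rnorm(512)
  wc <- wavelet_decompose(x, "db4", 3)
  expect_equal(sum(wc$approx^2) + sum(unlist(wc$details)^2), sum(x^2),
               tolerance = 1e-12)
  expect_true(all(wavelet_decompose(numeric(64), "db4", 3)$approx == 0))
  expect_error(wavelet_decompose(stats::rnorm(4), "db4", 3),
               class = "fatigueEEG_parameter_error")
})

test_that("hard and soft thresholds match their closed forms", {
  expect_equal(hard_threshold(c(5, 1, -4), 3), c(5, 0, -4))
  expect_equal(hard_threshold(c(5, 1, -4), 0), c(5, 1, -4))
  expect_equal(soft_threshold(c(5, -5, 2, -2), 3), c(2, -2, 0, 0))
  set.seed(3)
  d <- stats::rnorm(500, 0, 2)
  lam <- 3 * 2
  expect_equal(hard_threshold(d, lam), ifelse(abs(d) >= lam, d, 0))
  expect_equal(soft_threshold(d, lam),
               ifelse(abs(d) >= lam, sign(d) * (abs(d) - lam), 0))
  # soft rule is continuous across the knot
  eps <- seq(-1e-6, 1e-6, length.out = 21)
  expect_lt(max(abs(diff(soft_threshold(lam + eps, lam)))), 1e-5)
  expect_error(hard_threshold(d, -1), class = "fatigueEEG_parameter_error")
})

test_that("improved soft threshold follows its piecewise definition", {
  expect_equal(improved_soft_threshold(5, 3, 0.01), 0.01 * 9 - 3 + 5)  # 2.09
  expect_equal(improved_soft_threshold(2, 3, 0.01), 0.01 * 4)          # 0.04
  expect_equal(improved_soft_threshold(-5, 3, 0.01), -0.01 * 9 + 3 - 5)
  expect_equal(improved_soft_threshold(-2, 3, 0.01), -0.01 * 4)
  expect_equal(improved_soft_threshold(0, 3, 0.01), 0)
  set.seed(4)
  d <- stats::rnorm(300, 0, 4)
  expect_identical(improved_soft_threshold(d, 3, 0), soft_threshold(d, 3))
  expect_error(improved_soft_threshold(d, 3, 0.5),
               regexp = "side condition",
               class = "fatigueEEG_parameter_error")
})

test_that("improved rule is continuous at the knots and dominates soft", {
  lam <- 2.5
  for (a in c(0, 0.05, 0.2, 0.399)) {       # a < 1/lambda = 0.4
    for (knot in c(lam, -lam)) {
      grid <- knot + seq(-1e-7, 1e-7, length.out = 41)
      vals <- improved_soft_threshold(grid, lam, a)
      expect_lt(max(abs(diff(vals))), 1e-6)
    }
    d <- seq(-8, 8, by = 0.01)
    expect_true(all(abs(improved_soft_threshold(d, lam, a)) >=
                      abs(soft_threshold(d, lam)) - 1e-12))
  }
  # approaches pass-through (hard-like) just above the knot as a -> 1/lambda
  near <- improved_soft_threshold(lam + 1e-9, lam, 1 / lam - 1e-9)
  expect_equal(near, lam, tolerance = 1e-6)
})

test_that("level threshold follows its closed form and monotonicities", {
  expect_equal(level_threshold(0, 1, 100), 0)
  expect_equal(level_threshold(1, 1, exp(2)), 2 / log(2))
  l <- vapply(1:3, function(j) level_threshold(1.5, j, 512), 0)
  expect_true(all(diff(l) < 0))                     # decreasing in level
  expect_gt(level_threshold(2, 1, 512), level_threshold(1, 1, 512))
  expect_gt(level_threshold(1, 1, 1024), level_threshold(1, 1, 512))
  expect_error(level_threshold(1, 1, 1), class = "fatigueEEG_parameter_error")
})

test_that("noise scale estimation tracks white-noise level", {
  expect_equal(estimate_sigma(rep(0.6745, 10)), 1)
  expect_equal(estimate_sigma(numeric(5)), 0)
  expect_error(estimate_sigma(numeric(0)), class = "fatigueEEG_parameter_error")
  # Monte-Carlo: level-1 details of pure white noise, against the scaled
  # mean-absolute-deviation oracle E|N(0,s)| / 0.6745 = 0.7979 s / 0.6745
  set.seed(5)
  sig <- 2
  est <- replicate(100, {
    wc <- wavelet_decompose(stats::rnorm(2048, 0, sig), "db4", 3)
    estimate_sigma(wc$details[[1]])
  })
  oracle <- sqrt(2 / pi) * sig / 0.6745
  expect_lt(abs(mean(est) - oracle) / oracle, 0.1)
  # robust variant close to sigma itself
  est_med <- replicate(50, {
    wc <- wavelet_decompose(stats::rnorm(2048, 0, sig), "db4", 3)
    estimate_sigma(wc$details[[1]], "median_abs")
  })
  expect_equal(mean(est_med), sig, tolerance = 0.1)
})

test_that("denoising pipeline identities hold", {
  set.seed(6)
  t <- (0:1999) / 200
  smooth <- 10 * sin(2 * pi * 3 * t) + 4 * sin(2 * pi * 7 * t)
  # zero threshold => identity
  out0 <- denoise_signal(smooth, threshold_params(method = "hard", sigma = 0))
  expect_lt(max(abs(out0$signal - smooth)) / max(abs(smooth)), 1e-8)
  # noiseless smooth input is nearly untouched by every rule
  for (m in c("hard", "soft", "improved")) {
    out <- denoise_signal(smooth, threshold_params(method = m), reference = smooth)
    expect_lt(out$report$rmse / sqrt(mean(smooth^2)), 0.02)
  }
  # improved with a = 0 equals the soft pipeline bit-for-bit
  noisy <- smooth + stats::rnorm(2000, 0, 3)
  s_out <- denoise_signal(noisy, threshold_params(method = "soft"))
  i_out <- denoise_signal(noisy, threshold_params(method = "improved", a = 0))
  expect_identical(s_out$signal, i_out$signal)
  # report carries one lambda per level; level mode differs from global
  lv <- denoise_signal(noisy, threshold_params(lambda_mode = "level_dependent"))
  expect_length(lv$report$lambda, 3)
  expect_false(all(lv$report$lambda == lv$report$lambda[1]))
})

test_that("SNR and RMSE follow their formulas", {
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(snr(c(3, 4), c(0, 0)), 0)
  x <- stats::rnorm(100)
  expect_equal(rmse(x, x), 0)
  expect_equal(snr(x, x), Inf)
  set.seed(7)
  e <- stats::rnorm(100)
  expect_equal(snr(x, x + e) - snr(x, x + 2 * e), 20 * log10(2),
               tolerance = 1e-12)
  expect_error(snr(1:3, 1:4), class = "fatigueEEG_parameter_error")
  expect_error(rmse(numeric(0), numeric(0)), class = "fatigueEEG_parameter_error")
})
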