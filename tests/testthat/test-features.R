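test_that("Hann window endpoints, midpoint and sin^2 identity", {
  w <- hann_window(101)
  expect_equal(w[1], 0)
  expect_equal(w[101], 0)
  expect_equal(w[51], 1)
  n <- 0:100
  expect_lt(max(abs(w - sin(pi * n / 100)^2)), 1e-12)
  expect_error(hann_window(1), class = "fatigueEEG_parameter_error")
})

test_that("STFT matches a direct-summation DFT oracle", {
  set.seed(13)
  x <- stats::rnorm(64)
  N <- 16; hop <- 8
  spec <- stft(x, N = N, hop = hop, rate = 64)
  w <- 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1)))
  n_frames <- floor((64 - N) / hop) + 1
  expect_equal(nrow(spec$values), n_frames)
  for (m in seq_len(n_frames)) for (k in 0:(N - 1)) {
    direct <- sum(x[((m - 1) * hop + 1):((m - 1) * hop + N)] * w *
                    exp(-1i * 2 * pi * k * (0:(N - 1)) / N))
    expect_lt(Mod(spec$values[m, k + 1] - direct), 1e-9)
  }
})

test_that("STFT localizes tones and maps zero to zero", {
  rate <- 200; N <- 200
  x <- sin(2 * pi * 10 * (0:1999) / rate)     # bin k0 = 10 at N = rate
  spec <- stft(x, N = N, hop = 100, rate = rate)
  half <- 2:(N / 2)                            # skip DC, one-sided
  for (m in seq_len(nrow(spec$values)))
    expect_equal(which.max(Mod(spec$values[m, half])) + 1, 11)  # k = 10
  expect_true(all(Mod(stft(numeric(300), N = 200, rate = 200)$values) == 0))
  expect_error(stft(numeric(100), N = 200), class = "fatigueEEG_parameter_error")
})

test_that("PSD is non-negative, frame-averaged, and Parseval-consistent", {
  set.seed(14)
  x <- stats::rnorm(64)
  # one rectangular-window frame, assembled directly
  spec <- structure(list(values = t(stats::mvfft(matrix(x, ncol = 1))),
                         rate = 64, N = 64, hop = 64),
                    class = "spectrogram")
  p <- psd(spec)
  expect_true(all(p$energy >= 0))
  expect_equal(sum(p$energy) / p$N, sum(x^2), tolerance = 1e-10)
  # doubling amplitude quadruples the PSD
  spec2 <- structure(list(values = t(stats::mvfft(matrix(2 * x, ncol = 1))),
                          rate = 64, N = 64, hop = 64),
                     class = "spectrogram")
  expect_equal(psd(spec2)$psd, 4 * p$psd, tolerance = 1e-10)
})

test_that("band energies partition the spectrum and find the active band", {
  rate <- 200
  x <- sin(2 * pi * 10 * (0:1999) / rate)
  p <- psd(stft(x, N = 200, hop = 100, rate = rate))
  full <- band_energy(p, c(0, rate / 2))
  parts <- band_energy(p, c(0, 8)) + band_energy(p, c(8, 30)) +
    band_energy(p, c(30, rate / 2))
  expect_equal(parts, full, tolerance = 1e-12)
  alpha <- band_energy(p, c(8, 13))
  for (b in list(c(0.5, 4), c(4, 8), c(13, 30), c(30, 50)))
    expect_gt(alpha, 100 * band_energy(p, b))
  expect_warning(e0 <- band_energy(p, c(0.2, 0.4)), "no DFT bin")
  expect_equal(e0, 0)
  expect_error(band_energy(p, c(30, 20)), class = "fatigueEEG_parameter_error")
})

test_that("band-power features have the contracted geometry and names", {
  set.seed(15)
  ep <- eeg_epoch(matrix(stats::rnorm(32 * 400), nrow = 32,
                         dimnames = list(channel_names_1020(32), NULL)),
                  200, 2, "S1", "normal", 1)
  fv <- psd_features(ep)
  expect_length(fv, 160)                       # 32 channels x 5 bands
  expect_identical(names(fv)[1:5],
                   paste0("Fp1:", names(eeg_bands())))
  expect_true(all(is.finite(fv)))
})

test_that("slow-wave features separate the synthetic states", {
  fm <- tiny_features_psd()
  theta_cols <- grep(":theta$", fm$feature_names)
  theta <- rowMeans(fm$values[, theta_cols, drop = FALSE])
  expect_gt(mean(theta[fm$labels == "fatigue"]),
            mean(theta[fm$labels == "normal"]))
})

test_that("energy spectral density obeys Parseval and shift invariance", {
  expect_equal(esd(numeric(32))$total, 0)
  set.seed(16)
  x <- stats::rnorm(128)
  expect_equal(esd(x)$total, 128 * sum(x^2) / (2 * pi), tolerance = 1e-10)
  shifted <- c(x[33:128], x[1:32])
  expect_lt(max(abs(esd(shifted)$esd - esd(x)$esd)), 1e-9)
})

test_that("EMD energy features: geometry, zeros, and scale equivariance", {
  set.seed(17)
  ep <- eeg_epoch(matrix(stats::rnorm(2 * 512), nrow = 2,
                         dimnames = list(c("Fp1", "Fp2"), NULL)),
                  256, 2, "S1", "normal", 1)
  fv <- emd_esd_features(ep, n_imfs = 3)
  expect_length(fv, 6)
  expect_identical(names(fv)[1:3], sprintf("Fp1:imf%d_energy", 1:3))

  ep0 <- eeg_epoch(matrix(0, 2, 512), 256, 2, "S1", "normal", 1)
  expect_true(all(emd_esd_features(ep0, n_imfs = 3) == 0))

  ep2 <- ep; ep2$data <- 2 * ep$data
  expect_equal(emd_esd_features(ep2, n_imfs = 3), 4 * fv, tolerance = 1e-9)
})

test_that("IMF energies of separable tones stay near the signal energy", {
  rate <- 200
  t <- (0:(4 * rate - 1)) / rate
  x <- sin(2 * pi * 20 * t) + sin(2 * pi * 2 * t)
  ep <- eeg_epoch(matrix(x, nrow = 1, dimnames = list("Cz", NULL)),
                  rate, 4, "S1", "normal", 1)
  fv <- emd_esd_features(ep, n_imfs = 3)
  total <- length(x) * sum(x^2) / (2 * pi)     # Parseval bound
  expect_lte(sum(fv), 1.1 * total)
  expect_gt(sum(fv), 0.8 * total)              # tones live in the IMFs
})

test_that("feature matrices carry aligned metadata and reject bad shapes", {
  fm <- tiny_features_psd()
  expect_equal(ncol(fm$values), 4 * 5)
  expect_equal(nrow(fm$values), length(fm$labels))
  expect_error(feature_matrix(matrix(0, 2, 2), "one", c("a", "b"), c("s", "s")),
               class = "fatigueEEG_parameter_error")
  expect_error(feature_matrix(matrix(c(0, Inf, 0, 0), 2), c("a", "b"),
                              c("x", "y"), c("s", "s")),
               class = "fatigueEEG_data_error")
})

test_that("feature extraction is deterministic", {
  es <- tiny_epochs()
  sub <- eeg_epoch_set(es$epochs[1:2])
  expect_identical(extract_features(sub, "psd")$values,
                   extract_features(sub, "psd")$values)
  expect_identical(extract_features(sub, "emd")$values,
                   extract_features(sub, "emd")$values)
})

test_that("third-order cumulant: hand value, symmetry, Gaussian decay", {
  ce <- third_order_cumulant(c(1, 2, 3), M = 3, p_lags = 1)
  expect_equal(ce$r["0", "0"], 12)
  set.seed(18)
  x <- stats::rnorm(512)
  ce2 <- third_order_cumulant(x, M = 64, p_lags = 3)
  expect_lt(max(abs(ce2$r - t(ce2$r))), 1e-10)
  expect_error(third_order_cumulant(1:10, M = 3, p_lags = 1),
               class = "fatigueEEG_parameter_error")
  # averaging segments shrinks the (vanishing) Gaussian third cumulant
  wins <- 0
  for (s in 1:100) {
    set.seed(500 + s)
    xs <- stats::rnorm(6400)
    r1 <- third_order_cumulant(xs[1:64], M = 64, p_lags = 1)$r["0", "0"]
    rK <- third_order_cumulant(xs, M = 64, p_lags = 1)$r["0", "0"]
    wins <- wins + (abs(rK) < abs(r1))
  }
  expect_gte(wins, 90)
})

test_that("AR bispectrum: order-0 constant, argument symmetry, conventions", {
  set.seed(19)
  x <- stats::rnorm(1024)^3                    # skewed, non-Gaussian
  ce <- third_order_cumulant(x, M = 128, p_lags = 4)
  grid <- seq(-pi, pi, length.out = 9)
  b0 <- ar_bispectrum(ce, p = 0, grid = grid)
  expect_length(b0$a, 0)
  expect_true(all(b0$B == ce$r["0", "0"]))

  b2 <- ar_bispectrum(ce, p = 2, grid = grid)
  expect_lt(max(Mod(b2$B - t(b2$B))), 1e-10)   # B(w1,w2) = B(w2,w1)
  b2s <- ar_bispectrum(ce, p = 2, grid = grid, convention = "standard")
  expect_gt(max(Mod(b2$B - b2s$B)), 0)         # conventions differ
  expect_error(ar_bispectrum(ce, p = 9), class = "fatigueEEG_parameter_error")
})
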