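# Shared fixtures, memoized so expensive synthetic data is built once per
# test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# Small 4-subject dataset at analysis rate; enough epochs for LOSO.
tiny_dataset <- function() fixture("tiny_dataset", function() {
  generate_dataset(sim_config(n_subjects = 4, minutes_per_state = 1,
                              rate = 200, n_channels = 4, seed = 101))
})

# Epoch set from the tiny dataset (no resampling needed; band-limited).
tiny_epochs <- function() fixture("tiny_epochs", function() {
  preprocess_dataset(tiny_dataset(), target_rate = 200, band = c(0.1, 50),
                     epoch_s = 10)
})

# Full-size session design at the analysis rate (2 channels: epoch counts
# and split geometry do not depend on channel count).
full_size_epochs <- function() fixture("epochs_1440", function() {
  recs <- generate_dataset(sim_config(n_subjects = 6, minutes_per_state = 20,
                                      rate = 200, n_channels = 2, seed = 32))
  preprocess_dataset(recs, target_rate = 200, band = NULL, epoch_s = 10)
})

tiny_features_psd <- function() fixture("tiny_features_psd", function() {
  extract_features(tiny_epochs(), "psd")
})

tiny_features_emd <- function() fixture("tiny_features_emd", function() {
  extract_features(tiny_epochs(), "emd", n_imfs = 3)
})

# Two separable Gaussian blobs in 2-D: the classic separability fixture.
blob_data <- function(n_per = 50, gap = 4, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n_per, 0, 1), ncol = 2),
             matrix(stats::rnorm(2 * n_per, gap, 1), ncol = 2))
  list(x = x, y = rep(c("normal", "fatigue"), each = n_per))
}

# Periodogram-based relative band power, independent of the package's
# STFT/PSD code path: raw squared DFT magnitudes.
oracle_band_fraction <- function(x, rate, lo, hi) {
  P <- Mod(stats::fft(x))^2
  n <- length(x)
  f <- (seq_len(n) - 1) * rate / n
  half <- seq_len(floor(n / 2) + 1)
  sum(P[half][f[half] >= lo & f[half] < hi]) / sum(P[half])
}

# Least-squares sinusoid amplitude at a known frequency.
oracle_sine_amplitude <- function(x, rate, freq) {
  t <- (seq_along(x) - 1) / rate
  fit <- stats::lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t) - 1)
  sqrt(sum(stats::coef(fit)^2))
}

zero_crossings <- function(x) sum(diff(sign(x[x != 0])) != 0)
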