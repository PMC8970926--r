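#' Canonical EEG frequency bands
#'
#' Band edges in Hz: delta 0.5--4, theta 4--8, alpha 8--13, beta 13--30,
#' gamma 30--50. Bands are half-open `[lo, hi)` throughout the package.
#'
#' @return Named list of `c(lo, hi)` numeric pairs.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 50))
}

#' Default per-state band amplitudes
#'
#' RMS amplitude (microvolt) of each band-limited component for the two
#' vigilance states. Fatigue raises theta/delta; wakefulness shows the
#' stronger alpha/beta rhythm. These are free simulator parameters, not
#' estimates of any particular recording.
#'
#' @return List with elements `normal` and `fatigue`, each a named numeric
#'   vector over the bands of [eeg_bands()].
#' @export
default_band_powers <- function() {
  list(normal  = c(delta = 4, theta = 4,  alpha = 10, beta = 6, gamma = 2),
       fatigue = c(delta = 8, theta = 10, alpha = 5,  beta = 3, gamma = 2))
}

# 32-channel actiCAP-style 10-20 montage.
CHANNELS_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1", "FC2",
  "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2",
  "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")

#' Channel labels for the 10--20 montage
#'
#' First `n` labels of the 32-channel cap layout; positions beyond 32 get
#' generic `ChNN` names.
#'
#' @param n Number of channels.
#' @return Character vector of length `n`.
#' @export
channel_names_1020 <- function(n) {
  if (n <= length(CHANNELS_1020)) return(CHANNELS_1020[seq_len(n)])
  c(CHANNELS_1020, sprintf("Ch%02d", seq_len(n - length(CHANNELS_1020))))
}

#' Simulation configuration for synthetic EEG
#'
#' Bundles every knob of the synthetic-EEG generator: session design
#' (subjects, minutes per state, sampling rate, channel count), per-state
#' band amplitudes, broadband noise, mains interference, ocular-like
#' artifact transients, inter-subject gain variability, and the seed.
#'
#' @param n_subjects Number of subjects (each contributes one recording per
#'   state).
#' @param minutes_per_state Minutes of signal per state per subject.
#' @param rate Sampling rate in Hz; must exceed twice the highest band edge.
#' @param n_channels Number of channels (10--20 labels for the first 32).
#' @param band_powers List with `normal`/`fatigue` named amplitude vectors
#'   (microvolt RMS per band); fatigue must have strictly larger theta and
#'   delta than normal, and normal strictly larger alpha and beta.
#' @param noise_sd Standard deviation of additive broadband Gaussian noise
#'   (microvolt).
#' @param line_freq Mains interference frequency in Hz.
#' @param line_amp Mains interference peak amplitude (microvolt).
#' @param artifact_rate Expected low-frequency artifact transients per
#'   minute (Poisson arrivals).
#' @param artifact_amp Artifact peak amplitude as a multiple of the
#'   background (band + noise) standard deviation.
#' @param subject_gain_sd Standard deviation of the per-subject log-normal
#'   gain applied to every band amplitude.
#' @param seed Integer seed; all randomness derives deterministically from
#'   it (and from subject id / state).
#' @param bands Band definition list as from [eeg_bands()].
#'
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_subjects = 6, minutes_per_state = 20, rate = 1000,
                       n_channels = 32, band_powers = default_band_powers(),
                       noise_sd = 3, line_freq = 50, line_amp = 2,
                       artifact_rate = 4, artifact_amp = 5,
                       subject_gain_sd = 0.2, seed = 1,
                       bands = eeg_bands()) {
  cfg <- structure(
    list(n_subjects = n_subjects, minutes_per_state = minutes_per_state,
         rate = rate, n_channels = n_channels, band_powers = band_powers,
         noise_sd = noise_sd, line_freq = line_freq, line_amp = line_amp,
         artifact_rate = artifact_rate, artifact_amp = artifact_amp,
         subject_gain_sd = subject_gain_sd, seed = seed, bands = bands),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_subjects)) stop_config("n_subjects must be a non-negative integer")
  if (!is_scalar_num(cfg$minutes_per_state) || cfg$minutes_per_state <= 0)
    stop_config("minutes_per_state must be positive")
  if (!is_count(cfg$n_channels) || cfg$n_channels < 1)
    stop_config("n_channels must be a positive integer")
  nums <- c(cfg$noise_sd, cfg$line_freq, cfg$line_amp, cfg$artifact_rate,
            cfg$artifact_amp, cfg$subject_gain_sd)
  if (!all(vapply(nums, is_scalar_num, TRUE)) || any(nums < 0))
    stop_config("amplitudes and rates must be non-negative numbers")
  top <- max(vapply(cfg$bands, max, 0))
  if (!is_scalar_num(cfg$rate) || cfg$rate <= 2 * top)
    stop_config(sprintf("rate must exceed twice the highest band edge (%g Hz)", top))
  bp <- cfg$band_powers
  if (!all(c("normal", "fatigue") %in% names(bp)))
    stop_config("band_powers needs 'normal' and 'fatigue' entries")
  need <- names(cfg$bands)
  for (st in c("normal", "fatigue")) {
    if (!all(need %in% names(bp[[st]])))
      stop_config(sprintf("band_powers$%s must name every band", st))
    if (any(bp[[st]] < 0)) stop_config("band amplitudes must be >= 0")
  }
  if (!(bp$fatigue["theta"] > bp$normal["theta"] &&
        bp$fatigue["delta"] > bp$normal["delta"]))
    stop_config("fatigue theta and delta amplitudes must exceed normal's")
  if (!(bp$normal["alpha"] > bp$fatigue["alpha"] &&
        bp$normal["beta"] > bp$fatigue["beta"]))
    stop_config("normal alpha and beta amplitudes must exceed fatigue's")
  invisible(cfg)
}

#' Construct an EEG recording object
#'
#' @param data Channels x samples numeric matrix (microvolt).
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector, one name per matrix row.
#' @param subject_id Subject identifier.
#' @param state `"normal"` or `"fatigue"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, channel_names, subject_id, state) {
  rec <- structure(list(data = data, rate = rate,
                        channel_names = channel_names,
                        subject_id = as.character(subject_id),
                        state = state),
                   class = "eeg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  if (!is.matrix(rec$data) || !is.numeric(rec$data))
    stop_data("recording data must be a numeric matrix")
  if (nrow(rec$data) != length(rec$channel_names))
    stop_data("data must have exactly one row per channel name")
  if (!is_scalar_num(rec$rate) || rec$rate <= 0)
    stop_data("rate must be a positive number")
  if (!all(is.finite(rec$data))) stop_data("recording contains non-finite samples")
  if (!rec$state %in% c("normal", "fatigue"))
    stop_data("state must be 'normal' or 'fatigue'")
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, state %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$state, nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate))
  invisible(x)
}

# Band-limited Gaussian noise via FFT-domain brick-wall shaping, scaled to a
# target RMS. Robust at very low normalized band edges where IIR designs are
# fragile.
band_limited_noise <- function(n, rate, lo, hi, rms) {
  if (rms == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- (seq_len(n) - 1) * rate / n
  fmod <- pmin(f, rate - f)            # mirror frequency of each bin
  keep <- fmod >= lo & fmod < hi
  x <- Re(stats::fft(W * keep, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * rms / s
}

#' Generate one synthetic EEG recording
#'
#' The signal is a sum over bands of band-limited Gaussian oscillations
#' (independent per channel, per-subject log-normal amplitude gain), plus
#' broadband Gaussian noise, a mains sinusoid, and Poisson-arriving
#' low-frequency (1--3 Hz) damped-sinusoid artifact transients at
#' `artifact_amp` times the background standard deviation. Identical
#' `(cfg, subject_id, state)` calls are bit-identical.
#'
#' @param cfg A [sim_config()].
#' @param subject_id Subject identifier (any scalar; coerced to character).
#' @param state `"normal"` or `"fatigue"`.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(cfg, subject_id, state = c("normal", "fatigue")) {
  validate_sim_config(cfg)
  state <- match.arg(state)
  n <- round(cfg$minutes_per_state * 60 * cfg$rate)
  nch <- cfg$n_channels
  amps <- cfg$band_powers[[state]][names(cfg$bands)]

  # Per-subject gains depend on (seed, subject) only, so both states of one
  # subject share them.
  set.seed(derive_seed(cfg$seed, "subject-gain", subject_id))
  gains <- exp(stats::rnorm(length(cfg$bands), 0, cfg$subject_gain_sd))
  names(gains) <- names(cfg$bands)

  set.seed(derive_seed(cfg$seed, "recording", subject_id, state))
  data <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    x <- numeric(n)
    for (b in names(cfg$bands)) {
      bd <- cfg$bands[[b]]
      x <- x + band_limited_noise(n, cfg$rate, bd[1], bd[2], amps[b] * gains[b])
    }
    data[ch, ] <- x
  }

  tt <- (seq_len(n) - 1) / cfg$rate
  if (cfg$line_amp > 0) {
    phases <- stats::runif(nch, 0, 2 * pi)
    for (ch in seq_len(nch))
      data[ch, ] <- data[ch, ] + cfg$line_amp * sin(2 * pi * cfg$line_freq * tt + phases[ch])
  }
  if (cfg$noise_sd > 0)
    data <- data + matrix(stats::rnorm(nch * n, 0, cfg$noise_sd), nrow = nch)

  if (cfg$artifact_rate > 0) {
    background_sd <- sqrt(sum((amps * gains)^2) + cfg$noise_sd^2)
    n_events <- stats::rpois(1, cfg$minutes_per_state * cfg$artifact_rate)
    for (ev in seq_len(n_events)) {
      f <- stats::runif(1, 1, 3)
      tau <- stats::runif(1, 0.2, 0.5)
      len <- min(ceiling(4 * tau * cfg$rate), n)
      start <- sample.int(max(1, n - len + 1), 1)
      te <- (seq_len(len) - 1) / cfg$rate
      pulse <- exp(-te / tau) * sin(2 * pi * f * te)
      wch <- stats::runif(nch, 0.3, 1)
      idx <- start:(start + len - 1)
      data[, idx] <- data[, idx] +
        (cfg$artifact_amp * background_sd) * (wch %o% pulse)
    }
  }

  eeg_recording(data, cfg$rate, channel_names_1020(nch), subject_id, state)
}

#' Generate a full synthetic dataset
#'
#' One recording per subject per state (`n_subjects x 2` recordings),
#' deterministic under the config seed. Subjects are labelled
#' `"S1" ... "Sn"`.
#'
#' @param cfg A [sim_config()].
#' @return List of [eeg_recording()] objects (possibly empty).
#' @export
generate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  recs <- list()
  for (s in seq_len(cfg$n_subjects)) {
    id <- sprintf("S%d", s)
    for (st in c("normal", "fatigue"))
      recs[[length(recs) + 1]] <- generate_recording(cfg, id, st)
  }
  recs
}
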