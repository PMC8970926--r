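#' Hann window
#'
#' `w[n] = 0.5 (1 - cos(2 pi n / (N - 1))) = sin^2(pi n / (N - 1))`,
#' `n = 0 .. N-1`; endpoints are zero.
#'
#' @param N Window length, >= 2.
#' @return Numeric vector of length `N`.
#' @export
hann_window <- function(N) {
  if (!is_count(N) || N < 2) stop_param("N must be an integer >= 2")
  n <- 0:(N - 1)
  0.5 * (1 - cos(2 * pi * n / (N - 1)))
}

#' Short-time Fourier transform
#'
#' Frame `m` covers samples `[m hop, m hop + N)` (0-based); each frame is
#' Hann-windowed then transformed with a full `N`-bin DFT, giving angular
#' frequencies `w_k = 2 pi k / N`, `k = 0 .. N-1`.
#'
#' @param x Numeric signal, `length(x) >= N`.
#' @param N Window length in samples.
#' @param hop Hop between frame starts in samples (default `N/2`).
#' @param rate Sampling rate (Hz), carried for frequency axes.
#' @return A `spectrogram`: list with `values` (frames x N complex matrix),
#'   `rate`, `N`, `hop`.
#' @export
stft <- function(x, N = 200, hop = N %/% 2, rate = 200) {
  if (!is_count(N) || N < 2) stop_param("N must be an integer >= 2")
  if (!is_count(hop) || hop < 1) stop_param("hop must be a positive integer")
  if (length(x) < N) stop_param("signal shorter than one window")
  n_frames <- floor((length(x) - N) / hop) + 1
  w <- hann_window(N)
  frames <- matrix(0, nrow = N, ncol = n_frames)
  for (m in seq_len(n_frames))
    frames[, m] <- x[((m - 1) * hop + 1):((m - 1) * hop + N)] * w
  structure(list(values = t(stats::mvfft(frames)), rate = rate, N = N, hop = hop),
            class = "spectrogram")
}

#' Power spectral density from a spectrogram
#'
#' `E(w_k) = |X(m, w_k)|^2` averaged over frames; `PSD(w_k) = E(w_k) / N`.
#'
#' @param spec A `spectrogram` from [stft()].
#' @return An `eeg_psd`: list with `freq` (Hz per bin), `energy` `E(w_k)`,
#'   `psd`, `N`, `rate`; all values are non-negative.
#' @export
psd <- function(spec) {
  stopifnot(inherits(spec, "spectrogram"))
  if (nrow(spec$values) == 0) stop_param("empty spectrogram")
  E <- colMeans(Mod(spec$values)^2)
  structure(list(freq = (0:(spec$N - 1)) * spec$rate / spec$N,
                 energy = E, psd = E / spec$N, N = spec$N, rate = spec$rate),
            class = "eeg_psd")
}

#' Band energy from a PSD
#'
#' Sums `E(w_k)` over the non-redundant bins (`k <= N/2`) whose frequency
#' falls in the half-open band `[f_lo, f_hi)`; a band ending exactly at the
#' Nyquist frequency includes the Nyquist bin, so disjoint bands covering
#' `[0, rate/2]` partition the total energy.
#'
#' @param p An `eeg_psd` from [psd()].
#' @param band Numeric `c(f_lo, f_hi)` in Hz.
#' @return Scalar band energy; zero (with a warning) if no bin falls in the
#'   band.
#' @export
band_energy <- function(p, band) {
  stopifnot(inherits(p, "eeg_psd"))
  if (length(band) != 2 || band[1] < 0 || band[1] >= band[2] || band[2] > p$rate / 2)
    stop_param("band must satisfy 0 <= f_lo < f_hi <= rate/2")
  nyq <- p$rate / 2
  k_max <- floor(p$N / 2)           # non-redundant bins: k = 0 .. floor(N/2)
  f <- p$freq[seq_len(k_max + 1)]
  sel <- f >= band[1] & (f < band[2] | (band[2] == nyq & f == nyq))
  if (!any(sel)) {
    warning(sprintf("band [%g, %g) Hz contains no DFT bin", band[1], band[2]))
    return(0)
  }
  sum(p$energy[seq_len(k_max + 1)][sel])
}

#' Band-power features for one epoch
#'
#' One [band_energy()] per (channel, band) from the STFT power spectrum:
#' `channels x |bands|` features named `"chan:band"`.
#'
#' @param epoch An [eeg_epoch()].
#' @param bands Named list of band edges (default [eeg_bands()]).
#' @param N,hop STFT window and hop in samples (defaults: 1 s window, 50%
#'   overlap).
#' @return Named numeric feature vector.
#' @export
psd_features <- function(epoch, bands = eeg_bands(), N = NULL, hop = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (is.null(N)) N <- round(epoch$rate)
  if (is.null(hop)) hop <- N %/% 2
  nch <- nrow(epoch$data)
  out <- numeric(nch * length(bands))
  nms <- character(nch * length(bands))
  chn <- rownames(epoch$data) %||% sprintf("ch%d", seq_len(nch))
  i <- 0
  for (ch in seq_len(nch)) {
    p <- psd(stft(epoch$data[ch, ], N = N, hop = hop, rate = epoch$rate))
    for (b in names(bands)) {
      i <- i + 1
      out[i] <- band_energy(p, bands[[b]])
      nms[i] <- paste0(chn[ch], ":", b)
    }
  }
  stats::setNames(out, nms)
}

#' Energy spectral density
#'
#' `Phi(w_k) = |DFT(x)(w_k)|^2 / (2 pi)`, `k = 0 .. N-1`. The total
#' `sum_k Phi(w_k)` equals `N sum_n x[n]^2 / (2 pi)` (Parseval).
#'
#' @param x Non-empty numeric signal.
#' @return List with `esd` (numeric vector over bins) and `total` energy.
#' @export
esd <- function(x) {
  if (length(x) == 0) stop_param("x must be non-empty")
  phi <- Mod(stats::fft(x))^2 / (2 * pi)
  list(esd = phi, total = sum(phi))
}

#' EMD + energy-spectrum features for one epoch
#'
#' Per channel: empirical mode decomposition, keep the first `n_imfs` IMFs,
#' and take each IMF's total energy spectral density as one scalar feature
#' (`channels x n_imfs` features, e.g. 96 for 32 channels x 3 IMFs).
#' Channels yielding fewer than `n_imfs` IMFs contribute zero-energy
#' features for the missing layers.
#'
#' @param epoch An [eeg_epoch()].
#' @param n_imfs Number of IMF layers to keep (>= 1).
#' @param cfg A [sift_config()]; defaults to extracting at most `n_imfs`
#'   modes.
#' @return Named numeric feature vector (`"chan:imfK_energy"`).
#' @export
emd_esd_features <- function(epoch, n_imfs = 3, cfg = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (!is_count(n_imfs) || n_imfs < 1) stop_param("n_imfs must be >= 1")
  if (is.null(cfg)) cfg <- sift_config(max_imfs = n_imfs)
  nch <- nrow(epoch$data)
  chn <- rownames(epoch$data) %||% sprintf("ch%d", seq_len(nch))
  out <- numeric(nch * n_imfs)
  nms <- character(nch * n_imfs)
  i <- 0
  for (ch in seq_len(nch)) {
    x <- epoch$data[ch, ]
    dec <- if (all(x == 0)) list(imfs = list()) else emd_decompose(x, cfg)
    for (k in seq_len(n_imfs)) {
      i <- i + 1
      out[i] <- if (k <= length(dec$imfs)) esd(dec$imfs[[k]])$total else 0
      nms[i] <- sprintf("%s:imf%d_energy", chn[ch], k)
    }
  }
  stats::setNames(out, nms)
}

#' Feature matrix
#'
#' Epochs x features container with aligned names, class labels and
#' subject ids; the sample unit of the classification experiment.
#'
#' @param values Numeric matrix, one row per epoch.
#' @param feature_names Column names.
#' @param labels Per-epoch state labels.
#' @param subject_ids Per-epoch subject ids.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, feature_names, labels, subject_ids) {
  if (!is.matrix(values)) stop_param("values must be a matrix")
  if (ncol(values) != length(feature_names))
    stop_param("feature_names length must equal feature count")
  if (nrow(values) != length(labels) || nrow(values) != length(subject_ids))
    stop_param("labels and subject_ids must align with rows")
  if (!all(is.finite(values))) stop_data("feature matrix contains non-finite entries")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 labels = as.character(labels),
                 subject_ids = as.character(subject_ids)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features, %d subjects\n",
              nrow(x$values), ncol(x$values), length(unique(x$subject_ids))))
  invisible(x)
}

#' Extract features for every epoch in a set
#'
#' @param es An [eeg_epoch_set()].
#' @param method `"emd"` (EMD + energy spectrum) or `"psd"` (STFT band
#'   power).
#' @param ... Passed to [emd_esd_features()] or [psd_features()].
#' @return A [feature_matrix()].
#' @export
extract_features <- function(es, method = c("emd", "psd"), ...) {
  stopifnot(inherits(es, "eeg_epoch_set"))
  method <- match.arg(method)
  if (length(es$epochs) == 0) stop_param("empty epoch set")
  f <- switch(method, emd = emd_esd_features, psd = psd_features)
  rows <- lapply(es$epochs, f, ...)
  values <- do.call(rbind, rows)
  feature_matrix(values, colnames(values), es$labels, es$subject_ids)
}

# ---- higher-order spectra (off the default feature path) -------------------

#' Segmented third-order cumulant estimate
#'
#' Splits `x` into `K = length(x) / M` segments, computes the third-moment
#' estimate of each segment over lags `(m, n)`,
#' `r_i(m, n) = (1/M) sum_k x_i(k) x_i(k+m) x_i(k+n)` with the summation
#' range clipped so all indices stay in `1..M`, and averages the segments.
#'
#' @param x Numeric signal whose length is a multiple of `M`.
#' @param M Segment length.
#' @param p_lags Maximum absolute lag (`< M`).
#' @return A `cumulant_estimate`: list with `r` (the
#'   `(2 p + 1) x (2 p + 1)` lag matrix, dimnames = lags), `M`, `K`,
#'   `p_lags`.
#' @export
third_order_cumulant <- function(x, M, p_lags) {
  if (!is_count(M) || M < 1) stop_param("M must be a positive integer")
  if (length(x) %% M != 0 || length(x) == 0)
    stop_param("length(x) must be a positive multiple of M")
  if (!is_count(p_lags) || p_lags >= M) stop_param("p_lags must be < M")
  K <- length(x) %/% M
  lags <- -p_lags:p_lags
  r <- matrix(0, nrow = length(lags), ncol = length(lags),
              dimnames = list(lags, lags))
  for (i in seq_len(K)) {
    xi <- x[((i - 1) * M + 1):(i * M)]
    for (a in seq_along(lags)) for (b in seq_along(lags)) {
      m <- lags[a]; n <- lags[b]
      s1 <- max(1, 1 - m, 1 - n); s2 <- min(M, M - m, M - n)
      if (s1 > s2) next
      kk <- s1:s2
      r[a, b] <- r[a, b] + sum(xi[kk] * xi[kk + m] * xi[kk + n]) / M
    }
  }
  structure(list(r = r / K, M = M, K = K, p_lags = p_lags),
            class = "cumulant_estimate")
}

cumulant_lag <- function(ce, m, n) {
  ce$r[as.character(m), as.character(n)]
}

#' AR-model bispectrum from a cumulant estimate
#'
#' Solves the `(p+1) x (p+1)` cumulant system for the AR coefficients
#' `a_1..a_p` and the scale `beta`, then evaluates
#' `B(w1, w2) = beta I(w1) I(w2) Conj(I(w1 + w2))` on a grid, with
#' `I(w) = 1 + sum_n a_n exp(-j w (n - 1))` by default (`convention =
#' "printed"`); `convention = "standard"` uses the textbook
#' `exp(-j w n)` transfer.
#'
#' @param ce A `cumulant_estimate` covering lags up to `p`.
#' @param p AR model order (>= 0).
#' @param grid Numeric vector of angular frequencies in `[-pi, pi]`.
#' @param convention `"printed"` or `"standard"` exponent convention.
#' @return List with `B` (complex `length(grid) x length(grid)` matrix),
#'   `a` (AR coefficients), `beta`, `grid`.
#' @export
ar_bispectrum <- function(ce, p, grid = seq(-pi, pi, length.out = 33),
                          convention = c("printed", "standard")) {
  stopifnot(inherits(ce, "cumulant_estimate"))
  convention <- match.arg(convention)
  if (!is_count(p) || p > ce$p_lags)
    stop_param("p must be a non-negative integer covered by the cumulant lags")
  # R[i, j] = r(j - i, j - i), i, j = 0..p
  R <- outer(0:p, 0:p, Vectorize(function(i, j) cumulant_lag(ce, j - i, j - i)))
  if (p == 0) {
    a <- numeric(0); beta <- R[1, 1]
  } else {
    A <- R[-1, -1, drop = FALSE]
    rhs <- -R[-1, 1]
    cond <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
    a <- tryCatch(solve(A, rhs), error = function(e)
      abort_fatigue(sprintf("singular cumulant system (condition number %.3g)", cond),
                    "fatigueEEG_numerical_error"))
    beta <- sum(R[1, ] * c(1, a))
  }
  transfer <- function(w) {
    if (p == 0) return(rep(1 + 0i, length(w)))
    shift <- if (convention == "printed") 0 else 1
    vapply(w, function(wi)
      1 + sum(a * exp(-1i * wi * ((1:p) - 1 + shift))), complex(1))
  }
  Iw <- transfer(grid)
  B <- matrix(0i, length(grid), length(grid))
  for (i in seq_along(grid)) for (j in seq_along(grid))
    B[i, j] <- beta * Iw[i] * Iw[j] * Conj(transfer(grid[i] + grid[j]))
  list(B = B, a = a, beta = beta, grid = grid)
}
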