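#' Reduce the sampling rate of a recording
#'
#' Anti-alias low-pass filters each channel (Butterworth order 6, zero-phase
#' forward-backward, cutoff 0.8 x the target Nyquist) and decimates by the
#' integer factor `rate / target_rate`.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate New rate in Hz; must divide the current rate.
#' @return The downsampled [eeg_recording()] with
#'   `floor(n * target_rate / rate)` samples per channel.
#' @export
downsample <- function(rec, target_rate) {
  validate_recording(rec)
  if (!is_scalar_num(target_rate) || target_rate <= 0)
    stop_param("target_rate must be a positive number")
  factor <- rec$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop_param(sprintf("decimation factor %g is not an integer (rate %g -> %g)",
                       factor, rec$rate, target_rate))
  factor <- round(factor)
  if (factor == 1) return(rec)
  aa <- signal::butter(6, 0.8 * target_rate / rec$rate, type = "low")
  n_out <- floor(ncol(rec$data) / factor)
  idx <- seq(1, by = factor, length.out = n_out)
  out <- matrix(0, nrow = nrow(rec$data), ncol = n_out)
  for (ch in seq_len(nrow(rec$data)))
    out[ch, ] <- signal::filtfilt(aa, rec$data[ch, ])[idx]
  eeg_recording(out, target_rate, rec$channel_names, rec$subject_id, rec$state)
}

#' Zero-phase bandpass filter a recording
#'
#' Order-4 Butterworth high-pass at `low` plus order-4 Butterworth low-pass
#' at `high`, each applied forward-backward; the low-pass runs twice so a
#' mains tone 5 Hz above a 45 Hz edge is attenuated below 10% RMS. Length is
#' preserved.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @return The filtered [eeg_recording()].
#' @export
bandpass <- function(rec, low, high) {
  validate_recording(rec)
  if (!is_scalar_num(low) || !is_scalar_num(high) ||
      !(0 < low && low < high && high < rec$rate / 2))
    stop_param(sprintf("band edges must satisfy 0 < low < high < rate/2 = %g",
                       rec$rate / 2))
  hp <- signal::butter(4, low / (rec$rate / 2), type = "high")
  lp <- signal::butter(4, high / (rec$rate / 2), type = "low")
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    x <- signal::filtfilt(hp, out[ch, ])
    x <- signal::filtfilt(lp, x)
    out[ch, ] <- signal::filtfilt(lp, x)
  }
  eeg_recording(out, rec$rate, rec$channel_names, rec$subject_id, rec$state)
}

#' Construct an epoch
#'
#' @param data Channels x samples matrix.
#' @param rate Sampling rate (Hz).
#' @param duration Epoch length (s); `duration * rate` must equal `ncol(data)`.
#' @param subject_id,state,index Provenance: subject, class label, ordinal
#'   position within the source recording.
#' @return An `eeg_epoch` object.
#' @export
eeg_epoch <- function(data, rate, duration, subject_id, state, index) {
  if (!is.matrix(data)) stop_param("epoch data must be a matrix")
  if (!is_scalar_num(duration) || duration <= 0)
    stop_param("duration must be positive")
  if (abs(ncol(data) - duration * rate) > 1e-6)
    stop_param("epoch samples must equal duration * rate exactly")
  structure(list(data = data, rate = rate, duration = duration,
                 subject_id = as.character(subject_id), state = state,
                 index = index),
            class = "eeg_epoch")
}

#' Construct an epoch set
#'
#' All epochs must share rate, duration and channel count; the label vector
#' is aligned with the epoch list.
#'
#' @param epochs List of [eeg_epoch()] objects.
#' @return An `eeg_epoch_set`.
#' @export
eeg_epoch_set <- function(epochs) {
  if (length(epochs) > 0) {
    rates <- vapply(epochs, `[[`, 0, "rate")
    durs <- vapply(epochs, `[[`, 0, "duration")
    nchs <- vapply(epochs, function(e) nrow(e$data), 0L)
    if (length(unique(rates)) > 1 || length(unique(durs)) > 1 ||
        length(unique(nchs)) > 1)
      stop_param("all epochs must share rate, duration and channel count")
  }
  structure(list(epochs = epochs,
                 labels = vapply(epochs, `[[`, "", "state"),
                 subject_ids = vapply(epochs, `[[`, "", "subject_id")),
            class = "eeg_epoch_set")
}

#' @export
length.eeg_epoch_set <- function(x) length(x$epochs)

#' @export
print.eeg_epoch_set <- function(x, ...) {
  cat(sprintf("<eeg_epoch_set> %d epochs (%s)\n", length(x$epochs),
              paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping windows of `duration` seconds; the trailing
#' partial window is discarded. Labels are inherited from the recording's
#' state. A recording shorter than one epoch yields an empty set (with a
#' message), not an error.
#'
#' @param rec An [eeg_recording()].
#' @param duration Epoch duration in seconds; `duration * rate` must be an
#'   integer.
#' @return An [eeg_epoch_set()].
#' @export
epoch_recording <- function(rec, duration) {
  validate_recording(rec)
  spe <- duration * rec$rate
  if (!is_scalar_num(duration) || duration <= 0 || abs(spe - round(spe)) > 1e-9)
    stop_param("duration * rate must be a positive integer")
  spe <- round(spe)
  k <- floor(ncol(rec$data) / spe)
  if (k == 0)
    message(sprintf("recording shorter than one %gs epoch; empty epoch set", duration))
  epochs <- lapply(seq_len(k), function(i) {
    d <- rec$data[, ((i - 1) * spe + 1):(i * spe), drop = FALSE]
    rownames(d) <- rec$channel_names
    eeg_epoch(d, rec$rate, duration, rec$subject_id, rec$state, i)
  })
  eeg_epoch_set(epochs)
}

#' Combine epoch sets
#'
#' @param ... `eeg_epoch_set` objects.
#' @return A single [eeg_epoch_set()] with epochs concatenated in order.
#' @export
combine_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "eeg_epoch_set"))
    sets <- sets[[1]]
  eeg_epoch_set(do.call(c, lapply(sets, `[[`, "epochs")))
}

#' Standard preprocessing chain
#'
#' Downsample (if `target_rate` differs), bandpass, and epoch every
#' recording in a dataset, returning one combined epoch set. The default
#' order is downsample then bandpass.
#'
#' @param recordings List of [eeg_recording()] objects.
#' @param target_rate Rate after decimation (Hz).
#' @param band Bandpass edges `c(low, high)` in Hz, or `NULL` to skip.
#' @param epoch_s Epoch duration in seconds.
#' @return An [eeg_epoch_set()] spanning all recordings.
#' @export
preprocess_dataset <- function(recordings, target_rate = 200,
                               band = c(0.1, 50), epoch_s = 10) {
  sets <- lapply(recordings, function(rec) {
    if (rec$rate != target_rate) rec <- downsample(rec, target_rate)
    if (!is.null(band)) rec <- bandpass(rec, band[1], band[2])
    epoch_recording(rec, epoch_s)
  })
  combine_epoch_sets(sets)
}
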