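#' Write a recording to disk
#'
#' Two on-disk formats are supported: a plain CSV dialect (first column
#' `time_s`, then one column per channel, header row = channel names) with a
#' `key=value` sidecar `<path>.meta` holding subject, state and rate; and
#' 16-bit EDF (European Data Format), with subject and state embedded in the
#' patient/recording header fields.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path; extension picks the format when
#'   `format = "auto"`.
#' @param format `"auto"`, `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") write_recording_csv(rec, path) else write_recording_edf(rec, path)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File path.
#' @param format `"auto"`, `"csv"` or `"edf"`.
#' @return An [eeg_recording()]. For CSV, the rate is taken from the sidecar
#'   when present, otherwise inferred from the `time_s` column.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") read_recording_csv(path) else read_recording_edf(path)
}

# ---- CSV dialect -----------------------------------------------------------

meta_path <- function(path) paste0(path, ".meta")

write_recording_csv <- function(rec, path) {
  df <- data.table::as.data.table(t(rec$data))
  data.table::setnames(df, rec$channel_names)
  df <- cbind(data.table::data.table(time_s = (seq_len(ncol(rec$data)) - 1) / rec$rate), df)
  data.table::fwrite(df, path)
  writeLines(c(sprintf("subject_id=%s", rec$subject_id),
               sprintf("state=%s", rec$state),
               sprintf("rate=%.10g", rec$rate)),
             meta_path(path))
  invisible(path)
}

read_meta <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines[nzchar(lines)], "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) paste(p[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}

read_recording_csv <- function(path) {
  df <- tryCatch(
    data.table::fread(path, header = TRUE, fill = FALSE, sep = ","),
    error = function(e) stop_format(sprintf("malformed CSV '%s': %s", path, conditionMessage(e))),
    warning = function(w) stop_format(sprintf("malformed CSV '%s': %s", path, conditionMessage(w))))
  if (ncol(df) < 2 || names(df)[1] != "time_s")
    stop_format("CSV header must start with column 'time_s'")
  if (!all(vapply(df, is.numeric, TRUE)))
    stop_format("CSV contains a non-numeric column")
  if (anyNA(df))
    stop_format("CSV contains missing values (ragged or empty cells)")
  meta <- read_meta(meta_path(path))
  rate <- if (!is.null(meta$rate)) as.numeric(meta$rate) else {
    dt <- diff(df$time_s)
    if (length(dt) == 0 || any(dt <= 0)) stop_format("cannot infer rate from field 'time_s'")
    round(1 / stats::median(dt), 6)
  }
  eeg_recording(unname(t(as.matrix(df[, -1]))), rate, names(df)[-1],
                meta$subject_id %||% "unknown", meta$state %||% "normal")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- EDF (16-bit) ----------------------------------------------------------

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

write_recording_edf <- function(rec, path) {
  n <- ncol(rec$data); ns <- nrow(rec$data); rate <- rec$rate
  if (n %% rate == 0 && rate == round(rate)) {
    spr <- as.integer(rate); n_rec <- n %/% spr; dur <- 1
  } else {
    spr <- n; n_rec <- 1L; dur <- n / rate
  }
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  hdr_bytes <- 256 + 256 * ns
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(sprintf("subject=%s", rec$subject_id), 80),
    pad_field(sprintf("state=%s rate=%.10g", rec$state, rate), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(hdr_bytes, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(format(dur, digits = 7), 8),
    pad_field(ns, 4)), con, eos = NULL)
  fields <- list(
    list(rec$channel_names, 16), list(rep("", ns), 80),
    list(rep("uV", ns), 8),
    list(sprintf("%.7g", pmin_), 8), list(sprintf("%.7g", pmax_), 8),
    list(rep(dmin, ns), 8), list(rep(dmax, ns), 8),
    list(rep("", ns), 80), list(rep(spr, ns), 8), list(rep("", ns), 32))
  for (f in fields)
    writeChar(paste(vapply(f[[1]], pad_field, "", width = f[[2]]), collapse = ""),
              con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    block <- round((rec$data[, idx, drop = FALSE] - pmin_) * scale + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(con, width, n = 1) {
  vapply(seq_len(n), function(i) trimws(readChar(con, width, useBytes = TRUE)), "")
}

read_recording_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  read_edf_field(con, 8)                       # version
  patient <- read_edf_field(con, 80)
  recording <- read_edf_field(con, 80)
  read_edf_field(con, 8); read_edf_field(con, 8)   # date, time
  read_edf_field(con, 8)                       # header bytes
  read_edf_field(con, 44)
  n_rec <- as.integer(read_edf_field(con, 8))
  dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop_format("EDF header: invalid signal count")
  labels <- read_edf_field(con, 16, ns)
  read_edf_field(con, 80, ns)
  read_edf_field(con, 8, ns)                   # physical dimension
  pmin_ <- as.numeric(read_edf_field(con, 8, ns))
  pmax_ <- as.numeric(read_edf_field(con, 8, ns))
  dmin <- as.numeric(read_edf_field(con, 8, ns))
  dmax <- as.numeric(read_edf_field(con, 8, ns))
  read_edf_field(con, 80, ns)
  spr <- as.integer(read_edf_field(con, 8, ns))
  read_edf_field(con, 32, ns)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr, n_rec, dur)))
    stop_format("EDF header: unparseable numeric field")
  if (length(unique(spr)) != 1)
    stop_format("EDF: differing samples-per-record across signals unsupported")

  n <- n_rec * spr[1]
  data <- matrix(0, nrow = ns, ncol = n)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2, endian = "little")
    if (length(raw) < ns * spr[1]) stop_format("EDF: truncated data record")
    block <- matrix(raw, nrow = spr[1], ncol = ns)   # samples x signals
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t((block - rep(dmin, each = spr[1])) *
                       rep(scale, each = spr[1]) + rep(pmin_, each = spr[1]))
  }
  rate <- spr[1] / dur
  subj <- sub("^subject=", "", patient)
  state <- if (grepl("state=fatigue", recording)) "fatigue" else "normal"
  eeg_recording(data, rate, labels, subj, state)
}
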