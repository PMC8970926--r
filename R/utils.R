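# Internal condition helpers. All user-facing errors carry a package class so
# callers (and tests) can distinguish parameter/format/data errors.

abort_fatigue <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fatigueEEG_error")))
}

stop_param <- function(msg) abort_fatigue(msg, "fatigueEEG_parameter_error")
stop_format <- function(msg) abort_fatigue(msg, "fatigueEEG_format_error")
stop_data <- function(msg) abort_fatigue(msg, "fatigueEEG_data_error")
stop_config <- function(msg) abort_fatigue(msg, "fatigueEEG_config_error")

# Deterministic 31-bit seed derived from a base seed plus string salts.
# Keeps every derived seed strictly below 2^31 so set.seed() is safe.
derive_seed <- function(seed, ...) {
  salt <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                collapse = "|")
  h <- 0
  for (v in utf8ToInt(salt)) h <- (h * 131 + v) %% 2147483629
  as.integer(bitwXor(as.integer(h), as.integer(seed %% 2147483629)) %% 2147483629)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && abs(x - round(x)) < 1e-9

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
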