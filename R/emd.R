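#' Locate local extrema
#'
#' Strict local maxima and minima by neighbour comparison; a flat run
#' counts once, at its midpoint (earlier index on ties). Endpoints are not
#' extrema.
#'
#' @param x Numeric signal of length >= 3.
#' @return List with integer index vectors `maxima` and `minima` (1-based).
#' @export
find_extrema <- function(x) {
  if (!is.numeric(x) || length(x) < 3) stop_param("signal must have length >= 3")
  r <- rle(x)
  k <- length(r$lengths)
  if (k < 3) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1, r$lengths[-k]))
  v <- r$values
  interior <- 2:(k - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  is_min <- v[interior] < v[interior - 1] & v[interior] < v[interior + 1]
  mid <- as.integer(starts[interior] + (r$lengths[interior] - 1L) %/% 2L)
  list(maxima = mid[is_max], minima = mid[is_min])
}

no_extrema_condition <- function(msg) {
  structure(class = c("fatigueEEG_no_extrema", "error", "condition"),
            list(message = msg, call = NULL))
}

# Spline through extrema with mirror extension of the two end extrema, so
# the envelope does not swing wildly at the signal boundaries.
spline_envelope <- function(x, idx) {
  n <- length(x)
  tt <- idx; vv <- x[idx]
  m <- length(idx)
  left_t <- 2 - rev(tt[seq_len(min(2, m))])
  left_v <- rev(vv[seq_len(min(2, m))])
  right_t <- 2 * n - rev(tt[(m - min(2, m) + 1):m])
  right_v <- rev(vv[(m - min(2, m) + 1):m])
  ord <- order(c(left_t, tt, right_t))
  ts <- c(left_t, tt, right_t)[ord]
  vs <- c(left_v, vv, right_v)[ord]
  keep <- !duplicated(ts)
  stats::spline(ts[keep], vs[keep], xout = seq_len(n), method = "fmm")$y
}

#' Upper and lower envelopes through extrema
#'
#' Cubic-spline interpolants through the maxima (upper) and minima (lower),
#' extended past the signal ends by mirroring the two end extrema. At least
#' two maxima and two minima are required; otherwise a
#' `fatigueEEG_no_extrema` condition is signalled (sifting treats this as
#' termination).
#'
#' @param x Numeric signal.
#' @param maxima,minima Extrema indices, as from [find_extrema()].
#' @return List with numeric vectors `upper` and `lower` of `length(x)`.
#' @export
envelopes <- function(x, maxima, minima) {
  if (length(maxima) < 2 || length(minima) < 2)
    stop(no_extrema_condition(sprintf(
      "need >= 2 maxima and minima to fit envelopes (have %d / %d)",
      length(maxima), length(minima))))
  list(upper = spline_envelope(x, maxima), lower = spline_envelope(x, minima))
}

#' One sifting step
#'
#' Subtracts the envelope mean `m(t) = (e_up(t) + e_low(t)) / 2` from the
#' signal: `h = x - m`.
#'
#' @param x Numeric signal.
#' @return List with `h` (sifted signal) and `mean_env` (envelope mean).
#' @export
sift_once <- function(x) {
  ex <- find_extrema(x)
  env <- envelopes(x, ex$maxima, ex$minima)
  m <- (env$upper + env$lower) / 2
  list(h = x - m, mean_env = m)
}

#' Sifting configuration
#'
#' @param max_imfs Maximum number of IMFs to extract.
#' @param max_sift_iters Cap on inner sifting iterations per IMF.
#' @param sd_tol Cauchy criterion for the inner loop: stop when
#'   `sum((h_prev - h)^2) / sum(h_prev^2) < sd_tol`.
#' @param resid_energy_tol Outer stop: quit when residual energy falls
#'   below this fraction of the input energy (the "preset value" of the
#'   decomposition, realized as an energy fraction).
#' @param fixed_sift Optional fixed sift count per IMF (overrides the
#'   Cauchy criterion when set).
#' @param boundary Envelope boundary handling; only `"mirror"` is
#'   implemented.
#' @return A `sift_config` object.
#' @export
sift_config <- function(max_imfs = 10, max_sift_iters = 50, sd_tol = 0.2,
                        resid_energy_tol = 0.01, fixed_sift = NULL,
                        boundary = "mirror") {
  if (!is_count(max_imfs) || max_imfs < 1) stop_param("max_imfs must be >= 1")
  if (!is_count(max_sift_iters) || max_sift_iters < 1)
    stop_param("max_sift_iters must be >= 1")
  if (!is_scalar_num(sd_tol) || sd_tol <= 0) stop_param("sd_tol must be > 0")
  if (!is.null(fixed_sift) && (!is_count(fixed_sift) || fixed_sift < 1))
    stop_param("fixed_sift must be >= 1 when given")
  structure(list(max_imfs = max_imfs, max_sift_iters = max_sift_iters,
                 sd_tol = sd_tol, resid_energy_tol = resid_energy_tol,
                 fixed_sift = fixed_sift, boundary = match.arg(boundary, "mirror")),
            class = "sift_config")
}

#' Empirical mode decomposition
#'
#' Iteratively sifts the running residual into intrinsic mode functions
#' (IMFs), highest frequency first. Decomposition stops when the residual
#' has fewer than two extrema pairs (monotone), when `max_imfs` are
#' extracted, or when residual energy drops below
#' `resid_energy_tol x input energy`. By the telescoping construction,
#' `sum of IMFs + residual` equals the input exactly.
#'
#' @param x Numeric signal, length >= 8, finite.
#' @param cfg A [sift_config()].
#' @return An `imf_set`: list with `imfs` (list of numeric vectors),
#'   `residual`, and `sift_counts`.
#' @export
emd_decompose <- function(x, cfg = sift_config()) {
  if (!is.numeric(x) || !all(is.finite(x))) stop_data("input must be finite numeric")
  if (length(x) < 8) stop_param("signal must have length >= 8")
  stopifnot(inherits(cfg, "sift_config"))
  e_in <- sum(x^2)
  residual <- x
  imfs <- list(); sift_counts <- integer(0)

  while (length(imfs) < cfg$max_imfs) {
    if (e_in > 0 && sum(residual^2) < cfg$resid_energy_tol * e_in) break
    ex <- find_extrema(residual)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break

    h <- residual
    k <- 0
    repeat {
      k <- k + 1
      step <- tryCatch(sift_once(h), fatigueEEG_no_extrema = function(e) NULL)
      if (is.null(step)) break
      h_new <- step$h
      if (!is.null(cfg$fixed_sift)) {
        h <- h_new
        if (k >= cfg$fixed_sift) break
      } else {
        sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
        h <- h_new
        if (sd_crit < cfg$sd_tol || k >= cfg$max_sift_iters) break
      }
    }
    imfs[[length(imfs) + 1]] <- h
    sift_counts <- c(sift_counts, k)
    residual <- residual - h
  }

  structure(list(imfs = imfs, residual = residual, sift_counts = sift_counts),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (%d samples)\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}
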