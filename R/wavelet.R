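# Orthogonal periodized discrete wavelet transform.
#
# The analysis operator is the orthogonal matrix whose rows are the even
# shifts of the scaling/wavelet filters under periodic extension, so the
# inverse is its transpose and perfect reconstruction is exact for any even
# length. Odd lengths are handled by repeating the final sample for one
# level (recorded and trimmed on reconstruction).

# Daubechies scaling (decomposition low-pass) filters; orthonormality
# (sum h = sqrt(2), sum h^2 = 1) is asserted in the test suite.
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134, 0.8365163037378079,
          0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  db8 = c(-0.00011747678412476953, 0.0006754494064505693,
          -0.00039174037337694705, -0.004870352993451574,
          0.008746094047405777, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.0004724845739132828,
          -0.2840155429615469, -0.015829105256349306, 0.5853546836542067,
          0.6756307362972898, 0.31287159091429995, 0.05441584224310401),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427))
WAVELET_FILTERS$db1 <- WAVELET_FILTERS$haar

wavelet_filter_pair <- function(wavelet) {
  h <- WAVELET_FILTERS[[wavelet]]
  if (is.null(h))
    stop_param(sprintf("unknown wavelet '%s' (available: %s)", wavelet,
                       paste(names(WAVELET_FILTERS), collapse = ", ")))
  g <- rev(h) * (-1)^(seq_along(h) - 1)   # quadrature mirror filter
  list(h = h, g = g)
}

# One periodized analysis step: returns approximation and detail halves.
dwt_step <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2
  a <- numeric(half); d <- numeric(half)
  base_idx <- 2 * (seq_len(half) - 1)
  for (k in seq_along(h)) {
    idx <- (base_idx + (k - 1)) %% n + 1
    a <- a + h[k] * x[idx]
    d <- d + g[k] * x[idx]
  }
  list(a = a, d = d)
}

# Adjoint (= inverse, by orthogonality) of dwt_step.
idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  base_idx <- 2 * (seq_len(half) - 1)
  for (k in seq_along(h)) {
    idx <- (base_idx + (k - 1)) %% n + 1
    x[idx] <- x[idx] + h[k] * a + g[k] * d
  }
  x
}

#' Multilevel discrete wavelet decomposition
#'
#' Periodized orthogonal DWT: `J` detail levels plus a final approximation.
#' Unmodified coefficients reconstruct the input to machine precision via
#' [wavelet_reconstruct()].
#'
#' @param x Numeric signal of length at least `2^J`.
#' @param wavelet Filter name: `"haar"`/`"db1"`, `"db2"`, `"db4"`, `"db8"`,
#'   `"sym4"`.
#' @param J Number of decomposition levels (>= 1).
#' @return A `wavelet_coeffs` object with elements `details` (list of level
#'   1..J detail vectors, finest first), `approx`, `wavelet`, `J`.
#' @export
wavelet_decompose <- function(x, wavelet = "db4", J = 3) {
  if (!is.numeric(x) || !all(is.finite(x))) stop_data("signal must be finite numeric")
  if (!is_count(J) || J < 1) stop_param("J must be a positive integer")
  if (length(x) < 2^J)
    stop_param(sprintf("signal of length %d too short for %d levels", length(x), J))
  fl <- wavelet_filter_pair(wavelet)
  details <- vector("list", J)
  pads <- logical(J)
  cur <- x
  for (j in seq_len(J)) {
    if (length(cur) %% 2 == 1) {
      cur <- c(cur, cur[length(cur)])
      pads[j] <- TRUE
    }
    st <- dwt_step(cur, fl$h, fl$g)
    details[[j]] <- st$d
    cur <- st$a
  }
  structure(list(details = details, approx = cur, wavelet = wavelet, J = J,
                 pads = pads, n = length(x)),
            class = "wavelet_coeffs")
}

#' Inverse multilevel wavelet transform
#'
#' @param wc A `wavelet_coeffs` object from [wavelet_decompose()] (its
#'   coefficients possibly thresholded).
#' @return The reconstructed signal, at the original input length.
#' @export
wavelet_reconstruct <- function(wc) {
  stopifnot(inherits(wc, "wavelet_coeffs"))
  fl <- wavelet_filter_pair(wc$wavelet)
  cur <- wc$approx
  for (j in rev(seq_len(wc$J))) {
    cur <- idwt_step(cur, wc$details[[j]], fl$h, fl$g)
    if (wc$pads[j]) cur <- cur[-length(cur)]
  }
  cur
}
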