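# Discrete Hilbert transform via the FFT analytic-signal construction:
# zero the negative frequencies, double the positive ones, keep DC (and the
# Nyquist bin for even lengths), inverse-transform. The imaginary part of the
# result is the quadrature series; the principal-value convolution of the
# continuous definition has no discrete prescription, so this standard
# spectral construction realizes it.

# One-sided spectral weights for a length-n analytic signal.
analytic_weights <- function(n) {
  u <- numeric(n)
  u[1] <- 1
  if (n %% 2 == 0) {
    u[n / 2 + 1] <- 1
    if (n > 2) u[2:(n / 2)] <- 2
  } else {
    u[2:((n + 1) / 2)] <- 2
  }
  u
}

#' Discrete Hilbert transform
#'
#' Returns the quadrature companion of a real series: the series phase-shifted
#' by 90 degrees, computed with the FFT analytic-signal method. For an on-grid
#' cosine the result is the matching sine.
#'
#' @param signal Real numeric vector, length >= 2.
#' @return Real numeric vector of the same length.
#' @export
#' @examples
#' t <- (0:159) / 160
#' h <- hilbert_transform(cos(2 * pi * 10 * t))
#' max(abs(h - sin(2 * pi * 10 * t)))
hilbert_transform <- function(signal) {
  if (!is.numeric(signal) || length(signal) < 2L) {
    stop_invalid("`signal` must be a numeric series of length >= 2")
  }
  n <- length(signal)
  z <- fft(fft(signal) * analytic_weights(n), inverse = TRUE) / n
  Im(z)
}

# Hilbert transform of every row of a channels-by-samples matrix (vectorized
# with mvfft over channels).
hilbert_transform_rows <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop_invalid("need at least 2 samples per channel")
  u <- analytic_weights(n)
  z <- mvfft(mvfft(t(x)) * u, inverse = TRUE) / n
  t(Im(z))
}

#' Analytic signal
#'
#' Complex series `x + i * H(x)` whose real part is the input exactly and
#' whose modulus is the instantaneous envelope.
#'
#' @param signal Real numeric vector, length >= 2.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(signal) {
  complex(real = signal, imaginary = hilbert_transform(signal))
}
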