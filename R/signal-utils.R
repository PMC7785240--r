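#' Wrap angles to the interval (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length with every value in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Analytic signal via the FFT
#'
#' Computes the discrete analytic signal whose real part is the input and
#' whose imaginary part is its Hilbert transform, by zeroing negative
#' frequencies and doubling positive ones in the DFT.
#'
#' @param x real numeric vector (zero-mean narrowband input expected when the
#'   argument is to be interpreted as instantaneous phase).
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (anyNA(x)) stop("analytic_signal: input contains NA")
  n <- length(x)
  if (n < 2L) stop("analytic_signal: need at least 2 samples")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Centred convolution of x with an odd-length symmetric kernel, via FFT.
# Returns a series of the same length as x; edges see implicit zero padding.
centred_convolve <- function(x, taps) {
  n <- length(x)
  k <- length(taps)
  m <- (k - 1L) / 2L
  nfft <- stats::nextn(n + k - 1L, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(taps, numeric(nfft - k)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  y[(m + 1L):(m + n)]
}

#' Zero-phase FIR filtering
#'
#' Applies a symmetric (linear-phase) FIR kernel in the forward and backward
#' directions, so the net phase response is exactly zero and the magnitude
#' response is the square of the single-pass design response. For a symmetric
#' kernel this is computed as two centred convolutions, which is algebraically
#' identical to forward-backward filtering.
#'
#' @param x numeric series.
#' @param taps odd-length symmetric FIR coefficient vector.
#' @return filtered series, same length as `x`.
#' @export
zero_phase_filter <- function(x, taps) {
  k <- length(taps)
  if (k %% 2L == 0L) stop("zero_phase_filter: tap count must be odd")
  if (max(abs(taps - rev(taps))) > 1e-9 * max(abs(taps))) {
    stop("zero_phase_filter: taps must be symmetric (linear phase)")
  }
  centred_convolve(centred_convolve(x, taps), taps)
}

# Fraction-of-variance helpers -------------------------------------------

# Periodogram-based variance of x contributed by frequencies |f| in [lo, hi].
band_variance <- function(x, rate, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)  # fold to [0, rate/2]
  sum(p[f >= lo & f <= hi])
}

#' Band-limited 1/f background noise
#'
#' Generates a zero-mean, unit-variance realization of noise with power
#' spectral density proportional to 1/f^exponent, band-limited to (0, fmax].
#' Used as the resting-state BOLD background in the synthetic-data generator.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param exponent spectral exponent (1 = pink noise).
#' @param fmax upper band edge in Hz (defaults to Nyquist).
#' @return numeric vector of length `n`, standardized to unit variance.
#' @export
one_over_f_noise <- function(n, rate, exponent = 1, fmax = rate / 2) {
  if (n < 4L) stop("one_over_f_noise: n too small")
  nf <- n %/% 2L
  f <- (1:nf) * rate / n
  amp <- ifelse(f > 0 & f <= fmax, f^(-exponent / 2), 0)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  if (n %% 2L == 0L) z[nf] <- complex(real = stats::rnorm(1), imaginary = 0) * amp[nf]
  spec <- c(0, z, Conj(rev(z[seq_len(nf - (1 - n %% 2L))])))
  x <- Re(stats::fft(spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) stop("one_over_f_noise: degenerate realization")
  (x - mean(x)) / s
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler for the von Mises distribution with location
#' `mu` and concentration `kappa`. For `kappa` near zero the distribution is
#' uniform on the circle.
#'
#' @param n number of draws.
#' @param mu location parameter in radians.
#' @param kappa concentration parameter (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("rvonmises: kappa must be >= 0")
  if (kappa < 1e-8) return(wrap_phase(stats::runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    fz <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - fz)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      out[i] <- sign(u3 - 0.5) * acos(fz)
      i <- i + 1L
    }
  }
  wrap_phase(out + mu)
}
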