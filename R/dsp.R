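#' @keywords internal
#' @useDynLib gaitBCI, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Core single-rate DSP used throughout the package: Butterworth IIR design,
## zero-phase (forward-backward) filtering, Welch spectra, coloured noise.
## Implemented here because no IIR design routine ships with the base stack;
## the design follows the classical analog-prototype + bilinear-transform
## route and is unit-tested against closed-form passband/stopband behaviour.

# Polynomial from roots (complex), ascending degree order reversed to match
# the usual b/a convention (coefficient of z^0 first after normalization).
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Classical analog lowpass prototype, lowpass-to-bandpass transform and
#' bilinear mapping with frequency prewarping.  Returns transfer-function
#' coefficients \code{b} (numerator) and \code{a} (denominator), gain
#' normalized to exactly one at the (prewarped) band centre.
#'
#' @param low,high band edges in Hz, \code{0 < low < high < fs/2}.
#' @param fs sampling rate in Hz.
#' @param order analog prototype order (the bandpass filter has twice as
#'   many poles; forward-backward application doubles the effective order
#'   again).
#' @return list with elements \code{b}, \code{a}.
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2 (got ",
         low, "-", high, " Hz at fs=", fs, ")")
  ## prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_lp <- complex(real = -sin(theta), imaginary = cos(theta))
  ## prewarped analog edges
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  w1 <- warp(low); w2 <- warp(high)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  ## lowpass -> bandpass: each prototype pole p yields two poles solving
  ## s^2 - p*bw*s + w0^2 = 0
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((p * bw / 2)^2 - w0^2)
    p_bp <- c(p_bp, p * bw / 2 + disc, p * bw / 2 - disc)
  }
  ## bilinear transform; bandpass zeros: 'order' at s=0 -> z=1, and the
  ## implicit zeros at infinity -> z=-1
  fs2 <- 2 * fs
  z_d <- c(rep(1, order), rep(-1, order))
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  b <- Re(poly_from_roots(z_d))
  a <- Re(poly_from_roots(p_d))
  ## second-order sections: each conjugate pole pair with one zero at
  ## z = 1 and one at z = -1 (the natural pairing for a Butterworth
  ## bandpass).  The cascade is far better conditioned than the
  ## expanded-polynomial recursion for narrow bands.
  pu <- p_d[Im(p_d) >= 0]
  pu <- pu[order(-Mod(pu))]
  sos <- lapply(pu, function(p)
    list(b = c(1, 0, -1), a = c(1, -2 * Re(p), Mod(p)^2)))
  ## normalize gain to 1 at the prewarped centre frequency, spread evenly
  ## over the sections
  w0_d <- 2 * atan(w0 / fs2)
  zc <- exp(1i * w0_d)
  resp <- function(coef) sum(coef * zc^(-(seq_along(coef) - 1)))
  h_tot <- prod(vapply(sos, function(s) Mod(resp(s$b) / resp(s$a)), 0))
  g <- (1 / h_tot)^(1 / length(sos))
  sos <- lapply(sos, function(s) { s$b <- s$b * g; s })
  h <- resp(b) / resp(a)
  b <- b / Mod(h)
  list(b = b, a = a, sos = sos)
}

## Direct-form IIR filtering of each column of x (zero initial conditions).
iir_filter <- function(x, b, a) {
  x <- as.matrix(x)
  nb <- length(b)
  ## FIR part via C-level convolution filter, then the recursive AR part
  xp <- rbind(matrix(0, nb - 1, ncol(x)), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- v[nb:nrow(xp), , drop = FALSE]
  v[is.na(v)] <- 0
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1] / a[1], method = "recursive")
    y <- matrix(as.numeric(y), nrow(v), ncol(v)) / a[1]
  } else {
    y <- v / a[1]
  }
  y
}

#' Zero-phase forward-backward filtering
#'
#' Applies the IIR filter forward and then backward over time so that the
#' net phase response is zero (at the price of squaring the magnitude
#' response).  Odd (reflected) padding of three filter lengths suppresses
#' edge transients, matching common practice.
#'
#' @param x numeric vector, or matrix with time along rows (one column per
#'   channel).
#' @param b,a transfer-function coefficients from [butter_bandpass()], or
#'   the full filter object itself (then second-order sections are used).
#' @return filtered data with the shape of \code{x}.
#' @export
filtfilt <- function(x, b, a = NULL) {
  if (is.list(b)) { flt <- b } else { flt <- list(b = b, a = a) }
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  ord <- if (!is.null(flt$sos)) 2 * length(flt$sos)
  else max(length(flt$a), length(flt$b)) - 1
  npad <- 3 * ord
  if (n <= npad)
    stop("input too short for stable zero-phase filtering (need > ",
         npad, " samples, got ", n, ")")
  if (!is.null(flt$sos)) {
    sos <- t(vapply(flt$sos, function(s) c(s$b, s$a), numeric(6)))
    y <- sos_filtfilt_cpp(x, sos, npad)
  } else {
    pre <- 2 * x[rep(1, npad), , drop = FALSE] -
      x[(npad + 1):2, , drop = FALSE]
    post <- 2 * x[rep(n, npad), , drop = FALSE] -
      x[(n - 1):(n - npad), , drop = FALSE]
    xp <- rbind(pre, x, post)
    y <- iir_filter(xp, flt$b, flt$a)
    y <- y[nrow(y):1, , drop = FALSE]
    y <- iir_filter(y, flt$b, flt$a)
    y <- y[nrow(y):1, , drop = FALSE]
    y <- y[(npad + 1):(npad + n), , drop = FALSE]
  }
  if (vec) drop(y) else y
}

#' Welch power spectral density
#'
#' Hann-windowed segment averaging with 50% overlap; density scaling so
#' that \code{sum(psd) * df} approximates signal variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate Hz.
#' @param nperseg segment length in samples.
#' @return list with \code{freq} (Hz) and \code{psd} (power / Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), fs)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)
  u <- sum(w^2)
  nfreq <- floor(nperseg / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * w
    sp <- Mod(stats::fft(seg))^2
    acc <- acc + sp[1:nfreq]
  }
  psd <- acc / (length(starts) * u * fs)
  ## one-sided: double everything but DC (and Nyquist when nperseg even)
  dbl <- 2:(nfreq - if (nperseg %% 2 == 0) 1 else 0)
  psd[dbl] <- 2 * psd[dbl]
  list(freq = seq(0, nfreq - 1) * fs / nperseg, psd = psd)
}

#' Band power from a Welch spectrum
#' @param x numeric vector; @param fs Hz; @param band c(low, high) Hz.
#' @param nperseg Welch segment length.
#' @return integrated power in the band (same units as variance of x).
#' @export
band_power <- function(x, fs, band, nperseg = min(length(x), fs)) {
  sp <- welch_psd(x, fs, nperseg)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  df <- sp$freq[2] - sp$freq[1]
  sum(sp$psd[sel]) * df
}

#' Pink (1/f) noise
#'
#' Spectral-shaping generator: white Gaussian noise is coloured in the
#' frequency domain with a 1/sqrt(f) amplitude profile and rescaled to the
#' requested RMS.  Uses the current R random number stream.
#'
#' @param n samples; @param fs sampling rate Hz; @param rms target RMS.
#' @export
pink_noise <- function(n, fs, rms = 1) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror to the negative axis
  g <- ifelse(f < fs / n, 0, 1 / sqrt(pmax(f, fs / n)))
  x <- Re(stats::fft(sp * g, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal, computed in the frequency
#' domain.  Unlike plain rectification this removes the intra-cycle
#' oscillation of a band-limited transient, leaving one hump per event.
#'
#' @param x numeric vector.
#' @return non-negative envelope, same length.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else h[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Band-limited Gaussian noise (narrow-band oscillation surrogate)
#'
#' White noise bandpass-filtered to the requested band and scaled to the
#' requested RMS; serves as an amplitude- and phase-irregular rhythm.
#'
#' @param n samples; @param fs Hz; @param band c(low, high) Hz;
#' @param rms target RMS.
#' @export
narrowband_noise <- function(n, fs, band, rms = 1) {
  flt <- butter_bandpass(band[1], band[2], fs, order = 4)
  x <- filtfilt(stats::rnorm(n), flt)
  x * rms / stats::sd(x)
}
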