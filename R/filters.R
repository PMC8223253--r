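# Butterworth band-pass design (bilinear transform) and zero-phase filtering.
# No signal-processing package is available in the target library, so the
# classical design path is implemented here and checked against frozen
# reference coefficients in the tests.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Butterworth band-pass filter coefficients
#'
#' Designs a digital band-pass Butterworth filter of the given analog
#' prototype order via the lowpass-to-bandpass transform and the bilinear
#' transform (so the final transfer function has order `2 * order`).
#'
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Analog lowpass prototype order (default 4).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  stopifnot(low > 0, high > low, fs > 0, order >= 1)
  if (high >= fs / 2)
    stop("band edge at or above Nyquist: high = ", high, " Hz, fs = ", fs)
  # pre-warped analog edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # lowpass -> bandpass: each prototype pole yields two poles
  poles <- c(vapply(proto, function(p) {
    d <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
    (p * bw + d) / 2
  }, complex(1)), vapply(proto, function(p) {
    d <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
    (p * bw - d) / 2
  }, complex(1)))
  zeros <- rep(0 + 0i, order)
  gain <- bw^order
  # bilinear transform
  fs2 <- 2 * fs
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)
  gain_z <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zz <- c(zz, rep(-1 + 0i, length(poles) - length(zeros)))
  b <- Re(poly_from_roots(zz)) * gain_z
  a <- Re(poly_from_roots(zp))
  list(b = b / a[1], a = a / a[1])
}

# steady-state initial filter state (scaled by the first sample on use),
# removing start-up transients in filtfilt
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  # companion matrix of a (direct form II transposed state update)
  A <- rbind(-a[-1], cbind(diag(1, n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forward and backward with odd-reflection padding and
#' steady-state initial conditions, giving zero phase distortion and squared
#' magnitude response.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal.
#' @param padlen Reflection pad length; default `3 * (max(length(a),
#'   length(b)) - 1)`, capped at `length(x) - 1`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  ntaps <- max(length(a), length(b))
  if (is.null(padlen)) padlen <- 3 * (ntaps - 1)
  padlen <- min(padlen, n - 1)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  zi <- filter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}

#' Band-pass filter a signal into an HFO band
#'
#' Zero-phase 4th-order Butterworth band-pass (8th order after the band
#' transform, applied forward-backward). Stop-band attenuation one octave
#' outside the band exceeds 40 dB; pass-band ripple is below 1 dB.
#'
#' @param x Numeric signal (microvolts).
#' @param band An [hfo_band()] object or band name.
#' @param fs Sampling rate (Hz).
#' @param order Prototype order, default 4.
#' @return Filtered signal.
#' @examples
#' fs <- 1000
#' t <- seq(0, 1, by = 1 / fs)
#' x <- sin(2 * pi * 60 * t)
#' y <- bandpass(x, "gamma", fs)
#' @export
bandpass <- function(x, band, fs, order = 4) {
  if (is.character(band)) band <- hfo_band(band)
  if (band$high >= fs / 2)
    stop("band '", band$name, "' reaches Nyquist at fs = ", fs)
  coef <- butter_bandpass(band$low, band$high, fs, order = order)
  # long reflection pad: narrow-band IIR transients outlast 3*(ntaps-1)
  filtfilt(coef$b, coef$a, x, padlen = min(length(x) - 1, round(fs / 2)))
}

#' Analytic-signal envelope
#'
#' Magnitude of the Hilbert analytic signal, computed by FFT.
#'
#' @param x Numeric signal.
#' @return Envelope, same length as `x`.
#' @export
envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Welch power spectral density
#'
#' Hann-windowed segment-averaged periodogram with 50% overlap, density
#' scaling (power per Hz).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nperseg Segment length (default 1024 or `length(x)` if shorter).
#' @return data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 1024) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg))
  starts <- seq(1, n - nperseg + 1, by = step)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(fft(seg))^2 / (fs * sum(w^2))
    P <- P[seq_len(nf)]
    # one-sided
    if (nperseg %% 2 == 0) P[2:(nf - 1)] <- 2 * P[2:(nf - 1)]
    else P[2:nf] <- 2 * P[2:nf]
    acc <- acc + P
  }
  data.frame(freq = (seq_len(nf) - 1) * fs / nperseg,
             psd = acc / length(starts))
}
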