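#' Zero-phase band-pass filter
#'
#' Filters a single-channel trace with a zero-phase frequency-domain
#' band-pass.  The transfer function is 1 inside `[f_lo, f_hi]`, 0 in the
#' stop bands, with raised-cosine transitions of width `trans_lo` /
#' `trans_hi` Hz.  Because the response is real and even, the filter has
#' exactly zero phase (no group delay), and the stop-band attenuation is
#' far in excess of 40 dB.  The signal is reflection-padded before the
#' transform so circular wrap-around does not leak across the epoch edges.
#'
#' @param x numeric vector, the signal (uV).
#' @param f_lo,f_hi pass-band edges in Hz; `f_lo < f_hi <= fs/2`.
#' @param fs sampling rate in Hz.
#' @param trans_lo,trans_hi transition-band widths in Hz.  Defaults: a
#'   quarter of `f_lo` (capped at 20 Hz) below, 20 Hz above (capped at the
#'   headroom to Nyquist).
#' @return filtered vector, same length as `x`.
#' @export
bandpass_zero_phase <- function(x, f_lo, f_hi, fs,
                                trans_lo = NULL, trans_hi = NULL) {
  stopifnot(is.numeric(x), length(x) > 1, fs > 0)
  if (!(f_lo < f_hi) || f_hi > fs / 2)
    stop("infeasible band: need f_lo < f_hi <= fs/2 (got ",
         f_lo, "-", f_hi, " Hz at fs ", fs, ")")
  if (is.null(trans_lo)) trans_lo <- min(f_lo / 4, 20)
  if (is.null(trans_hi)) trans_hi <- min(20, (fs / 2 - f_hi))
  n <- length(x)
  # reflect-pad one second (or the signal length) each side
  npad <- min(n - 1L, as.integer(fs))
  xp <- c(rev(x[2:(npad + 1L)]), x, rev(x[(n - npad):(n - 1L)]))
  np <- length(xp)
  freqs <- (seq_len(np) - 1L) / np * fs
  freqs <- pmin(freqs, fs - freqs)           # two-sided frequency axis
  h <- raised_cosine_response(freqs, f_lo, f_hi, trans_lo, trans_hi)
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / np
  y[(npad + 1L):(npad + n)]
}

# Raised-cosine band-pass magnitude response evaluated at |f|.
raised_cosine_response <- function(f, f_lo, f_hi, trans_lo, trans_hi) {
  h <- numeric(length(f))
  pass <- f >= f_lo & f <= f_hi
  h[pass] <- 1
  if (trans_lo > 0) {
    lo <- f >= (f_lo - trans_lo) & f < f_lo
    h[lo] <- 0.5 * (1 + cos(pi * (f_lo - f[lo]) / trans_lo))
  }
  if (trans_hi > 0) {
    hi <- f > f_hi & f <= (f_hi + trans_hi)
    h[hi] <- 0.5 * (1 + cos(pi * (f[hi] - f_hi) / trans_hi))
  }
  h
}

#' Zero-phase low-pass / high-pass variants used internally
#' @noRd
lowpass_zero_phase <- function(x, f_hi, fs, trans_hi = NULL) {
  bandpass_zero_phase(x, 0, f_hi, fs, trans_lo = 0, trans_hi = trans_hi)
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)`; its modulus is the
#' instantaneous amplitude envelope and its argument the instantaneous
#' phase.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Amplitude envelope of a band-passed trace
#' @param x signal, `f_lo`/`f_hi` band edges (Hz), `fs` sampling rate.
#' @return non-negative envelope vector.
#' @export
band_envelope <- function(x, f_lo, f_hi, fs) {
  Mod(analytic_signal(bandpass_zero_phase(x, f_lo, f_hi, fs)))
}

# centred moving RMS with window of w samples (w odd preferred); edges use
# the truncated window so output length equals input length.
moving_rms <- function(x, w) {
  stopifnot(w >= 1)
  sq <- x^2
  k <- rep(1, w)
  s <- stats::filter(sq, k, sides = 2)
  cnt <- stats::filter(rep(1, length(x)), k, sides = 2)
  # fill truncated edges explicitly
  half <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in which(is.na(s))) {
    lo <- max(1L, i - half); hi <- min(n, i + w - 1L - half)
    s[i] <- sum(sq[lo:hi]); cnt[i] <- hi - lo + 1L
  }
  sqrt(as.numeric(s) / as.numeric(cnt))
}

# centred moving sum of |diff(x)| over w consecutive first differences
# (short line length).  L[i] = sum_{j=i-w+1..i? } -- we centre the window on
# the sample: L[i] = sum of |x[j]-x[j-1]| for j in (i-half+1)..(i+half)
moving_line_length <- function(x, w) {
  d <- c(0, abs(diff(x)))
  k <- rep(1, w)
  s <- stats::filter(d, k, sides = 2)
  half <- (w - 1L) %/% 2L
  n <- length(x)
  for (i in which(is.na(s))) {
    lo <- max(1L, i - half); hi <- min(n, i + w - 1L - half)
    s[i] <- sum(d[lo:hi])
  }
  as.numeric(s)
}
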