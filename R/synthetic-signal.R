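#' Specification of a synthetic iEEG channel background
#'
#' Describes one 1/f^alpha Gaussian background trace emulating an
#' interictal slow-wave-sleep iEEG epoch (default: 5 minutes at 1000 Hz).
#'
#' @param duration_s epoch duration in seconds (> 0; default 300).
#' @param fs sampling rate in Hz (>= 600 so the 80-300 Hz band is
#'   representable; default 1000).
#' @param noise_sd marginal standard deviation of the background in uV
#'   (default 20).
#' @param spectral_exponent alpha of the 1/f^alpha power spectrum
#'   (default 1).
#' @param seed integer RNG seed.
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(duration_s = 300, fs = 1000, noise_sd = 20,
                        spectral_exponent = 1, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid spec: duration_s must be > 0")
  if (!is.numeric(fs) || fs < 600)
    stop("invalid spec: fs must be >= 600 Hz (2 x 300 Hz analysis band)")
  structure(list(duration_s = duration_s, fs = fs, noise_sd = noise_sd,
                 spectral_exponent = spectral_exponent,
                 seed = as.integer(seed)),
            class = "signal_spec")
}

#' Generate a 1/f^alpha Gaussian background trace
#'
#' Shapes white Gaussian noise in the frequency domain so that power
#' falls off as 1/f^alpha, then rescales to `noise_sd` and removes the
#' mean.  Deterministic given the seed carried by the [signal_spec()].
#'
#' @param spec a [signal_spec()].
#' @return numeric vector of `duration_s * fs` samples (uV), zero mean.
#' @export
make_background <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  n <- round(spec$duration_s * spec$fs)
  w <- withr::with_seed(spec$seed, stats::rnorm(n))
  if (spec$spectral_exponent != 0) {
    W <- stats::fft(w)
    f <- (seq_len(n) - 1) / n * spec$fs
    f <- pmin(f, spec$fs - f)
    f[1] <- Inf                       # kill DC
    g <- 1 / f^(spec$spectral_exponent / 2)
    w <- Re(stats::fft(W * g, inverse = TRUE)) / n
  }
  w <- w - mean(w)
  w * (spec$noise_sd / stats::sd(w))
}

#' Describe an event planted into a synthetic trace
#'
#' @param kind one of `"oscillation"`, `"sharp_transient"`,
#'   `"spike_wave_complex"`.
#' @param t0 onset in seconds from epoch start.
#' @param f0 oscillation centre frequency in Hz (oscillations: 80-300).
#' @param n_cycles number of cycles of the burst (oscillations: >= 4;
#'   default 8).
#' @param amplitude peak amplitude in uV.
#' @param width_ms transient width in milliseconds (sharp transients).
#' @return a `planted_event` object.
#' @export
planted_event <- function(kind = c("oscillation", "sharp_transient",
                                   "spike_wave_complex"),
                          t0, f0 = NA_real_, n_cycles = 8, amplitude = 50,
                          width_ms = 30) {
  kind <- match.arg(kind)
  if (kind == "oscillation") {
    if (!is.finite(f0) || f0 < 80 || f0 > 300)
      stop("oscillation f0 must be within 80-300 Hz")
    if (n_cycles < 4) stop("oscillation needs n_cycles >= 4")
  }
  structure(list(kind = kind, t0 = t0, f0 = f0, n_cycles = n_cycles,
                 amplitude = amplitude, width_ms = width_ms),
            class = "planted_event")
}

event_duration_s <- function(event) {
  switch(event$kind,
         oscillation = event$n_cycles / event$f0,
         sharp_transient = 2 * event$width_ms / 1000,
         spike_wave_complex = 0.4)
}

check_bounds <- function(event, n, fs) {
  i0 <- round(event$t0 * fs) + 1L
  dur <- event_duration_s(event)
  i1 <- i0 + round(dur * fs) - 1L
  if (i0 < 1L || i1 > n)
    stop("event at t0=", event$t0, " s extends outside the epoch")
  c(i0, i1)
}

#' Add a Hann-tapered oscillatory burst to a trace
#'
#' The burst is `n_cycles` of a sinusoid at `f0` under a full-length Hann
#' window; only samples inside the burst window change.  This is the
#' canonical "true HFO": a spontaneous oscillation standing out in
#' amplitude from the background.
#'
#' @param x signal vector (uV).
#' @param event a [planted_event()] with kind `"oscillation"`.
#' @param fs sampling rate Hz.
#' @return modified signal.
#' @export
inject_oscillation <- function(x, event, fs) {
  stopifnot(inherits(event, "planted_event"), event$kind == "oscillation")
  idx <- check_bounds(event, length(x), fs)
  i <- idx[1]:idx[2]
  m <- length(i)
  t <- (seq_len(m) - 1) / fs
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
  x[i] <- x[i] + event$amplitude * hann * sin(2 * pi * event$f0 * t)
  x
}

#' Add a non-oscillatory sharp transient (false-ripple generator)
#'
#' Injects a sharply-contoured biphasic spike: a piecewise-linear
#' deflection of total width `2 * width_ms` whose corners give the
#' power-law spectral tail of real epileptiform transients.  The trace
#' contains no sustained oscillation, but high-pass filtering at 80 Hz
#' rings at the corners and produces a ripple-like deflection -- the
#' planted ground-truth negative for the time-frequency verifier.
#'
#' @inheritParams inject_oscillation
#' @export
inject_sharp_transient <- function(x, event, fs) {
  stopifnot(inherits(event, "planted_event"), event$kind == "sharp_transient")
  idx <- check_bounds(event, length(x), fs)
  i <- idx[1]:idx[2]
  m <- length(i)
  tc <- (seq_len(m) - (m + 1) / 2) / fs        # centred time axis (s)
  tau <- event$width_ms / 1000 / 3
  # biphasic exponential cusp: single sharp zero-crossing, monotone
  # power-law spectral tail (no sustained oscillation at any frequency)
  g <- -sign(tc) * exp(-abs(tc) / tau)
  x[i] <- x[i] + event$amplitude * g
  x
}

#' Synthesize an epoch with slow-wave phase to HFO amplitude coupling
#'
#' Builds `slow + A0 * (1 + m * cos(phase_slow)) * cos(2*pi*carrier_f*t)
#' + background`.  The analytic mean vector length of (HFO amplitude,
#' slow-wave phase) of the noiseless construction is `A0 * m / 2`, giving
#' a closed-form target for the modulation index.
#'
#' @param spec a [signal_spec()]; set `noise_sd = 0` for the noiseless
#'   closed-form fixture.
#' @param slow_f slow-wave frequency, 3-4 Hz.
#' @param mod_depth coupling depth m in `[0, 1]`.
#' @param carrier_f HFO carrier frequency (Hz).
#' @param carrier_amp A0, carrier amplitude in uV.
#' @param slow_amp slow-wave amplitude in uV (default 100).
#' @return numeric signal vector.
#' @export
make_coupled_epoch <- function(spec, slow_f = 3.5, mod_depth = 0.5,
                               carrier_f = 120, carrier_amp = 10,
                               slow_amp = 100) {
  stopifnot(inherits(spec, "signal_spec"))
  if (slow_f < 3 || slow_f > 4) stop("invalid spec: slow_f must be in [3, 4] Hz")
  if (mod_depth < 0 || mod_depth > 1) stop("invalid spec: mod_depth must be in [0, 1]")
  n <- round(spec$duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  phi <- 2 * pi * slow_f * t
  sig <- slow_amp * cos(phi) +
    carrier_amp * (1 + mod_depth * cos(phi)) * cos(2 * pi * carrier_f * t)
  if (spec$noise_sd > 0) sig <- sig + make_background(spec)
  sig
}
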