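#' Extract the phase/amplitude pair for phase-amplitude coupling
#'
#' Phase is the instantaneous angle of the analytic signal of the
#' 3-4 Hz band-passed trace; amplitude is the envelope of the
#' `amp_floor_f`-300 Hz band-passed trace.  Both filters are zero-phase.
#' A warning flag is attached when the epoch holds fewer than ten
#' slow-wave cycles.
#'
#' @param x single-channel signal (uV).
#' @param fs sampling rate (Hz).
#' @param amp_floor_f HFO-band floor: 80, 150 or 250 (Hz).
#' @param slow_band slow-wave band, default `c(3, 4)` Hz.
#' @return a `pac_series` list: `phase` (radians, (-pi, pi]),
#'   `amplitude` (uV), `fs`, `short_epoch` flag.
#' @export
extract_pac_series <- function(x, fs, amp_floor_f = 80, slow_band = c(3, 4)) {
  if (!amp_floor_f %in% c(80, 150, 250))
    stop("amp_floor_f must be one of 80, 150, 250 Hz")
  short_epoch <- length(x) / fs < 10 / slow_band[1]
  if (short_epoch)
    warning("epoch shorter than 10 slow-wave cycles; phase estimates unstable")
  slow <- bandpass_zero_phase(x, slow_band[1], slow_band[2], fs,
                              trans_lo = 1, trans_hi = 1)
  phase <- Arg(analytic_signal(slow))
  amp <- band_envelope(x, amp_floor_f, 300, fs)
  structure(list(phase = phase, amplitude = amp, fs = fs,
                 short_epoch = short_epoch),
            class = "pac_series")
}

#' Modulation index (mean vector length)
#'
#' `MI = | mean( A(t) * exp(i * phi(t)) ) |` -- the modulus of the
#' amplitude-weighted mean phase vector, in amplitude units (uV).  For a
#' carrier of amplitude `A0` modulated in depth `m` by the slow-wave
#' phase, the analytic value is `A0 * m / 2`.
#'
#' @param pac a `pac_series` from [extract_pac_series()].
#' @return non-negative scalar MI (uV); 0 for an all-zero amplitude.
#' @export
modulation_index <- function(pac) {
  stopifnot(inherits(pac, "pac_series"))
  if (!length(pac$amplitude)) stop("empty series")
  Mod(mean(pac$amplitude * exp(1i * pac$phase)))
}

#' Per-channel MI for one band floor
#' @inheritParams extract_pac_series
#' @return scalar MI (uV).
#' @export
channel_mi <- function(x, fs, amp_floor_f = 80) {
  modulation_index(extract_pac_series(x, fs, amp_floor_f))
}
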