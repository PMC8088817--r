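#' Morlet time-frequency map around a detected event
#'
#' Computes a continuous Morlet wavelet transform (default 7 cycles, 30
#' log-spaced frequencies from 10 to 300 Hz) of the *unfiltered* trace in
#' a window spanning the event plus `pad_s` of flank on each side.  Power
#' is z-scored per frequency row against the flanking padding, so a
#' genuine oscillation appears as an isolated high-z blob at its
#' frequency while the high-pass tail of a sharp transient remains
#' anchored to the low-frequency ridge.
#'
#' @param x unfiltered single-channel signal (uV).
#' @param fs sampling rate (Hz).
#' @param t_start,t_end event window in seconds (half-open).
#' @param pad_s flank padding per side in seconds (default 0.25).
#' @param freqs analysis frequencies (Hz); default 30 log-spaced 10-300.
#' @param n_cycles Morlet cycles (default 7).
#' @return a `tf_map` object: `power` (frequency x time z-scores),
#'   `raw_power`, `freqs`, `times` (s, epoch clock), `event` window, and
#'   an `edge_flag` set when reflection padding was needed.
#' @export
tf_map <- function(x, fs, t_start, t_end, pad_s = 0.25,
                   freqs = exp(seq(log(10), log(300), length.out = 30)),
                   n_cycles = 7) {
  stopifnot(t_end > t_start)
  n <- length(x)
  i0 <- floor(t_start * fs) + 1L
  i1 <- min(n, ceiling(t_end * fs))
  pad <- round(pad_s * fs)
  lo <- i0 - pad; hi <- i1 + pad
  edge_flag <- lo < 1L || hi > n
  seg <- x[max(1L, lo):min(n, hi)]
  if (lo < 1L) seg <- c(rev(seg[2:(1L - lo + 1L)]), seg)
  if (hi > n) seg <- c(seg, rev(seg[(length(seg) - (hi - n)):(length(seg) - 1L)]))
  m <- length(seg)
  # FFT-based complex Morlet convolution, one row per frequency
  segF <- stats::fft(seg - mean(seg))
  fax <- (seq_len(m) - 1) / m * fs
  pow <- matrix(0, nrow = length(freqs), ncol = m)
  for (k in seq_along(freqs)) {
    f0 <- freqs[k]
    sigma_f <- f0 / n_cycles
    # Gaussian in frequency (analytic Morlet): keep positive frequencies
    H <- exp(-0.5 * ((fax - f0) / sigma_f)^2)
    H[fax > fs / 2] <- 0
    w <- stats::fft(segF * H, inverse = TRUE) / m
    pow[k, ] <- Mod(w)^2
  }
  times <- (seq(lo, hi) - 1) / fs
  ev_cols <- times >= t_start & times < t_end
  flank <- !ev_cols
  mu <- rowMeans(pow[, flank, drop = FALSE])
  sdev <- apply(pow[, flank, drop = FALSE], 1, stats::sd)
  sdev[sdev <= 0] <- Inf
  z <- sweep(sweep(pow, 1, mu), 1, sdev, `/`)
  structure(list(power = z, raw_power = pow, freqs = freqs, times = times,
                 event = c(t_start, t_end), ev_cols = ev_cols,
                 edge_flag = edge_flag, method = "morlet"),
            class = "tf_map")
}

#' Label an event from its time-frequency signature
#'
#' Operationalizes blob-based verification: the event-time spectral
#' profile (per-frequency maximum z inside the event window) must show a
#' local maximum at >= 80 Hz that is *sustained* through the event window
#' (its row's mean z reaches `act_thr` -- a chance maximum of the z
#' series does not) and *isolated* from the low-frequency
#' ridge -- the z profile between the low-frequency maximum and the
#' high-frequency peak must dip below `trough_frac` of the peak.  An
#' isolated blob is labelled `vHFO_80_150` / `vHFO_150_250` /
#' `vHFO_250_300` by its peak frequency.  A high-frequency tail that
#' stays attached to a dominant low-frequency transient is a `Spike`
#' (the high-pass filtering artefact); broadband activation without a
#' low-frequency anchor is `Artifact`; everything else (including blobs
#' touching the ridge without a clear trough) is `Others`.
#'
#' @param map a [tf_map()].
#' @param band_floor detection band floor (Hz); a blob below it still
#'   verifies if within 80-300.
#' @param act_thr z threshold for "active" power (default 3): the
#'   high-frequency power must stand out from the flanks in time.
#' @param trough_frac when the activation is connected to the ridge but
#'   the raw-power profile still dips below this fraction of the peak,
#'   the blob touches the ridge and the conservative label Others is
#'   used (default 0.5).
#' @param broadband_frac fraction of >= 80 Hz rows active beyond which an
#'   unanchored activation is called broadband (default 0.8).
#' @return one of `"vHFO_80_150"`, `"vHFO_150_250"`, `"vHFO_250_300"`,
#'   `"Spike"`, `"Artifact"`, `"Others"`.
#' @export
classify_event <- function(map, band_floor = 80, act_thr = 3,
                           trough_frac = 0.5, broadband_frac = 0.8) {
  stopifnot(inherits(map, "tf_map"))
  prof_z <- apply(map$power[, map$ev_cols, drop = FALSE], 1, max)
  prof_m <- rowMeans(map$power[, map$ev_cols, drop = FALSE])
  prof_r <- apply(map$raw_power[, map$ev_cols, drop = FALSE], 1, max)
  f <- map$freqs
  hi <- f >= 80
  lo <- f < 80
  peak_z <- max(prof_z[hi])
  if (!is.finite(peak_z) || peak_z < act_thr) return("Others")
  i_star <- which(hi)[which.max(prof_z[hi])]
  # a genuine blob is *sustained* through the event window, not a chance
  # maximum of the z series: the peak row's mean z must also be active
  # (background rows top out near 1-2 by the max statistic alone)
  if (prof_m[i_star] < act_thr) return("Others")
  f_star <- f[i_star]
  # the anchor must be genuinely low-frequency activity: exclude the
  # Morlet skirt of the whole 80-300 Hz analysis range (3 sigma_f at the
  # 80 Hz edge, i.e. rows above 80 * (1 - 3/7)), so broadband
  # high-frequency energy cannot masquerade as its own anchor, and demand
  # a markedly stronger excursion than the noise ceiling of a
  # max-over-time statistic
  anchor <- f < 80 * (1 - 3 / 7)
  anchor_thr <- 2 * act_thr
  low_peak_z <- if (any(anchor)) max(prof_z[anchor]) else -Inf
  if (low_peak_z < anchor_thr) {
    # no low-frequency anchor: band-limited blob or broadband artifact
    # (broadband = active across the whole 80-300 Hz range, ends included)
    if (mean(prof_z[hi] >= act_thr) >= broadband_frac &&
        prof_z[which(hi)[1]] >= act_thr &&
        prof_z[length(f)] >= act_thr) return("Artifact")
    return(vhfo_band_label(f_star))
  }
  # anchored: a genuine oscillation shows an activation gap between the
  # low-frequency ridge and its blob; a transient drives the whole
  # column so the z-activation stays connected from the anchor upward
  i_low <- which(anchor)[which.max(prof_z[anchor])]
  between <- seq_len(length(f)) > i_low & seq_len(length(f)) < i_star
  if (!any(between)) return("Spike")
  z_trough <- min(prof_z[between])
  if (z_trough < act_thr) return(vhfo_band_label(f_star))
  # connected ridge: isolated raw-power maxima riding on it are ambiguous
  ratio <- min(prof_r[between]) / prof_r[i_star]
  if (ratio < trough_frac) return("Others")
  "Spike"
}

vhfo_band_label <- function(f_star) {
  if (f_star < 80) return("Others")
  if (f_star < 150) "vHFO_80_150"
  else if (f_star < 250) "vHFO_150_250"
  else "vHFO_250_300"
}

#' Verify every event in a detection table
#'
#' Runs [tf_map()] + [classify_event()] per event and fills the `label`
#' column.
#'
#' @param events detector event table.
#' @param x unfiltered signal the events were detected on.
#' @param fs sampling rate (Hz).
#' @param ... forwarded to [tf_map()] and [classify_event()].
#' @return the event table with labels set.
#' @export
verify_events <- function(events, x, fs, ...) {
  if (nrow(events) == 0) return(events)
  events$label <- vapply(seq_len(nrow(events)), function(i) {
    map <- tf_map(x, fs, events$t_start[i], events$t_end[i])
    classify_event(map, events$band_floor[i], ...)
  }, "")
  events
}

vhfo_labels_at_or_above <- function(band_floor) {
  all_lab <- c(vHFO_80_150 = 80, vHFO_150_250 = 150, vHFO_250_300 = 250)
  names(all_lab)[all_lab >= band_floor]
}

#' Verified-HFO rate per 5 minutes
#'
#' Counts only events whose verified label is a vHFO sub-band at or above
#' `band_floor` (nesting: vHFO>80 includes the 80-150, 150-250 and
#' 250-300 sub-bands; vHFO>150 the upper two; vHFO>250 the last).
#'
#' @param events labelled event table; unverified events are an error.
#' @param band_floor 80, 150 or 250 (Hz).
#' @param epoch_duration_s epoch length (s).
#' @return vHFO events per 5 min.
#' @export
verified_rate <- function(events, band_floor, epoch_duration_s) {
  stopifnot(epoch_duration_s > 0)
  if (nrow(events) == 0) return(0)
  if (any(events$label == "unverified"))
    stop("events must be verified before computing a vHFO rate")
  sum(events$label %in% vhfo_labels_at_or_above(band_floor)) *
    300 / epoch_duration_s
}
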