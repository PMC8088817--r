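#' Detector parameter bundle
#'
#' Holds the shared band definition and the per-detector thresholds.  The
#' analysis bands are f_lo-300 Hz for f_lo in {80, 150, 250}.  Threshold
#' defaults: short-time energy (STE) flags runs of the moving RMS greater
#' than 5 SDs above the epoch RMS mean containing more than 6 rectified
#' peaks above 3 SDs; short line length (SLL) uses the 97.5th percentile
#' of the empirical line-length distribution; the Hilbert (HIL) detector
#' uses envelope excursions above mean + 5 SD within 5-s analysis blocks;
#' the Montreal (MNI) detector uses the 99.9999th percentile of the
#' baseline energy distribution when a baseline is present and otherwise
#' the per-minute 95th percentile with iterative re-detection.
#'
#' @param band_floor lower band edge, one of 80, 150, 250 (Hz).
#' @param band_ceiling upper band edge (Hz, fixed 300 by default).
#' @param rms_window_ms STE moving-RMS window (ms).
#' @param rms_threshold_sd STE RMS threshold in SDs above the mean.
#' @param min_peaks STE requires strictly more than this many rectified
#'   peaks above `peak_threshold_sd`.
#' @param peak_threshold_sd STE rectified-peak threshold (SDs).
#' @param min_duration_ms minimum event duration (ms), all detectors.
#' @param ll_window_ms SLL line-length window; default one cycle at
#'   `band_floor`.
#' @param ecdf_percentile SLL threshold percentile.
#' @param envelope_threshold_sd HIL envelope threshold (SDs).
#' @param analysis_window_s HIL block length (s).
#' @param baseline_percentile MNI baseline-branch percentile.
#' @param no_baseline_percentile MNI no-baseline-branch percentile.
#' @param segment_s MNI no-baseline re-detection segment length (s).
#' @param baseline_segment_s MNI baseline-candidate segment length (s).
#' @param min_baseline_frac minimum fraction of the epoch that must
#'   qualify as baseline for the baseline branch.
#' @param flatness_floor spectral-flatness floor below which a segment is
#'   considered oscillation-dominated (hence not baseline).
#' @param mni_iterations fixed iteration count of the no-baseline branch.
#' @param mni_rms_window_ms MNI energy window (ms).
#' @param merge_gap_ms supra-threshold runs closer than this are merged
#'   before the duration/peak criteria.
#' @return a `detector_params` list.
#' @export
detector_params <- function(band_floor = 80, band_ceiling = 300,
                            rms_window_ms = 3, rms_threshold_sd = 5,
                            min_peaks = 6, peak_threshold_sd = 3,
                            min_duration_ms = 6,
                            ll_window_ms = 1000 / band_floor,
                            ecdf_percentile = 97.5,
                            envelope_threshold_sd = 5, analysis_window_s = 5,
                            baseline_percentile = 99.9999,
                            no_baseline_percentile = 95,
                            segment_s = 60, baseline_segment_s = 1,
                            min_baseline_frac = 0.05, flatness_floor = 0.25,
                            mni_iterations = 5, mni_rms_window_ms = 10,
                            merge_gap_ms = 10) {
  if (!band_floor %in% c(80, 150, 250))
    stop("band_floor must be one of 80, 150, 250 Hz")
  stopifnot(ecdf_percentile > 0, ecdf_percentile < 100,
            baseline_percentile > 0, baseline_percentile < 100,
            no_baseline_percentile > 0, no_baseline_percentile < 100)
  as.list(environment())
}

# maximal runs of TRUE -> matrix with columns start, end (sample indices)
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# merge runs separated by fewer than gap samples
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap)
      out[nrow(out), "end"] <- runs[i, "end"]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

# strict-rise peak rule: x[i] > x[i-1] and x[i] >= x[i+1]; a plateau
# counts once (at its first sample).
find_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# dominant frequency of a segment via the periodogram
segment_peak_freq <- function(seg, fs) {
  n <- length(seg)
  if (n < 4) return(NA_real_)
  p <- Mod(stats::fft(seg - mean(seg)))^2
  half <- 2:(floor(n / 2) + 1)
  f <- (half - 1) / n * fs
  f[which.max(p[half])]
}

events_frame <- function(runs, x, fs, detector, band_floor,
                         channel_id = NA_character_) {
  if (is.null(runs) || nrow(runs) == 0) return(empty_events())
  data.frame(
    channel_id = channel_id,
    t_start = (runs[, "start"] - 1) / fs,
    t_end = runs[, "end"] / fs,
    detector = detector,
    band_floor = band_floor,
    peak_freq = vapply(seq_len(nrow(runs)), function(i)
      segment_peak_freq(x[runs[i, "start"]:runs[i, "end"]], fs), 0),
    label = "unverified",
    stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(channel_id = character(), t_start = numeric(),
             t_end = numeric(), detector = character(),
             band_floor = numeric(), peak_freq = numeric(),
             label = character(), stringsAsFactors = FALSE)
}

#' Short-time energy (STE) HFO detector
#'
#' Flags segments whose moving RMS exceeds the epoch RMS mean by more
#' than `rms_threshold_sd` SDs for at least `min_duration_ms`, and which
#' contain strictly more than `min_peaks` rectified peaks above
#' `peak_threshold_sd` SDs of the rectified band-passed trace.
#' Supra-threshold runs closer than `merge_gap_ms` are merged before the
#' duration and peak criteria.
#'
#' @param x raw single-channel signal (uV); the band-pass is applied
#'   internally.
#' @param fs sampling rate (Hz).
#' @param params a [detector_params()].
#' @param channel_id optional label copied into the event table.
#' @return data.frame of events (`t_start`/`t_end` in seconds, half-open
#'   intervals).
#' @export
detect_ste <- function(x, fs, params = detector_params(),
                       channel_id = NA_character_) {
  w <- max(1L, round(params$rms_window_ms / 1000 * fs))
  if (length(x) < w) stop("epoch shorter than the RMS window")
  xb <- bandpass_zero_phase(x, params$band_floor, params$band_ceiling, fs)
  r <- moving_rms(xb, w)
  thr <- mean(r) + params$rms_threshold_sd * stats::sd(r)
  runs <- logical_runs(r > thr)
  if (nrow(runs) == 0) return(empty_events())
  runs <- merge_runs(runs, round(params$merge_gap_ms / 1000 * fs))
  keep_dur <- (runs[, "end"] - runs[, "start"] + 1L) >=
    round(params$min_duration_ms / 1000 * fs)
  runs <- runs[keep_dur, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_events())
  rect <- abs(xb)
  peak_thr <- mean(rect) + params$peak_threshold_sd * stats::sd(rect)
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    seg <- rect[runs[i, "start"]:runs[i, "end"]]
    pk <- find_peaks(seg)
    sum(seg[pk] > peak_thr) > params$min_peaks
  }, TRUE)
  events_frame(runs[keep, , drop = FALSE], xb, fs, "STE",
               params$band_floor, channel_id)
}

#' Short line length (SLL) HFO detector
#'
#' The line-length series is the windowed sum of absolute successive
#' differences of the band-passed trace; events are maximal runs above
#' the 97.5th percentile of its empirical cumulative distribution,
#' subject to merging and the minimum duration.
#'
#' @inheritParams detect_ste
#' @export
detect_sll <- function(x, fs, params = detector_params(),
                       channel_id = NA_character_) {
  w <- max(2L, round(params$ll_window_ms / 1000 * fs))
  if (length(x) < w) stop("epoch shorter than the line-length window")
  xb <- bandpass_zero_phase(x, params$band_floor, params$band_ceiling, fs)
  L <- moving_line_length(xb, w)
  thr <- stats::quantile(L, params$ecdf_percentile / 100, names = FALSE)
  runs <- logical_runs(L > thr)
  if (nrow(runs) == 0) return(empty_events())
  runs <- merge_runs(runs, round(params$merge_gap_ms / 1000 * fs))
  keep <- (runs[, "end"] - runs[, "start"] + 1L) >=
    round(params$min_duration_ms / 1000 * fs)
  events_frame(runs[keep, , drop = FALSE], xb, fs, "SLL",
               params$band_floor, channel_id)
}

#' Hilbert-envelope (HIL) HFO detector
#'
#' Computes the analytic-signal amplitude envelope of the band-passed
#' trace and flags excursions above mean + `envelope_threshold_sd` SD,
#' with the statistics taken within consecutive `analysis_window_s`
#' blocks.
#'
#' @inheritParams detect_ste
#' @export
detect_hil <- function(x, fs, params = detector_params(),
                       channel_id = NA_character_) {
  if (length(x) < 4) stop("epoch too short for envelope analysis")
  xb <- bandpass_zero_phase(x, params$band_floor, params$band_ceiling, fs)
  env <- Mod(analytic_signal(xb))
  n <- length(env)
  block <- max(4L, round(params$analysis_window_s * fs))
  supra <- logical(n)
  starts <- seq(1L, n, by = block)
  for (s in starts) {
    e <- min(n, s + block - 1L)
    seg <- env[s:e]
    thr <- mean(seg) + params$envelope_threshold_sd * stats::sd(seg)
    supra[s:e] <- seg > thr
  }
  runs <- logical_runs(supra)
  if (nrow(runs) == 0) return(empty_events())
  runs <- merge_runs(runs, round(params$merge_gap_ms / 1000 * fs))
  keep <- (runs[, "end"] - runs[, "start"] + 1L) >=
    round(params$min_duration_ms / 1000 * fs)
  events_frame(runs[keep, , drop = FALSE], xb, fs, "HIL",
               params$band_floor, channel_id)
}

# spectral flatness of a segment within the analysis band (geometric over
# arithmetic mean of the periodogram); ~1 for broadband noise, ~0 for a
# sustained sinusoid.
band_spectral_flatness <- function(seg, fs, f_lo, f_hi) {
  n <- length(seg)
  p <- Mod(stats::fft(seg - mean(seg)))^2
  f <- (seq_len(n) - 1) / n * fs
  keep <- f >= f_lo & f <= f_hi
  p <- p[keep]
  p <- p[p > 0]
  if (!length(p)) return(1)
  exp(mean(log(p))) / mean(p)
}

# identify baseline samples: the epoch is cut into baseline_segment_s
# segments; a segment qualifies when its mean line length lies below the
# epoch median line length (quiet) AND its spectral flatness is above
# flatness_floor (not oscillation-dominated).
mni_baseline_mask <- function(xb, fs, params) {
  n <- length(xb)
  d <- c(0, abs(diff(xb)))
  seg_len <- max(2L, round(params$baseline_segment_s * fs))
  starts <- seq(1L, n, by = seg_len)
  ends <- pmin(n, starts + seg_len - 1L)
  seg_ll <- vapply(seq_along(starts), function(i)
    mean(d[starts[i]:ends[i]]), 0)
  med <- stats::median(seg_ll)
  mask <- logical(n)
  for (i in seq_along(starts)) {
    quiet <- seg_ll[i] <= med
    flat <- band_spectral_flatness(xb[starts[i]:ends[i]], fs,
                                   params$band_floor, params$band_ceiling) >=
      params$flatness_floor
    mask[starts[i]:ends[i]] <- quiet && flat
  }
  mask
}

#' Montreal (MNI) percentile HFO detector
#'
#' Computes a moving-RMS energy series of the band-passed trace.  If
#' enough of the epoch qualifies as baseline (quiet, non-oscillatory
#' stretches), events are energy runs above the 99.9999th percentile of
#' the baseline energy distribution.  Without a baseline, the detector
#' falls back to per-minute segments: runs above the segment's 95th
#' energy percentile, re-detected iteratively with detected samples
#' removed from the reference distribution.
#'
#' @inheritParams detect_ste
#' @export
detect_mni <- function(x, fs, params = detector_params(),
                       channel_id = NA_character_) {
  w <- max(1L, round(params$mni_rms_window_ms / 1000 * fs))
  if (length(x) < w) stop("epoch shorter than the energy window")
  xb <- bandpass_zero_phase(x, params$band_floor, params$band_ceiling, fs)
  energy <- moving_rms(xb, w)
  n <- length(energy)
  base <- mni_baseline_mask(xb, fs, params)
  min_dur <- round(params$min_duration_ms / 1000 * fs)
  gap <- round(params$merge_gap_ms / 1000 * fs)
  if (mean(base) >= params$min_baseline_frac) {
    thr <- stats::quantile(energy[base], params$baseline_percentile / 100,
                           names = FALSE)
    supra <- energy > thr
  } else {
    supra <- logical(n)
    seg_len <- max(2L, round(params$segment_s * fs))
    starts <- seq(1L, n, by = seg_len)
    for (s in starts) {
      e <- min(n, s + seg_len - 1L)
      idx <- s:e
      detected <- logical(length(idx))
      for (it in seq_len(params$mni_iterations)) {
        ref <- energy[idx][!detected]
        if (!length(ref)) break
        thr <- stats::quantile(ref, params$no_baseline_percentile / 100,
                               names = FALSE)
        new <- energy[idx] > thr
        if (all(new == detected)) break
        detected <- detected | new
      }
      supra[idx] <- detected
    }
  }
  runs <- logical_runs(supra)
  if (nrow(runs) == 0) return(empty_events())
  runs <- merge_runs(runs, gap)
  keep <- (runs[, "end"] - runs[, "start"] + 1L) >= min_dur
  events_frame(runs[keep, , drop = FALSE], xb, fs, "MNI",
               params$band_floor, channel_id)
}

#' Run one of the four detectors by name
#' @param detector `"STE"`, `"SLL"`, `"HIL"` or `"MNI"`.
#' @inheritParams detect_ste
#' @export
detect_hfo <- function(x, fs, detector = c("STE", "SLL", "HIL", "MNI"),
                       params = detector_params(),
                       channel_id = NA_character_) {
  detector <- match.arg(detector)
  fn <- switch(detector, STE = detect_ste, SLL = detect_sll,
               HIL = detect_hil, MNI = detect_mni)
  fn(x, fs, params, channel_id)
}

#' HFO rate per 5 minutes
#'
#' Counts events with the requested band floor and rescales the count to
#' the conventional 300-s denominator.
#'
#' @param events event data.frame as returned by the detectors.
#' @param epoch_duration_s epoch length in seconds (> 0).
#' @param band_floor band floor to count (Hz); NULL counts everything.
#' @return events per 5 min (numeric scalar).
#' @export
event_rate <- function(events, epoch_duration_s, band_floor = NULL) {
  stopifnot(epoch_duration_s > 0)
  k <- if (is.null(band_floor)) nrow(events)
       else sum(events$band_floor == band_floor)
  k * 300 / epoch_duration_s
}
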