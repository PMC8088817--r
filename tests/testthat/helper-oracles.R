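# Brute-force oracle implementations of the detector rules, written as
# plain loops with their own window/percentile/SD arithmetic.  They share
# only the band-pass filter with the package (the band definition is
# common infrastructure; the detection *rules* are re-derived here
# independently).  Used to certify the vectorized detectors exactly.

oracle_sd <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# linear-interpolation (type 7) percentile, written out longhand
oracle_quantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(length(s), lo + 1)] - s[lo])
}

# centred moving RMS, truncated windows at the edges
oracle_moving_rms <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + w - 1L - half)
    out[i] <- sqrt(sum(x[lo:hi]^2) / (hi - lo + 1L))
  }
  out
}

# centred moving line length over w first differences
oracle_moving_ll <- function(x, w) {
  n <- length(x)
  d <- c(0, abs(diff(x)))
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + w - 1L - half)
    out[i] <- sum(d[lo:hi])
  }
  out
}

# maximal runs of TRUE by explicit scan
oracle_runs <- function(flag) {
  starts <- integer(); ends <- integer()
  inrun <- FALSE
  for (i in seq_along(flag)) {
    if (flag[i] && !inrun) { starts <- c(starts, i); inrun <- TRUE }
    if (!flag[i] && inrun) { ends <- c(ends, i - 1L); inrun <- FALSE }
  }
  if (inrun) ends <- c(ends, length(flag))
  cbind(start = starts, end = ends)
}

oracle_merge <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap)
      out[nrow(out), "end"] <- runs[i, "end"]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

oracle_duration_filter <- function(runs, min_dur) {
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs)))
    keep[i] <- (runs[i, "end"] - runs[i, "start"] + 1L) >= min_dur
  runs[keep, , drop = FALSE]
}

# events as (t_start, t_end) pairs for comparison with the package tables
oracle_times <- function(runs, fs) {
  if (nrow(runs) == 0)
    return(data.frame(t_start = numeric(), t_end = numeric()))
  data.frame(t_start = (runs[, "start"] - 1) / fs, t_end = runs[, "end"] / fs)
}

# STE rule: moving RMS > mean + 5 SD; merged runs of >= min duration;
# strictly more than 6 rectified peaks above mean + 3 SD of |xb|
oracle_ste <- function(x, fs, p = detector_params()) {
  xb <- bandpass_zero_phase(x, p$band_floor, p$band_ceiling, fs)
  w <- max(1L, round(p$rms_window_ms / 1000 * fs))
  r <- oracle_moving_rms(xb, w)
  thr <- sum(r) / length(r) + p$rms_threshold_sd * oracle_sd(r)
  runs <- oracle_runs(r > thr)
  if (nrow(runs) == 0) return(oracle_times(runs, fs))
  runs <- oracle_merge(runs, round(p$merge_gap_ms / 1000 * fs))
  runs <- oracle_duration_filter(runs, round(p$min_duration_ms / 1000 * fs))
  rect <- abs(xb)
  pk_thr <- sum(rect) / length(rect) + p$peak_threshold_sd * oracle_sd(rect)
  keep <- logical(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- rect[runs[i, "start"]:runs[i, "end"]]
    npk <- 0L
    for (j in seq_along(seg)) {
      if (j == 1L || j == length(seg)) next
      if (seg[j] > seg[j - 1] && seg[j] >= seg[j + 1] && seg[j] > pk_thr)
        npk <- npk + 1L
    }
    keep[i] <- npk > p$min_peaks
  }
  oracle_times(runs[keep, , drop = FALSE], fs)
}

# SLL rule: line length above its 97.5th empirical percentile
oracle_sll <- function(x, fs, p = detector_params()) {
  xb <- bandpass_zero_phase(x, p$band_floor, p$band_ceiling, fs)
  w <- max(2L, round(p$ll_window_ms / 1000 * fs))
  L <- oracle_moving_ll(xb, w)
  thr <- oracle_quantile(L, p$ecdf_percentile / 100)
  runs <- oracle_runs(L > thr)
  if (nrow(runs) == 0) return(oracle_times(runs, fs))
  runs <- oracle_merge(runs, round(p$merge_gap_ms / 1000 * fs))
  runs <- oracle_duration_filter(runs, round(p$min_duration_ms / 1000 * fs))
  oracle_times(runs, fs)
}

# HIL rule: Hilbert envelope > mean + 5 SD within consecutive 5-s blocks
oracle_hil <- function(x, fs, p = detector_params()) {
  xb <- bandpass_zero_phase(x, p$band_floor, p$band_ceiling, fs)
  env <- Mod(analytic_signal(xb))
  n <- length(env)
  block <- max(4L, round(p$analysis_window_s * fs))
  supra <- logical(n)
  s <- 1L
  while (s <= n) {
    e <- min(n, s + block - 1L)
    seg <- env[s:e]
    thr <- sum(seg) / length(seg) + p$envelope_threshold_sd * oracle_sd(seg)
    for (j in s:e) supra[j] <- env[j] > thr
    s <- e + 1L
  }
  runs <- oracle_runs(supra)
  if (nrow(runs) == 0) return(oracle_times(runs, fs))
  runs <- oracle_merge(runs, round(p$merge_gap_ms / 1000 * fs))
  runs <- oracle_duration_filter(runs, round(p$min_duration_ms / 1000 * fs))
  oracle_times(runs, fs)
}

oracle_flatness <- function(seg, fs, f_lo, f_hi) {
  n <- length(seg)
  pw <- Mod(stats::fft(seg - sum(seg) / n))^2
  keep <- numeric()
  for (k in seq_len(n)) {
    f <- (k - 1) / n * fs
    if (f >= f_lo && f <= f_hi && pw[k] > 0) keep <- c(keep, pw[k])
  }
  if (!length(keep)) return(1)
  exp(sum(log(keep)) / length(keep)) / (sum(keep) / length(keep))
}

# MNI rule: baseline branch = 99.9999th percentile of baseline energy;
# no-baseline branch = per-segment 95th percentile with iterative
# re-detection, detected samples removed from the reference
oracle_mni <- function(x, fs, p = detector_params()) {
  xb <- bandpass_zero_phase(x, p$band_floor, p$band_ceiling, fs)
  w <- max(1L, round(p$mni_rms_window_ms / 1000 * fs))
  energy <- oracle_moving_rms(xb, w)
  n <- length(energy)
  d <- c(0, abs(diff(xb)))
  seg_len <- max(2L, round(p$baseline_segment_s * fs))
  starts <- seq(1L, n, by = seg_len)
  seg_ll <- numeric(length(starts))
  for (i in seq_along(starts)) {
    e <- min(n, starts[i] + seg_len - 1L)
    seg_ll[i] <- sum(d[starts[i]:e]) / (e - starts[i] + 1L)
  }
  med <- stats::median(seg_ll)
  base <- logical(n)
  for (i in seq_along(starts)) {
    e <- min(n, starts[i] + seg_len - 1L)
    ok <- seg_ll[i] <= med &&
      oracle_flatness(xb[starts[i]:e], fs, p$band_floor, p$band_ceiling) >=
        p$flatness_floor
    for (j in starts[i]:e) base[j] <- ok
  }
  if (sum(base) / n >= p$min_baseline_frac) {
    thr <- oracle_quantile(energy[base], p$baseline_percentile / 100)
    supra <- energy > thr
  } else {
    supra <- logical(n)
    blk <- max(2L, round(p$segment_s * fs))
    for (s in seq(1L, n, by = blk)) {
      e <- min(n, s + blk - 1L)
      idx <- s:e
      detected <- logical(length(idx))
      for (it in seq_len(p$mni_iterations)) {
        ref <- energy[idx][!detected]
        if (!length(ref)) break
        thr <- oracle_quantile(ref, p$no_baseline_percentile / 100)
        new <- energy[idx] > thr
        if (all(new == detected)) break
        detected <- detected | new
      }
      supra[idx] <- detected
    }
  }
  runs <- oracle_runs(supra)
  if (nrow(runs) == 0) return(oracle_times(runs, fs))
  runs <- oracle_merge(runs, round(p$merge_gap_ms / 1000 * fs))
  runs <- oracle_duration_filter(runs, round(p$min_duration_ms / 1000 * fs))
  oracle_times(runs, fs)
}

# Mann-Whitney U statistic as an AUC oracle: all-pairs loop
oracle_auc <- function(score, truth) {
  pos <- score[truth == 1]; neg <- score[truth == 0]
  u <- 0
  for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}

# mean vector length by direct summation (modulation-index oracle)
oracle_mvl <- function(amp, phase) {
  re <- 0; im <- 0
  for (i in seq_along(amp)) {
    re <- re + amp[i] * cos(phase[i])
    im <- im + amp[i] * sin(phase[i])
  }
  sqrt(re^2 + im^2) / length(amp)
}

# leave-self-out z-score against the k nearest sites with one-pass
# one-sided outlier exclusion, all longhand
oracle_zscore <- function(site_xyz, site_val, q_xyz, q_val, k,
                          outlier_sd, self = NA_integer_) {
  d <- numeric(nrow(site_xyz))
  for (i in seq_len(nrow(site_xyz)))
    d[i] <- sqrt(sum((site_xyz[i, ] - q_xyz)^2))
  ord <- order(d, seq_along(d))
  if (!is.na(self)) ord <- ord[ord != self]
  v <- site_val[ord[seq_len(k)]]
  mu <- sum(v) / k
  sg <- oracle_sd(v)
  if (is.finite(sg) && sg > 0) {
    keep <- v <= mu + outlier_sd * sg
    if (!all(keep)) {
      v <- v[keep]
      mu <- sum(v) / length(v)
      sg <- if (length(v) > 1) oracle_sd(v) else 0
    }
  } else sg <- 0
  if (sg > 0) (q_val - mu) / sg else NA_real_
}
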