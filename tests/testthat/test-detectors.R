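# short fixture: 8 s of 1/f background with two strong ripple bursts and
# one sharp transient, used for rule-level checks
detector_fixture <- function(seed = 21, duration_s = 8) {
  spec <- signal_spec(duration_s = duration_s, seed = seed)
  x <- make_background(spec)
  a <- 15 * sd(bandpass_zero_phase(x, 80, 300, spec$fs))
  x <- inject_oscillation(x, planted_event("oscillation", t0 = 2, f0 = 120,
                                           n_cycles = 12, amplitude = a),
                          spec$fs)
  x <- inject_oscillation(x, planted_event("oscillation", t0 = 5.5, f0 = 220,
                                           n_cycles = 12, amplitude = a),
                          spec$fs)
  x <- inject_sharp_transient(x, planted_event("sharp_transient", t0 = 4,
                                               amplitude = 20 * sd(x)),
                              spec$fs)
  list(x = x, fs = spec$fs)
}

test_that("detected events carry sensible metadata: ordering, duration floor, band and peak frequency", {
  fx <- detector_fixture()
  p <- detector_params()
  for (d in c("STE", "SLL", "HIL", "MNI")) {
    ev <- detect_hfo(fx$x, fx$fs, d, p, channel_id = "LA1")
    expect_gt(nrow(ev), 0)
    expect_true(all(diff(ev$t_start) > 0))
    expect_true(all(ev$t_end > ev$t_start))
    expect_true(all(ev$t_end - ev$t_start >= p$min_duration_ms / 1000 - 1e-9))
    expect_true(all(ev$band_floor == 80))
    expect_true(all(ev$channel_id == "LA1"))
    expect_true(all(ev$label == "unverified"))
    expect_true(all(ev$peak_freq > 0 & ev$peak_freq <= fx$fs / 2))
  }
})

test_that("detectors are deterministic and find the planted bursts at both 120 and 220 Hz", {
  fx <- detector_fixture()
  hits <- function(ev, t0) any(ev$t_start < t0 + 0.15 & ev$t_end > t0)
  for (d in c("STE", "SLL", "HIL", "MNI")) {
    ev <- detect_hfo(fx$x, fx$fs, d)
    expect_identical(ev, detect_hfo(fx$x, fx$fs, d))
    expect_true(hits(ev, 2), label = paste(d, "finds the 120 Hz burst"))
    expect_true(hits(ev, 5.5), label = paste(d, "finds the 220 Hz burst"))
  }
})

test_that("the 250 Hz band floor suppresses a 120 Hz burst but keeps a 280 Hz one", {
  spec <- signal_spec(duration_s = 8, seed = 33)
  x <- make_background(spec)
  a <- 15 * sd(bandpass_zero_phase(x, 250, 300, spec$fs))
  x <- inject_oscillation(x, planted_event("oscillation", t0 = 2, f0 = 120,
                                           n_cycles = 12, amplitude = a), spec$fs)
  x <- inject_oscillation(x, planted_event("oscillation", t0 = 6, f0 = 280,
                                           n_cycles = 16, amplitude = a), spec$fs)
  ev <- detect_ste(x, spec$fs, detector_params(band_floor = 250))
  expect_true(any(ev$t_start < 6.2 & ev$t_end > 6))
  expect_false(any(ev$t_start < 2.2 & ev$t_end > 2))
})

test_that("supra-threshold runs separated by less than the merge gap fuse into one event", {
  runs <- cbind(start = c(1L, 15L, 60L), end = c(10L, 20L, 70L))
  merged <- hfomi:::merge_runs(runs, gap = 10L)
  expect_equal(nrow(merged), 2)
  expect_equal(unname(merged[1, ]), c(1L, 20L))
  # and a gap of exactly the limit stays separate
  expect_equal(nrow(hfomi:::merge_runs(cbind(start = c(1L, 21L),
                                             end = c(10L, 30L)), 10L)), 2)
})

test_that("the rectified-peak rule counts plateau maxima once and requires a strict majority", {
  expect_identical(hfomi:::find_peaks(c(0, 1, 1, 0)), 2L)
  expect_identical(hfomi:::find_peaks(c(0, 2, 0, 3, 0)), c(2L, 4L))
  expect_identical(hfomi:::find_peaks(c(3, 2, 1)), integer())
})

test_that("MNI falls back to iterative per-segment percentiles when no baseline exists", {
  # continuous large-amplitude oscillation: no quiet stretches anywhere
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  x <- 100 * sin(2 * pi * 130 * t) * (1 + 0.5 * sin(2 * pi * 0.3 * t)) +
    make_background(signal_spec(duration_s = 20, seed = 5, noise_sd = 5))
  p <- detector_params()
  xb <- bandpass_zero_phase(x, 80, 300, fs)
  expect_lt(mean(hfomi:::mni_baseline_mask(xb, fs, p)), p$min_baseline_frac)
  ev <- detect_mni(x, fs, p)
  expect_gt(nrow(ev), 0)                   # the fallback branch still detects
})

test_that("event rates rescale to the 300-s convention and filter by band floor", {
  ev <- data.frame(band_floor = c(80, 80, 150))
  expect_equal(event_rate(ev, epoch_duration_s = 150), 6)
  expect_equal(event_rate(ev, epoch_duration_s = 300, band_floor = 80), 2)
  expect_equal(event_rate(ev, epoch_duration_s = 300, band_floor = 150), 1)
  expect_error(event_rate(ev, epoch_duration_s = 0), "epoch_duration_s")
  expect_error(detector_params(band_floor = 100), "band_floor")
})
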