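# one labelled event of each planted kind, on a shared background
verification_case <- function(kind, seed = 8) {
  spec <- signal_spec(duration_s = 6, seed = seed)
  x <- make_background(spec)
  if (kind == "oscillation") {
    a <- 12 * sd(bandpass_zero_phase(x, 80, 300, spec$fs))
    x <- inject_oscillation(x, planted_event("oscillation", t0 = 3, f0 = 130,
                                             n_cycles = 12, amplitude = a),
                            spec$fs)
    win <- c(3, 3 + 12 / 130)
  } else {
    x <- inject_sharp_transient(x, planted_event("sharp_transient", t0 = 3,
                                                 amplitude = 20 * sd(x)),
                                spec$fs)
    win <- c(3, 3.06)
  }
  list(x = x, fs = spec$fs, win = win)
}

test_that("the time-frequency map z-scores against the flanks and spans the requested window", {
  cs <- verification_case("oscillation")
  map <- tf_map(cs$x, cs$fs, cs$win[1], cs$win[2])
  expect_s3_class(map, "tf_map")
  expect_equal(dim(map$power), c(30, sum(map$times >= cs$win[1] - 0.25 - 1e-9 &
                                           map$times <= cs$win[2] + 0.25 + 1e-9)))
  expect_false(map$edge_flag)
  # the blob must be strongest near the planted 130 Hz row
  prof <- apply(map$power[, map$ev_cols], 1, max)
  expect_equal(map$freqs[which.max(prof)], 130, tolerance = 130 * 0.2)
  # an event at the epoch edge sets the edge flag
  expect_true(tf_map(cs$x, cs$fs, 0.01, 0.05)$edge_flag)
})

test_that("a planted ripple verifies as vHFO in its band and a sharp transient as Spike", {
  osc <- verification_case("oscillation")
  expect_identical(classify_event(tf_map(osc$x, osc$fs, osc$win[1], osc$win[2])),
                   "vHFO_80_150")
  tr <- verification_case("sharp_transient")
  expect_identical(classify_event(tf_map(tr$x, tr$fs, tr$win[1], tr$win[2])),
                   "Spike")
})

test_that("a window of plain background verifies as Others and anchorless broadband noise as Artifact", {
  vhfo <- c("vHFO_80_150", "vHFO_150_250", "vHFO_250_300")
  for (s in 13:16) {
    spec <- signal_spec(duration_s = 6, seed = s)
    x <- make_background(spec)
    expect_identical(classify_event(tf_map(x, spec$fs, 3, 3.1)), "Others")
  }
  # broadband high-frequency noise spanning 80-300 Hz with no
  # low-frequency anchor is the canonical Artifact signature
  spec <- signal_spec(duration_s = 6, seed = 13)
  x <- make_background(spec)
  withr::with_seed(99, {
    hf <- bandpass_zero_phase(rnorm(length(x)), 85, 300, spec$fs)
  })
  w <- x
  i <- 3000:3100
  w[i] <- w[i] + hf[i] * 25 * sd(x) / sd(hf)
  expect_identical(classify_event(tf_map(w, spec$fs, 3, 3.1)), "Artifact")
  # a white-noise burst carries low-frequency power too: it has an
  # anchor, so it must not verify as a genuine oscillation
  wb <- x
  wb[i] <- wb[i] + withr::with_seed(98, rnorm(101, sd = 25 * sd(x)))
  expect_false(classify_event(tf_map(wb, spec$fs, 3, 3.1)) %in% vhfo)
})

test_that("verify_events labels every row and verified rates respect band nesting", {
  osc <- verification_case("oscillation")
  ev <- detect_ste(osc$x, osc$fs)
  expect_error(verified_rate(ev, 80, 6), "verified")
  lab <- verify_events(ev, osc$x, osc$fs)
  expect_false(any(lab$label == "unverified"))
  # nesting identity: rate(>80) = rate(>150) + count of 80-150 labels
  r80 <- verified_rate(lab, 80, 6)
  r150 <- verified_rate(lab, 150, 6)
  r250 <- verified_rate(lab, 250, 6)
  n_80_150 <- sum(lab$label == "vHFO_80_150") * 300 / 6
  n_150_250 <- sum(lab$label == "vHFO_150_250") * 300 / 6
  expect_equal(r80, r150 + n_80_150)
  expect_equal(r150, r250 + n_150_250)
  expect_gte(r150, r250)
})

test_that("band labels partition 80-300 Hz by peak frequency", {
  expect_identical(hfomi:::vhfo_band_label(100), "vHFO_80_150")
  expect_identical(hfomi:::vhfo_band_label(150), "vHFO_150_250")
  expect_identical(hfomi:::vhfo_band_label(250), "vHFO_250_300")
  expect_identical(hfomi:::vhfo_band_label(40), "Others")
  expect_identical(hfomi:::vhfo_labels_at_or_above(150),
                   c("vHFO_150_250", "vHFO_250_300"))
})
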