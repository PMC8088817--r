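test_that("electrode layouts keep the clinical masks spatially and logically consistent", {
  lay <- make_electrode_layout(80, seed = 2)
  expect_equal(nrow(lay), 80)
  expect_identical(lay$non_epileptic, !(lay$soz | lay$lesion | lay$spiking))
  expect_true(any(lay$resected) && any(!lay$resected))
  # complete resection covers the SOZ; partial resection misses part of it
  expect_true(all(lay$resected[lay$soz]))
  part <- make_electrode_layout(80, seed = 2, resect_soz = FALSE)
  expect_true(any(!part$resected[part$soz]))
  # coordinates lie on the hemispheric patch
  r <- sqrt(lay$x_mm^2 + lay$y_mm^2 + lay$z_mm^2)
  expect_true(all(abs(r - 70) < 1))
  expect_true(all(lay$z_mm > -1))
})

test_that("the simulated cohort is reproducible and its truth tables recompute the planted quantities", {
  spec <- cohort_spec(n_patients = 12, seed = 44)
  b1 <- simulate_cohort(spec)
  b2 <- simulate_cohort(spec)
  expect_identical(b1$clinical, b2$clinical)
  expect_identical(b1$channels, b2$channels)
  # truth invariant: the stored Subtraction truth equals a recomputation
  # from the per-channel true rates
  for (i in seq_along(b1$channels)) {
    ch <- b1$channels[[i]]
    keep <- !ch$artifact
    expect_equal(b1$truth$subtraction_true[i],
                 mean(ch$true_rate[keep & ch$resected]) -
                   mean(ch$true_rate[keep & !ch$resected]), tolerance = 1e-12)
  }
  # and the outcome probabilities equal the logistic of the linear predictor
  expect_equal(b1$truth$p_success, plogis(b1$truth$linpred), tolerance = 1e-12)
  expect_true(all(b1$clinical$ilae_class %in% 1:6))
  expect_identical(b1$clinical$success, b1$clinical$ilae_class == 1L)
})

test_that("epileptic channels carry the planted rate multiplier on average", {
  b <- simulate_cohort(cohort_spec(n_patients = 30, seed = 45,
                                   epileptic_rate_multiplier = 4))
  ratio_rate <- ratio_mi <- numeric(0)
  for (ch in b$channels) {
    epi <- ch$soz | ch$lesion | ch$spiking
    ratio_rate <- c(ratio_rate, mean(ch$true_rate[epi]) / mean(ch$true_rate[!epi]))
    ratio_mi <- c(ratio_mi, mean(ch$true_mi[epi]) / mean(ch$true_mi[!epi]))
  }
  expect_equal(mean(ratio_rate), 4, tolerance = 0.5)
  expect_equal(mean(ratio_mi), 4, tolerance = 0.5)
})

test_that("unknown coefficient names and degenerate specs are rejected", {
  expect_error(cohort_spec(true_beta = c(nope = 1)), "unknown coefficient")
  expect_error(cohort_spec(n_patients = 1), "n_patients")
  expect_error(cohort_spec(frac_non_epileptic = 1.2), "frac_non_epileptic")
  expect_error(make_electrode_layout(1), "2 channels")
})

test_that("a synthesized channel plants the number of events its truth row prescribes", {
  row <- data.frame(artifact = FALSE, true_rate = 6)
  out <- synthesize_channel(row, signal_spec(duration_s = 50), seed = 9)
  expect_equal(nrow(out$events), round(6 * 50 / 300))
  expect_equal(length(out$signal), 50 * 1000)
  # the planted events are detectable where they were planted
  ev <- detect_ste(out$signal, 1000)
  for (t0 in out$events$t0)
    expect_true(any(ev$t_start < t0 + 0.2 & ev$t_end > t0))
})

test_that("cohort files round-trip through the tabular readers", {
  b <- simulate_cohort(cohort_spec(n_patients = 4, seed = 46))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  clin <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(nrow(clin), 4)
  expect_identical(clin$success, b$clinical$success)
  tab <- read_channel_table(file.path(dir, "P001_channels.tsv"))
  expect_identical(tab$non_epileptic, b$channels[["P001"]]$non_epileptic)
})
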