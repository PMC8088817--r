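#' Synthetic electrode layout on a hemispheric surface
#'
#' Samples `n_channels` distinct coordinates on a hemispheric patch
#' (sphere of radius 70 mm, upper hemisphere) and assigns the clinical
#' masks: a spatially clustered seizure-onset zone, an adjacent lesion
#' and spiking zone, random artifact channels, and a resection cap
#' centred on the SOZ.  `non_epileptic` is derived as outside SOZ,
#' lesion and spiking zones.
#'
#' @param n_channels number of electrodes (>= 2 when a resection is
#'   requested).
#' @param seed RNG seed.
#' @param soz_frac,lesion_frac,spiking_frac,artifact_frac approximate
#'   fractions of channels per mask.
#' @param resect_soz when TRUE the resection cap covers the whole SOZ;
#'   when FALSE it deliberately misses part of it.
#' @param radius_mm sphere radius (default 70).
#' @return data.frame: `channel, x_mm, y_mm, z_mm, artifact, soz,
#'   lesion, spiking, resected, non_epileptic`.
#' @export
make_electrode_layout <- function(n_channels, seed = 1L, soz_frac = 0.1,
                                  lesion_frac = 0.05, spiking_frac = 0.15,
                                  artifact_frac = 0.05, resect_soz = TRUE,
                                  radius_mm = 70) {
  if (n_channels < 2) stop("invalid spec: need >= 2 channels for a resection")
  withr::with_seed(seed, {
    # uniform directions on the upper hemisphere
    u <- stats::runif(n_channels); v <- stats::runif(n_channels)
    theta <- acos(u)                 # polar angle in [0, pi/2]
    phi <- 2 * pi * v
    xyz <- radius_mm * cbind(x_mm = sin(theta) * cos(phi),
                             y_mm = sin(theta) * sin(phi),
                             z_mm = cos(theta))
    xyz <- xyz + matrix(stats::rnorm(3 * n_channels, sd = 0.01), ncol = 3)
    centre <- sample.int(n_channels, 1)
    d <- sqrt(colSums((t(xyz) - xyz[centre, ])^2))
    ord <- order(d)
    n_soz <- max(1L, round(soz_frac * n_channels))
    n_spk <- max(1L, round(spiking_frac * n_channels))
    n_les <- round(lesion_frac * n_channels)
    soz <- logical(n_channels); soz[ord[seq_len(n_soz)]] <- TRUE
    spiking <- logical(n_channels); spiking[ord[seq_len(n_soz + n_spk)]] <- TRUE
    lesion <- logical(n_channels)
    if (n_les > 0) lesion[ord[seq_len(n_les)]] <- TRUE
    artifact <- stats::runif(n_channels) < artifact_frac
    # resection cap: covers the SOZ (complete) or only its inner half
    n_res <- if (resect_soz) n_soz + max(1L, round(0.05 * n_channels))
             else max(1L, floor(n_soz / 2))
    resected <- logical(n_channels)
    resected[ord[seq_len(min(n_res, n_channels - 1L))]] <- TRUE
    # guarantee at least one preserved and one resected non-artifact channel
    if (all(resected[!artifact])) resected[ord[n_channels]] <- FALSE
    if (!any(resected & !artifact)) artifact[ord[1]] <- FALSE
    tab <- data.frame(channel = sprintf("CH%03d", seq_len(n_channels)),
                      xyz, artifact = artifact, soz = soz, lesion = lesion,
                      spiking = spiking, resected = resected)
    validate_channel_table(tab)
  })
}

#' Specification of a synthetic surgical cohort
#'
#' Defaults emulate the study cohort: 135 patients with 32-152 analysed
#' electrodes each (mean near 108), roughly 70% baseline success, and
#' the marginal covariate distributions of the patient profile (50.4%
#' male, 33.3% daily seizures, 52.6% left-hemispheric, 58.5% MRI lesion,
#' 86.7% habitual seizures captured, 12.6% incomplete SOZ resection,
#' 63.0% extra-temporal resection, mean resection 16.2%).
#'
#' @param n_patients cohort size (>= 2; default 135).
#' @param channels_per_patient integer range, default `c(32, 152)`.
#' @param frac_non_epileptic target fraction of non-epileptic sites per
#'   patient (in (0,1); default 0.7).
#' @param epileptic_rate_multiplier factor applied to event rates and MI
#'   at epileptic channels (default 4).
#' @param true_beta named coefficient vector over the ten clinical
#'   covariates plus `biomarker` (the Subtraction statistic); unnamed
#'   entries default to 0.  Coefficients act on cohort-centred
#'   covariates, so the intercept controls the baseline success rate.
#' @param intercept logistic intercept; the default 0.867 gives a
#'   baseline success probability of 0.704 with zero effects.
#' @param seed RNG seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 135, channels_per_patient = c(32, 152),
                        frac_non_epileptic = 0.7,
                        epileptic_rate_multiplier = 4,
                        true_beta = c(biomarker = 0.5), intercept = 0.867,
                        seed = 1L) {
  if (n_patients < 2) stop("invalid spec: n_patients >= 2")
  if (frac_non_epileptic <= 0 || frac_non_epileptic >= 1)
    stop("invalid spec: frac_non_epileptic in (0,1)")
  beta <- stats::setNames(numeric(length(covariate_names()) + 1),
                          c(covariate_names(), "biomarker"))
  if (length(true_beta)) {
    if (is.null(names(true_beta)) && length(true_beta) == length(beta))
      beta[] <- true_beta
    else {
      bad <- setdiff(names(true_beta), names(beta))
      if (length(bad)) stop("unknown coefficient names: ",
                            paste(bad, collapse = ", "))
      beta[names(true_beta)] <- true_beta
    }
  }
  if (!all(is.finite(beta)) || !is.finite(intercept))
    stop("invalid spec: coefficients must be finite")
  structure(list(n_patients = as.integer(n_patients),
                 channels_per_patient = as.integer(channels_per_patient),
                 frac_non_epileptic = frac_non_epileptic,
                 epileptic_rate_multiplier = epileptic_rate_multiplier,
                 true_beta = beta, intercept = intercept,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Names of the ten clinical outcome-model covariates
#' @return character vector.
#' @export
covariate_names <- function() {
  c("age", "sex", "daily_seizures", "n_aeds", "left_hemisphere",
    "mri_lesion", "habitual_sz_captured", "soz_fully_resected",
    "extratemporal_resection", "resection_size_pct")
}

#' Build the outcome-model design data.frame
#'
#' Numeric coding: logical yes = 1, male = 1, left = 1; age and AED
#' count numeric; resection size in percent.
#'
#' @param clinical clinical data.frame (see [read_clinical_table()]).
#' @param biomarker optional per-patient Subtraction biomarker column.
#' @return data.frame ready for [fit_logistic()] / [loo_predict()].
#' @export
model_design <- function(clinical, biomarker = NULL) {
  d <- clinical[, covariate_names()]
  for (nm in names(d)) d[[nm]] <- as.numeric(d[[nm]])
  if (!is.null(biomarker)) d$biomarker <- as.numeric(biomarker)
  d
}

sample_clinical <- function(n) {
  # marginals of the study's patient profile; joint structure independent
  age <- round(pmin(44, pmax(4, stats::rgamma(n, shape = 4, scale = 3.3))))
  data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    age = age,
    sex = stats::runif(n) < 0.504,
    daily_seizures = stats::runif(n) < 0.333,
    n_aeds = sample(c(1, 2, 3, 5), n, replace = TRUE,
                    prob = c(40, 60, 34, 1) / 135),
    left_hemisphere = stats::runif(n) < 0.526,
    mri_lesion = stats::runif(n) < 0.585,
    habitual_sz_captured = stats::runif(n) < 0.867,
    soz_fully_resected = stats::runif(n) < 0.874,
    extratemporal_resection = stats::runif(n) < 0.630,
    resection_size_pct = pmin(91.6, pmax(0.6, stats::rlnorm(n, log(13), 0.7))))
}

#' Simulate a full synthetic cohort with known ground truth
#'
#' Generates, per patient, an electrode layout, channel-level true HFO
#' rates (events / 5 min) and modulation-index values with epileptic
#' channels scaled by `epileptic_rate_multiplier`, noisy "observed"
#' values (Poisson counts for rates, log-normal noise for MI), the ten
#' clinical covariates, and an outcome drawn from
#' `Bernoulli(logistic(intercept + x . true_beta))` where `x` includes
#' the patient's true Subtraction biomarker.  The resection cap covers
#' the epileptic cluster when `soz_fully_resected` is TRUE and misses
#' half of it otherwise, tying the biomarker to the outcome model.  The
#' complete truth tables are retained so every planted rate and outcome
#' probability can be recomputed exactly.
#'
#' @param spec a [cohort_spec()].
#' @param base_rate_meanlog,base_rate_sdlog log-normal parameters of the
#'   baseline channel HFO rate (default meanlog log(2), sdlog 0.8 --
#'   a few events per 5 min at non-epileptic cortex).
#' @param base_mi_meanlog,base_mi_sdlog log-normal parameters of the
#'   baseline channel MI (uV).
#' @return a `cohort_bundle` list: `clinical`, `channels` (per-patient
#'   data.frames with layout, `true_rate`, `rate`, `true_mi`, `mi`),
#'   `truth` (`beta`, `intercept`, `subtraction_true`, `linpred`,
#'   `p_success`), `warnings`, `spec`.
#' @export
simulate_cohort <- function(spec, base_rate_meanlog = log(2),
                            base_rate_sdlog = 0.8,
                            base_mi_meanlog = log(0.3),
                            base_mi_sdlog = 0.6) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_patients
    clinical <- sample_clinical(n)
    # epileptic-cluster size consistent with the non-epileptic fraction
    epi_frac <- 1 - spec$frac_non_epileptic
    channels <- vector("list", n)
    sub_true <- numeric(n)
    for (i in seq_len(n)) {
      nc <- sample(seq(spec$channels_per_patient[1],
                       spec$channels_per_patient[2]), 1)
      lay <- make_electrode_layout(
        nc, seed = sample.int(.Machine$integer.max, 1),
        soz_frac = epi_frac * 0.35, spiking_frac = epi_frac * 0.5,
        lesion_frac = epi_frac * 0.15,
        resect_soz = clinical$soz_fully_resected[i])
      epi <- lay$soz | lay$lesion | lay$spiking
      true_rate <- stats::rlnorm(nc, base_rate_meanlog, base_rate_sdlog)
      true_rate[epi] <- true_rate[epi] * spec$epileptic_rate_multiplier
      rate <- stats::rpois(nc, true_rate)
      true_mi <- stats::rlnorm(nc, base_mi_meanlog, base_mi_sdlog)
      true_mi[epi] <- true_mi[epi] * spec$epileptic_rate_multiplier
      mi <- true_mi * stats::rlnorm(nc, 0, 0.2)
      lay$true_rate <- true_rate; lay$rate <- as.numeric(rate)
      lay$true_mi <- true_mi; lay$mi <- mi
      channels[[i]] <- lay
      keep <- !lay$artifact
      sub_true[i] <- mean(true_rate[keep & lay$resected]) -
        mean(true_rate[keep & !lay$resected])
    }
    x <- model_design(clinical, biomarker = sub_true)
    # coefficients act on cohort-centred covariates so the intercept sets
    # the baseline success rate regardless of covariate location
    xc <- scale(as.matrix(x), center = TRUE, scale = FALSE)
    linpred <- spec$intercept + xc %*% spec$true_beta[colnames(x)]
    p <- stats::plogis(as.numeric(linpred))
    success <- stats::runif(n) < p
    clinical$ilae_class <- ifelse(success, 1L, 0L)
    # failure classes 2-5, worse class for lower success probability
    fail <- which(!success)
    if (length(fail)) {
      q <- rank(p[fail], ties.method = "first") / (length(fail) + 1)
      clinical$ilae_class[fail] <- 5L - findInterval(q, c(0.25, 0.5, 0.75))
    }
    clinical$success <- success
    warn <- character()
    const <- vapply(model_design(clinical), function(v) length(unique(v)) == 1,
                    TRUE)
    if (any(const))
      warn <- c(warn, paste("degenerate design: constant covariate(s):",
                            paste(names(const)[const], collapse = ", ")))
    names(channels) <- clinical$patient
    structure(list(clinical = clinical, channels = channels,
                   truth = list(beta = spec$true_beta,
                                intercept = spec$intercept,
                                subtraction_true = sub_true,
                                linpred = as.numeric(linpred),
                                p_success = p),
                   warnings = warn, spec = spec),
              class = "cohort_bundle")
  })
}

#' Synthesize the iEEG epoch of one simulated channel
#'
#' Materializes a signal consistent with a channel row from
#' [simulate_cohort()]: 1/f background with `round(true_rate)` planted
#' oscillations at random times/frequencies within 80-300 Hz (artifact
#' channels get broadband high-amplitude noise instead).
#'
#' @param channel_row one row of a per-patient channel data.frame.
#' @param sig_spec a [signal_spec()] for the background.
#' @param snr_sd planted-burst amplitude in multiples of the band-passed
#'   background SD (default 15).
#' @param seed RNG seed.
#' @return list `signal`, `events` (planted-truth data.frame).
#' @export
synthesize_channel <- function(channel_row, sig_spec = signal_spec(),
                               snr_sd = 15, seed = 1L) {
  sp <- sig_spec; sp$seed <- seed
  bg <- make_background(sp)
  if (isTRUE(channel_row$artifact)) {
    noisy <- sp; noisy$seed <- seed + 1L
    noisy$spectral_exponent <- 0; noisy$noise_sd <- sp$noise_sd * 20
    return(list(signal = bg + make_background(noisy),
                events = data.frame()))
  }
  band_sd <- stats::sd(bandpass_zero_phase(bg, 80, 300, sp$fs))
  k <- round(channel_row$true_rate * sp$duration_s / 300)
  ev <- withr::with_seed(seed + 7L, data.frame(
    t0 = if (k > 0) sort(stats::runif(k, 0.5, sp$duration_s - 0.5)) else numeric(),
    f0 = if (k > 0) stats::runif(k, 85, 295) else numeric()))
  x <- bg
  for (j in seq_len(nrow(ev)))
    x <- inject_oscillation(x, planted_event("oscillation", t0 = ev$t0[j],
                                             f0 = ev$f0[j], n_cycles = 8,
                                             amplitude = snr_sd * band_sd),
                            sp$fs)
  list(signal = x, events = ev)
}

#' Write a simulated cohort to disk
#'
#' Channel metadata (with observed biomarkers) as per-patient TSV, the
#' clinical table as CSV, and the truth tables as CSV.
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (p in names(bundle$channels))
    utils::write.table(bundle$channels[[p]],
                       file.path(dir, paste0(p, "_channels.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- data.frame(patient = bundle$clinical$patient,
                      subtraction_true = bundle$truth$subtraction_true,
                      linpred = bundle$truth$linpred,
                      p_success = bundle$truth$p_success)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
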