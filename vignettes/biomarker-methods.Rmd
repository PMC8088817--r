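---
title: "Interictal HFO and coupling biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal HFO and coupling biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfomi)
```

## The scientific problem

Epilepsy surgery succeeds when the cortex that generates seizures is
removed.  Two interictal (between-seizure) intracranial EEG signatures
mark epileptogenic tissue without waiting for a seizure: brief
high-frequency oscillations (HFOs, 80–300 Hz) and the coupling of
high-frequency amplitude to the phase of slow waves (3–4 Hz) during
slow-wave sleep.  If these signatures truly mark tissue that must be
removed, then a statistic contrasting the *resected* against the
*preserved* electrode sites of a patient should predict whether that
patient becomes seizure-free.

`hfomi` implements that chain end to end: HFO detection, time–frequency
verification of detected events, a mean-vector-length modulation index,
normalization against a normative atlas of non-epileptic cortex,
patient-level Subtraction biomarkers, and logistic outcome models with
honest cross-validation.  Because real intracranial recordings cannot
ship with a package, every stage is validated on synthetic signals and
cohorts with planted ground truth.

## Signal model and synthetic data

A background channel is Gaussian noise shaped to a $1/f^\alpha$ power
spectrum ($\alpha = 1$ by default, SD 20 µV, 1000 Hz sampling), the
canonical broadband character of intracranial EEG.  Onto this background
the generators plant:

* **oscillatory bursts** — `n_cycles` of a sinusoid at $f_0 \in [80,
  300]$ Hz under a full-length Hann taper (`inject_oscillation()`): the
  ground-truth *true* HFO;
* **sharp transients** — a biphasic exponential cusp
  $-\mathrm{sign}(t)\,e^{-|t|/\tau}$ (`inject_sharp_transient()`).  The
  cusp has a single sharp zero-crossing and a monotonically decaying
  spectral tail, so it contains no sustained oscillation at any
  frequency, yet high-pass filtering rings at the discontinuity and
  produces a ripple-shaped deflection.  It is the ground-truth *false*
  HFO used to challenge the verifier;
* **coupled epochs** — $s(t) = A_{\mathrm{slow}}\cos\phi(t) + A_0\,
  (1 + m\cos\phi(t))\cos(2\pi f_c t)$ with $\phi$ the phase of a 3–4 Hz
  slow wave.  The mean vector length of (amplitude, phase) of the
  noiseless construction is exactly $A_0 m/2$, a closed-form oracle for
  the modulation index.

The cusp shape was chosen over smoother transient models
(Gaussian-derivative, piecewise-linear) deliberately: smooth transients
carry essentially no energy above 80 Hz (so "false ripples" would only
be noise maxima), while piecewise-linear ones have sinc-like spectral
nulls that create spurious isolated blobs.  The cusp produces a real,
strong, band-passed deflection (tens of background SDs) whose
time–frequency signature is genuinely that of a filtering artefact.

**Scope of emulation.**  The synthetic family reproduces the *spectral*
and *morphological* features the algorithms key on — it does not emulate
electrode physics, volume conduction, sleep architecture, or
non-stationary artefact regimes.  Passing the test suite therefore
certifies the algorithms against their stated rules and against planted
truth, not clinical performance on real recordings.

## The four detectors

All detectors band-pass the trace to $f$–300 Hz ($f \in \{80, 150,
250\}$), merge supra-threshold runs separated by less than 10 ms, and
discard events shorter than 6 ms.  Their rules, with config-exposed
defaults (`detector_params()`):

* **STE** (short-time energy): moving RMS (3 ms window) above the epoch
  mean + 5 SD, and the run must contain more than 6 rectified peaks
  above mean + 3 SD of the rectified trace.
* **SLL** (short line length): windowed sum of absolute successive
  differences (window = one cycle at the band floor) above the 97.5th
  percentile of its empirical distribution.  As a pure percentile rule
  it flags a fixed fraction of every epoch; its value lies in *relative*
  rates, not absolute ones.
* **HIL** (Hilbert envelope): analytic-signal envelope above mean + 5 SD
  computed within consecutive 5 s blocks, localizing the statistics in
  time.
* **MNI** (percentile with baseline logic): a moving-RMS energy series
  thresholded at the 99.9999th percentile of the *baseline* energy
  distribution when enough of the epoch qualifies as baseline, otherwise
  per-60-s segments at the 95th percentile with five iterative
  re-detections (detected samples removed from the reference
  distribution each pass).

Baseline identification for MNI uses 1 s candidate segments that must be
both quiet (segment mean line length at or below the median across
segments) and non-oscillatory (band spectral flatness ≥ 0.25).  One
second — rather than a longer 10 s candidate — is a deliberate choice:
a single HFO inside a long candidate raises its mean energy by only a
few percent, within segment-to-segment noise, so burst-bearing stretches
leak into the baseline and the extreme 99.9999th percentile threshold
explodes; 1 s segments exclude them reliably.  The parameter remains
exposed.

Every detector is certified *exactly* against a literal brute-force
re-implementation of its rule (plain loops, longhand percentiles and
SDs) on short fixtures, and for sensitivity/false alarms against planted
15 SD bursts on 5-minute epochs.

## Time–frequency verification

Automatic detectors cannot distinguish a genuine oscillation from the
band-passed ringing of a sharp transient; the classical remedy is visual
review of a time–frequency map, which `classify_event()` automates.  A
Morlet transform (7 cycles, 30 log-spaced frequencies 10–300 Hz, 250 ms
flanking pads) of the *unfiltered* trace is z-scored per frequency row
against the flanks.  The decision logic:

1. The per-row maximum z inside the event window must reach 3 at some
   row ≥ 80 Hz, **and** that row's *mean* z across the window must also
   reach 3.  The second condition matters: the maximum of ~100 z values
   exceeds 3 by chance on plain background, while a genuine blob is
   sustained through the event (planted bursts show mean z in the
   hundreds, background tops out near 2).
2. A **low-frequency anchor** is sought below $80(1 - 3/7) \approx 46$
   Hz — below the Morlet skirt ($3\sigma_f$ at the 80 Hz band edge) so
   broadband high-frequency energy cannot masquerade as its own anchor —
   at twice the activation threshold (a max statistic needs the
   stricter cut).
3. **Unanchored** activation is an isolated blob: labelled
   `vHFO_80_150` / `vHFO_150_250` / `vHFO_250_300` by peak frequency,
   unless it spans the whole 80–300 Hz range (both ends active, ≥ 80 %
   of rows active), which is `Artifact`.
4. **Anchored** activation with a z gap between the anchor and the blob
   is still a vHFO (oscillation riding on a slow wave); without a gap the
   high-frequency power is the monotone tail of a transient — `Spike` —
   unless the raw-power profile still dips below 50 % of the peak, an
   ambiguous blob touching the ridge that is conservatively labelled
   `Others`.

Verified rates nest by construction: the vHFO > 80 Hz rate counts all
three sub-bands, vHFO > 150 Hz the upper two, vHFO > 250 Hz the last —
an identity the tests assert exactly.

## Modulation index

Among the many phase–amplitude coupling estimators, the package adopts
the **mean vector length**: $\mathrm{MI} = |\,\mathrm{mean}(A(t)
e^{i\phi(t)})\,|$ with $\phi$ from the 3–4 Hz analytic signal and $A$
the envelope of the $f$–300 Hz band.  The choice is deliberate: it is
the estimator with a closed form on the synthetic family ($A_0 m / 2$),
it is linear in signal amplitude (tested as exact scale equivariance),
and it needs no binning or surrogate tuning.  Its known drawback —
amplitude units rather than a normalized quantity — is immaterial here
because downstream use is either z-normalization against the atlas or a
within-patient subtraction, both of which remove the scale.

## Normative atlas

What counts as a *high* HFO rate varies across cortex, so channel values
are z-scored against the `k = 60` closest non-epileptic sites (outside
the seizure-onset, lesional, and spiking zones) pooled across the
cohort.  Distances are Euclidean in template millimetres — a geodesic
cortical-surface metric would be anatomically richer, but it requires a
mesh and introduces mesh-dependent nondeterminism; Euclidean distance is
deterministic, and the k-sweep analysis shows classification accuracy is
insensitive to the neighbourhood definition beyond ~60 sites (range of
in-sample AUC over $k \in [60, 100]$ under 0.05 on homogeneous
cohorts).  Ties break by site index, queries of atlas sites leave
themselves out, and a one-sided outlier rule drops neighbour values more
than 10 SD *above* the mean (one pass).  A useful arithmetic fact: a
lone outlier among $k$ values has z at most $(k-1)/\sqrt{k}$, so the
10 SD rule can only ever fire for $k > 101$ — it is an extreme-tail
guard, not routine trimming.  When the neighbourhood variance is zero
(e.g. no events anywhere nearby), the z-score is reported as `NA` and
propagates to an `NA` patient biomarker rather than a fabricated value.

## Subtraction biomarkers and outcome models

The patient-level statistic is the mean biomarker over resected channels
minus the mean over preserved channels (artifact channels excluded).
Four variants enter the models: raw rate, z-rate, raw MI, z-MI.

Outcomes are modelled by maximum-likelihood logistic regression of
surgical success on ten clinical covariates (age, sex, seizure
frequency, drug count, laterality, MRI lesion status, habitual-seizure
capture, completeness of seizure-onset-zone resection, resection
location and size), optionally augmented with one Subtraction biomarker.
Reported per fit: odds ratios with Wald 95 % intervals, Cox–Snell and
Nagelkerke $R^2$, a likelihood-ratio model p, and a separation flag
(separation is flagged, never silently penalized).  The ROC machinery is
authored in-package because it is part of the validated surface: the
trapezoidal AUC is proved equal to the Mann–Whitney U probability on
every fixture, model comparison uses a t-test of per-threshold
sensitivity×specificity products against the chance value 0.25 (with
Bonferroni correction for the family size), generalization is measured
by leave-one-out cross-validation, and calibration is summarized by
decile bins plus the observed success frequency among high- (> 0.8) and
low- (< 0.2) confidence predictions, with a Spearman rank test of
predicted probability against the ordinal outcome class.

## The synthetic cohort and problem sizes

`simulate_cohort()` generates electrodes on a 70 mm hemispheric patch
with a spatially clustered epileptic zone, channel-level *true* rates
(log-normal, epileptic channels scaled by a multiplier, default 4) and
observed Poisson counts, true and noisy MI values, ten clinical
covariates with realistic marginals, and an outcome drawn from a
logistic model whose coefficients act on cohort-centred covariates (so
the intercept pins the baseline success rate).  The resection cap covers
the epileptic cluster exactly when the "SOZ fully resected" covariate is
true, tying the biomarker to the outcome mechanism.  The full truth
tables ship in the bundle, so every planted rate and outcome probability
can be recomputed exactly — the invariant the cohort tests assert.

The simulator works at the *biomarker* level: channel rates and MI
values are drawn directly rather than synthesized as signals.  This is a
design decision about scale: a cohort of 135 patients × ~100 channels ×
5 minutes at 1 kHz is ~10⁷ samples per channel and tens of gigabytes per
cohort, which no test budget supports — and the signal chain is already
certified separately on planted epochs.  `synthesize_channel()` bridges
the levels on demand: it materializes a signal whose planted event count
matches a channel's truth row, and the tests confirm the detectors
recover those events where they were planted.

Default sizes (135 patients, 32–152 channels, 300 s epochs at 1000 Hz,
k = 60, 10–100 k-sweep) are the package's own choices, picked so that a
full pipeline run and the entire validation suite execute in minutes on
one CPU while keeping every statistic in a regime where its asymptotics
are meaningful.

## What the validation shows — and what it cannot

The test suite certifies: exact rule equivalence of all four detectors
against brute-force oracles; ≥ 0.9 sensitivity at 15 SD burst amplitude
with near-silent background false-alarm behaviour for the two
thresholded-energy detectors; ≥ 0.9 sensitivity and specificity of the
verifier on planted oscillations versus planted transients; the
modulation index within a fraction of a percent of its closed form;
atlas z calibration (mean ≈ 0, SD ≈ 1 on homogeneous sites); the
Subtraction algebra; nominal Wald coverage; the in-sample → LOO
optimism ordering with chance-level LOO on null cohorts; k-stability of
the accuracy beyond 60 sites; and byte-identical reruns.

It does **not** show clinical validity on real intracranial EEG: the
synthetic family is a model of the relevant signal features, not of
patients.  The package's claim is that the *machinery* is correct and
honest; the clinical question needs clinical data.
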