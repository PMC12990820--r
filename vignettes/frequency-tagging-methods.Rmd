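---
title: "Frequency-tagging analysis of visual statistical learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagging analysis of visual statistical learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the scientific choices behind `freqtagsl`: the
generative model of the synthetic data, the analysis statistics, the
parameters that matter and their defaults, the numerical conventions, and
the known limitations — in particular what passing tests on synthetic
cohorts do and do not establish about real infant EEG.

## Stimulus model

Eight abstract shapes stream at 6 Hz in 24-s trials: a 2-s fade-in
(12 shapes), a 20-s triggered core (120 shapes) and a 2-s fade-out. Three
conditions differ only in their transitional-probability (TP) structure.

* **Doublet**: a per-subject random partition of the shapes into four
  ordered pairs. Within a pair the TP is 1; the next pair is drawn
  uniformly among the three other pairs (no immediate repetition), so the
  pair-to-pair TP is 1/3.
* **Control**: a per-subject random split into four first-position and
  four second-position shapes, giving 16 possible pairs; only the
  identical previous pair is excluded from the next draw. The TP from a
  first-position shape to any particular second-position shape is 1/4.
* **Random**: any shape except the immediately preceding one, uniformly —
  a shape-to-shape TP of 1/7.

Successor sampling is uniform over the admissible set. "Pseudo-random"
presentation constrains only immediate repetition; uniformity is the
minimal additional assumption and makes all TPs analytic, which is what
the sequence tests assert. Two consequences of the "exclude only the
identical pair" rule in the control condition are worth noting: pairs
sharing one member may follow each other, and the TP from a pair's second
shape to the next pair's first shape works out to 1/4 at the shape level
(conditionally 3/15 or 4/15 given the previous pair), not 1/3. The
package reports empirical TPs rather than forcing any nominal value.
Fade-period shapes follow the same generation rules and are merely
flagged untriggered; their identities are not otherwise constrained.

`empirical_tp()` summarizes a generated stream by the observed conditional
probability of each successor. Because the observed probabilities in a
row sum to 1 and the admissible successor sets have fixed size, the mean
over observed successors equals the analytic TP exactly once every
admissible transition has been seen — the package's design-math checks
rely on this, not on sampling error bounds.

## Synthetic EEG

Each subject's recording is a channels-by-samples matrix at a configurable
sampling rate (default 1000 Hz; the test suite uses 100–250 Hz):

* **Evoked signal.** A sum of fixed-phase sinusoids at the base
  frequencies (6, 12, 18, 24 Hz) and, in the doublet and control
  conditions, at the doublet frequencies (3, 9 Hz). Steady-state responses
  are modelled as stationary sinusoids rather than convolved transient
  responses; every downstream statistic is amplitude-spectrum based, so
  only the amplitude at the tagged bins matters. Per-channel amplitude is
  scaled by a Gaussian spatial gain (SD 0.045 m) centred on the medial
  occipital sensors, floored at 2% elsewhere.
* **Noise.** 1/f background noise (power exponent 1), synthesized by
  spectral shaping of white noise with a 0.5 Hz low-frequency knee, plus
  log-normal per-channel variance jitter. The noise scale is referenced
  to a 1000 Hz sampling rate (per-sample SD grows with sqrt(fs)), so the
  noise power spectral density — and hence the SNR of a fixed-amplitude
  response — does not depend on the sampling rate. This is what allows
  the tests to run at reduced rates with the same SNR structure.
* **Looking behaviour.** Per-trial looking durations are drawn from
  20 × Beta(1.6, 1) seconds. The evoked signal is present only during the
  fade-in and the first "looked" seconds of the core (the infant looks,
  then looks away); with the default calibration roughly three quarters
  of trials pass the combined validity criteria, matching the
  valid-trial rates typical of this paradigm.
* **Bad channels.** `corrupt_channels()` replaces a configurable number
  of channels (default 18, a typical per-infant interpolated-channel
  count for high-density nets) with high-variance white noise, recording
  ground truth for the repair tests.
* **Between-subject variance.** One log10-normal responsiveness gain per
  subject (SD 0.15) multiplies all amplitudes, producing nonzero ICCs in
  the fitted models.

Default amplitudes are calibration constants, not claims: they were set
once, from a measured amplitude-to-SNR map, so that valid-trial ROI-mean
SNRs approximate the magnitudes reported for this paradigm (combined
doublet-level SNR near 1.9 under the doublet condition, 1.4 under
control, 1.0 under random; 6 Hz SNR around 4–5). Two caveats. First, a
synthetic channel with zero doublet amplitude has expected SNR 1, the
noise floor: values below 1 (as real random-condition infants show) are
sampling fluctuations of real data that the generator does not emulate.
Second, condition effects enter through amplitudes only; there is no
latency, topography-shape, or attentional difference between conditions.

The montage is the published 128-channel geodesic net layout shipped as a
CSV; channel adjacency is 6-nearest-neighbour on the 3-D sensor
positions (no neighbour scheme is prescribed for this net, and k = 6
approximates the geodesic tessellation). Recordings round-trip through
EDF (16-bit, one file per subject) with CSV/JSON sidecars for triggers,
trial metadata and looking durations.

## Preprocessing

A deliberately simplified stand-in for the full robust preprocessing
pipelines used on real infant EEG: average referencing, robust-z
noisy-channel detection (one-sided on channel variance,
`z > 4`) with neighbour-mean interpolation iterated at most 3 times, and
trigger-based segmentation into exact 20-s cores. The rationale: the
downstream statistics depend only on gross channel health, and the
synthetic corruption model is variance-based, so variance outlier repair
is the matching inverse. In the pipeline, channel repair runs *before*
average referencing so corrupted channels cannot leak broadband noise
into the common reference. Line-noise removal is omitted (none is
simulated). Segments are not detrended or tapered: all tagged frequencies
are exact multiples of the 0.05 Hz bin spacing, so spectral leakage is
structural rather than window-dependent, and the SNR statistic is a
ratio of neighbouring bins that shares any residual broadband structure.

## SNR

For a 20-s segment the FFT bin spacing is 0.05 Hz and 6 Hz falls exactly
on bin 120. SNR at a tagged frequency is the amplitude at its bin divided
by the mean amplitude of the 10 surrounding bins — offsets ±2..6, i.e.
5 bins per side excluding the bin immediately adjacent on each side.
Amplitude (not power) is the primary statistic; a raw-power variant can
be derived from the same spectra but is not calibrated against anything.
The neighbour mean is floored at machine epsilon times the spectrum norm
so noiseless synthetic input yields a large finite SNR rather than
infinity. SNR is computed per trial and per channel, then averaged —
over the 3-channel medial occipital ROI (channels 74, 75, 82; the
10-channel set is a config alternative), and over the selected harmonic
sets — consistent with trial-level modelling. Averaging spectra before
SNR would be the alternative convention; it is not the default because
the models operate on trials.

## Valid trials and harmonic selection

A trial is valid when the 6 Hz SNR exceeds 2 (strictly) in at least one
of the 10 predefined occipital channels *and* the infant looked for more
than 7 s (strictly). "Above" bounds are read as strict inequalities; the
boundary cases are tested. Subjects need at least two valid trials.
Orders are renumbered consecutively over each subject's valid trials, and
model analyses keep the longest prefix of orders at which every condition
retains at least 40% of its subjects.

Candidate harmonics in 2–36 Hz are multiples of 6 Hz (base) and odd
multiples of 3 Hz (doublet: 3, 9, 15, 21, 27, 33 — never overlapping the
base family). Selection is a two-sided one-sample Wilcoxon signed-rank
test of per-trial SNR against 1 at level .05, pooling trials across
subjects (the trial is the observation unit; a subject-mean variant is a
one-line change on the input table). Base candidates pool all conditions;
doublet candidates pool doublet and control only, since no doublet-rate
response exists under random. On null (white-noise) cohorts the per-
candidate false-selection rate is close to the nominal level — slightly
above it, because the null SNR distribution is mildly right-skewed around
1 rather than symmetric; the acceptance suite measures this.

## Maximum statistics

Whole-scalp significance uses the permutation maximum statistic: the
observed statistic is the per-channel mean SNR over units (a subject's
valid trials at the individual level; subjects at the group level), and
each permutation independently replaces each unit's topography with the
all-ones unit topography with probability 1/2, records the maximum over
channels of the surrogate mean, and the threshold is the empirical
(1 − alpha) quantile (higher order statistic, reproducible under a fixed
seed) of 10,000 such maxima. Significance uses a strict inequality, and
the all-zero mask is allowed (its influence at 10,000 permutations is
negligible).

A property of this surrogate scheme that users should understand: the
replacement value (exactly 1) carries no sampling variance, so surrogate
means are systematically less dispersed than the observed all-real mean,
and on *null* data the scheme is anticonservative — Monte-Carlo runs in
the test suite measure a family-wise positive rate of roughly 0.3 rather
than 0.05 on white-noise cohorts of 10 units. It behaves as a detection
heuristic whose thresholds scale with the data (strong responses inflate
the null maxima and raise the bar), not as an exact test. The package
therefore also implements `method = "signflip"`, which reflects each
unit's topography about the unit topography (SNR → 2 − SNR), the
standard one-sample permutation scheme; it is exact under a symmetric
null and measures near-nominal (slightly inflated by the right skew of
null SNR). The masking scheme remains the default because it is the
procedure this analysis tradition uses; conclusions drawn from it on
real data should rest on the localization pattern, not the nominal
alpha. A further practical limit: with n units there are only 2^n masks,
so with fewer than about 6 units the observed mean cannot exceed the
null's upper tail and nothing can reach significance.

## Mixed-model ladder

The analysis table holds one row per valid trial (orders 1..K): log10
base-level SNR, log10 doublet-level SNR (both right-skewed on the natural
scale), and the untransformed learning index (their ratio; the index is a
ratio of like quantities and is modelled as-is, with a log variant left
to the user). Condition uses simple coding — treatment contrasts shifted
to sum to zero — so the intercept is the unweighted grand mean of the
condition means; age is expressed in years to keep coefficients
comparably sized.

`fit_ladder()` starts from a random-intercept-only model and adds, in
order: trial order, condition, age, and the condition-by-order
interaction (bringing in any missing main effects). Each candidate is
compared to the current model by likelihood-ratio test on ML fits and
adopted when significant with a lower AIC; the selected model is
refitted by REML for the reported estimates (ML is required for valid
LRT comparisons between fixed-effect structures; REML gives the less
biased variance components for reporting). Singular fits are flagged,
not hidden. Wald 95% CIs accompany Satterthwaite t tests. ICC is the
random-intercept variance over the total. `post_hoc()` produces
Tukey-adjusted pairwise condition contrasts, per-condition means
back-transformed through 10^x for the log outcomes, and — when the
interaction is retained — pairwise slope contrasts and condition
comparisons at fixed orders (1, 5, K). Degrees of freedom are
Satterthwaite throughout (the `emmeans` default for these models is
reported alongside each contrast).

`simulate_snr_table()` draws tables directly from this generative model
(condition means 0.272/0.134/−0.047 on log10 doublet SNR, a −0.025
per-order slope on base SNR, and variance components giving ICCs near
0.23/0.08 — magnitudes typical of this paradigm). It is the workhorse of
the parameter-recovery simulations: 200 cohorts of 10 subjects per
condition with 9 valid trials recover the doublet > control > random
ordering and the negative base-level slope in well over 90% of runs, and
a 1:3 variance ratio yields ICC estimates within 0.05 of 0.25.

## Problem sizes and numerical conventions

The shipped tests simulate at 100–250 Hz sampling with 2–9 subjects and
2–8 trials per subject for the end-to-end paths, 500 Monte-Carlo cohorts
for the error-rate measurements (1000 permutations each), and 200 cohorts
for the model-recovery suites; these sizes make every stochastic
assertion's Monte-Carlo error small relative to its band. Sequencing
checks use 10,000–50,000-shape streams. Tagged frequencies are validated
to lie exactly on bins (no interpolation is ever performed); ties in
dominant-frequency selection resolve to the lower frequency; quantiles of
permutation nulls use the higher order statistic; all randomness flows
through R's global RNG so a single `set.seed()` reproduces any result,
and `run_pipeline()` records the seed and a config hash in its manifest.

## Limitations

The synthetic cohort emulates amplitude structure, spatial weighting,
1/f noise, attention gating and channel corruption — not eye movements,
line noise, non-stationary oscillatory background, inter-subject
topography differences, or any learning dynamics beyond an optional
log-amplitude drift over trials. Passing tests therefore establish that
the analysis machinery is correct and calibrated under its own
assumptions, not that those assumptions describe infant EEG. Coefficients
estimated from real recordings (thresholds, W statistics, model
estimates) depend on the real data and are intentionally out of scope.
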