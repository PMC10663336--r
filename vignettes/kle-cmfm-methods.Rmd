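---
title: "Quantifying cardiac magnetic field map topology with Kullback-Leibler entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac magnetic field map topology with Kullback-Leibler entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Magnetocardiography (MCG) records the heart's magnetic field — of order 10 pT
— over the chest wall with SQUID magnetometers. Sampling the field component
perpendicular to the chest on a regular sensor grid yields a cardiac magnetic
field map (CMFM): a time-resolved spatial image of the currents of the cardiac
cycle. Myocarditis disturbs ventricular repolarisation, and with it the
spatial topology of the field during the STT interval (end of the S wave to
end of the T wave). Two qualitative facts make a simple statistical pipeline
work: healthy subjects' maps are very similar to one another, while each
pathological map is distorted in its own subject-specific way.

`mcgkle` implements the full analysis chain on a common map format — a 6 x 6
grid covering about 20 cm x 20 cm, 1,000 samples at 1,000 Hz per averaged
beat, R peak aligned at sample 333 — together with a synthetic cohort
generator, so every stage can be exercised, calibrated and stress-tested
without access to patient recordings.

## The pipeline

**Beat averaging.** A multi-beat recording with R-peak annotations is cut
into windows of 333 samples up to and including the R peak plus 667 after,
and averaged per channel (`average_beats()`). Averaging n beats reduces
uncorrelated sensor noise by sqrt(n). Input at other sampling rates is
linearly resampled onto the 1,000 Hz grid first; beats whose window overruns
the recording are dropped, never padded. A per-channel baseline (mean of the
first 100 samples of the map, a pre-QRS quiescent stretch) is subtracted by
default; the window length is a package choice, as acquisition software
conventions vary.

**QRS-strength normalisation.** The factor
gamma = (1/36) sum_i (1/t_QRS) sum_t |B[i, t]|, with the inner sum over the
closed QRS window (both cursors included, t_QRS = number of samples),
captures the overall field strength during depolarisation. Dividing the map
by gamma (`normalize_map()`) cancels sensor-to-heart distance differences:
any positive rescaling of a map normalises to the same result, and the
operation is idempotent. The closed-interval convention is asserted by a
worked example in the tests (two positions with QRS samples {1,2,3} and
{0,0,6} give gamma = 2 exactly).

**Segment extraction** (`extract_segment()`). Two variants, as used in
practice: *fixed* windows of 80 ms from QRS onset and 250 ms from STT onset
(pure slices, no interpolation), and *length-normalised* windows that
linearly resample the full cursor-to-cursor segment onto 20 (QRS) or 40
(STT) equispaced points including both endpoints. Length normalisation
removes between-subject differences in segment duration and reduces the
correlation between neighbouring time points; `intersample_correlation()`
reports the maximum absolute between-feature correlation as a diagnostic
with a configurable warning threshold (default 0.2). The threshold is a
report, not a gate: the sample counts 20/40 are the published configuration
and are not re-selected automatically.

**KLE features** (`to_distribution()`, `kl_entropy()`, `kle_features()`).
At each time point within a segment, the 36 map values are converted to a
probability distribution and compared with a reference distribution via
KL(P, Q) = sum_i P_i ln(P_i / Q_i) (natural log; values in nats). The
reference map Q (`build_reference()`) is the element-wise mean of the
reference group's segment maps — normally the healthy controls. How a signed
field becomes a distribution is a genuine design choice; the default takes
absolute values (preserving the positions of the field poles, which carry
the discriminative topology), adds a smoothing mass of 1e-6 times the
slice's maximum (so the conversion is scale-invariant and the logarithm is
always defined), and normalises to unit sum. `square` and `minshift`
strategies are available; all results record the strategy used. A subject
equal to the reference — or a positive multiple of it — scores exactly zero
at every time point.

**Classification** (`lda_fit()`, `kle_loocv()`). Two-class Fisher LDA with
equal priors: w = S^-1 (mu1 - mu0) with S the pooled within-class
covariance, threshold at the midpoint of the projected class means. A ridge
term S + lambda tr(S)/p I (default lambda = 1e-3) keeps the 40-feature fit
defined at cohort sizes of a few dozen. Validation is leave-one-out with
strict leakage control: for every fold the reference map is rebuilt from the
training-fold members of the reference group only, all training features are
recomputed against it, and the held-out subject only ever meets the fold's
own reference and model. A sentinel test asserts this: perturbing only the
held-out subject leaves that fold's trained model bit-identical. Whether the
original analyses excluded the held-out subject from the reference is not
something the published record states; the strict choice is the defensible
one, and it is a possible source of small differences from published
accuracies. Sensitivity, specificity and accuracy use the
pathology-positive convention; undefined ratios are reported as `NA`, never
silently zero.

**Confound checks.** `heart_rate_test()` compares per-subject mean heart
rates (from R-peak intervals) between groups with a two-sided Mann-Whitney U
test — sinus tachycardia is a symptom of acute myocarditis, so a
non-significant result is the precondition for attributing classification to
map topology. `segment_length_test()` does the same for native segment
durations. The U test uses the exact null distribution when both groups have
at most 20 observations and no ties, and the normal approximation with
continuity and tie corrections otherwise, so p-values are bit-reproducible.

## The synthetic cohort generator

The generator (`cohort_spec()`, `simulate_cohort()`) stands in for
non-deposited patient cohorts. Its physics is deliberately minimal: a single
equivalent point magnetic dipole whose moment traces two compact-support
phases per beat — a fast, large-moment rotation over the QRS window and a
slower, smaller rotation (40% amplitude) over the STT window — evaluated
through the magnetostatic dipole equation at a 6 x 6 grid 10 cm above the
heart-centred origin, perpendicular component only. No torso volume
conductor, no lead fields: the analysis needs plausible rotating-map
topology, not biophysical fidelity.

Default study conditions, chosen once during design and then frozen:

* **Group sizes** 57 healthy / 40 pathology, the structure of a single-centre
  case-control study.
* **Healthy variability** (`healthy_jitter = 0.05`): each subject perturbs
  the canonical trajectory's amplitudes, angles and dipole position by ~5%
  — a tight healthy cluster.
* **Pathology mechanism** (`effect_size = 2`): the dipole moment is rotated
  *within the sensor plane* during the STT interval by a subject-specific
  angle, uniform on (-pi, pi) at full effect (scaled down linearly below
  `effect_size = 2`), so each pathological map is unique. Two properties of
  this family matter. In-plane rotation relocates the field poles without
  changing the pattern class, so pathological maps remain the same *kind* of
  map as healthy ones — out-of-plane rotations or dipole displacement were
  found to create a second pattern class that made the groups separable
  against *any* reference, which real data do not show. And uniform angles
  cancel in the group mean, so a reference map built from the pathology
  group averages away the canonical topology — reproducing the observed
  collapse of classification under a pathology-built reference. The
  perturbed interval is configurable (`pathology_target`), defaulting to
  STT because repolarisation is where myocarditis acts.
* **Beats and noise** (`n_beats = 30`, `beat_noise_sd = 900` in the
  generator's arbitrary field units, QRS peak ~2000): a 30-second resting
  recording at ~70 bpm whose averaged maps carry realistic residual noise —
  calibrated by a pilot grid so that LOOCV accuracy on the STT segment
  lands near 0.8 at these group sizes, the regime reported for real
  cohorts, rather than in a noise-free regime where every configuration
  saturates.
* **Heart rate** 70 +/- 6 bpm and **segment lengths** QRS 90 +/- 8 ms,
  STT 300 +/- 30 ms, identical in both groups: segment duration and heart
  rate carry no class information, so the confound tests must come out
  negative on average.
* **Seeds**: one master seed; per-subject seeds are derived by hashing the
  subject id and avalanche-mixing (murmur3 finalizer) with the master seed.
  Cohorts are therefore extensible without reshuffling existing subjects.
  The mixing step is load-bearing: feeding blocks of *consecutive* integers
  to R's Mersenne-Twister produces small cross-correlations between streams
  that are enough to bias cohort-level rank tests away from their nominal
  size.

What the generator does *not* emulate: hardware-specific filter artefacts
and ringing, P waves (only QRS and STT are analysed), baseline drift,
non-Gaussian or spatially correlated sensor noise, and any real
electrophysiology of myocarditis. Passing tests on synthetic cohorts
therefore show that the pipeline detects subject-specific STT topology
distortions of the kind and size the generator produces — they do not
certify clinical performance.

## Numerical choices and degenerate inputs

* Interpolation everywhere is linear (`stats::approx`): resampling to
  1,000 Hz, segment length normalisation, dipole trajectory evaluation.
* The QRS window entering the normalisation factor is closed at both
  cursors; t_QRS is counted in samples. At 1,000 Hz samples and milliseconds coincide; after resampling
  the samples convention is used.
* An all-zero map slice cannot be converted to a distribution and raises an
  error naming the time point; an identically-zero QRS window makes
  gamma = 0 and normalisation refuses it. Both arise only for degenerate
  inputs (e.g. exact cancellation), not for noisy data.
* `kl_entropy()` validates that inputs are strictly positive and sum to 1
  within 1e-9.
* A singular pooled covariance with lambda = 0 is an error advising
  regularisation rather than a silent pseudo-inverse.
* PCA (`pca_project()`) fixes signs so each component's largest-magnitude
  loading is positive, making projections reproducible across platforms.
* All file writes are atomic (write-temp-then-rename), artefacts embed a
  configuration fingerprint, and averaged maps serialise at %.17g so a
  write-read cycle is bit-exact.

## Problem sizes used by the test suite

The shipped tests run the full chain at desk scale, as the package's own
choice of test conditions: null-calibration uses 100 replicate cohorts of
30 + 30 subjects with 6 beats each (chance behaviour and test size do not
depend on beat count); the headline-pattern and reversed-reference checks
use three fixed-seed replicates of the full 57 + 40 cohort at the default
30 beats, comparing replicate means because single-cohort LOOCV accuracy at
n = 97 varies by about +/-0.05 between cohorts; Monte-Carlo checks of the
averaging law use 40 repetitions of 4-beat recordings. `scripts/acceptance.R`
regenerates the default cohort from a command-line seed and recomputes every
headline quantity from scratch.

## Known limitations

* The distribution conversion underlying the KLE is not uniquely determined
  by the published record; results can shift between `abs` and `square`
  strategies. The default is stated in every artefact.
* Per-fold reference rebuilding is stricter than what some published
  analyses may have done; accuracies here are conservative.
* KL entropy is not a metric (asymmetric, no triangle inequality); absolute
  feature values are only meaningful relative to a stated reference group.
  Symmetrised divergences are deliberately out of scope.
* The LDA is two-class with equal priors; prevalence-weighted priors,
  other classifiers, and automatic feature selection are out of scope.
* With 40 features and fewer than ~100 subjects the discriminant is
  ridge-stabilised; reported accuracies depend mildly on lambda.
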