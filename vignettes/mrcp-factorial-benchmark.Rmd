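---
title: "Benchmarking MRCP detection: bands, spatial filters, and detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking MRCP detection: bands, spatial filters, and detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A movement-related cortical potential (MRCP) is a slow negative EEG
deflection, largest near the vertex (Cz), that builds up during the second
or two before a voluntary movement. Detecting it in single trials of
self-paced EEG is the core problem of asynchronous brain-computer
interfaces for movement rehabilitation: the system must notice that the
user is about to move without any cue or trial structure. Detection
performance depends heavily on three preprocessing/classification choices
that interact with one another:

* the **frequency band** the EEG is filtered to (MRCPs live below ~5 Hz);
* the **spatial representation** — no filtering (NoF), surface Laplacian
  (SL), independent components (ICA), a common-spatial-patterns projection
  (CSP), or principal components (PCA);
* the **detector** — shrinkage LDA, a grid-searched SVM, one-nearest-
  neighbor with Euclidean (1-NN-ED) or band-constrained DTW distance
  (1-NN-DTW), a matched filter (MF), or DTW-barycenter template matching
  (TM).

`mrcpbench` implements the full factorial benchmark over five 1-Hz bands
spanning 0.01-5 Hz, the five spatial representations, and the six
detectors, scored by the F1 of MRCP-epoch detection and analyzed with a
three-way repeated-measures ANOVA. Because real recordings cannot be
bundled, a synthetic session generator with known ground truth stands in
for the data; every stage of the pipeline is testable against that ground
truth.

## The pipeline

For each subject (one `EEGSession`) and band:

1. **Causal band filtering.** A forward-only second-order Butterworth
   band-pass per channel (`bandpassSession`). The order is fixed at 2:
   higher-order IIR band-passes with a 0.01 Hz edge at fs = 1024 Hz are
   numerically fragile. The implementation verifies the filter's pole
   moduli and refuses unstable designs, suggesting an equivalent high-pass
   + low-pass cascade.
2. **Decimation (optional, default on at 64 Hz).** All analysis bands live
   below 5 Hz, so epochs decimated to 64 Hz (anti-aliased,
   `decimateSession`) carry the same information in 128 samples instead of
   2048. This is what makes the 2,010-cell grid tractable on one CPU; the
   native rate is available by setting `decimateTo = NULL`.
3. **Segmentation** (`segmentSession`): one MRCP epoch covering the 2 s
   before each movement onset and one non-MRCP epoch covering the 2 s after
   the offset. Trials whose onset comes less than 4 s after the previous
   offset are dropped entirely; epochs that would leave the recording are
   dropped individually. Every drop is logged.
4. **z-normalization** (`zNormalizeEpochs`): per channel and epoch, mean 0
   and *population* (1/N) SD 1. The population convention is a documented
   constant; whether normalization is per channel or per whole epoch is not
   dictated by the protocol, and per channel was chosen.
5. **Stratified split** (`stratifiedSplit`): per class, a seeded shuffle
   with `floor(2/3 n)` epochs to training (so pooled totals of 184/163
   yield 122/108 train and 62/55 test).
6. **Spatial fitting on the training partition only** (`fitSpatial`),
   giving 19 (NoF) + 9 (SL) + 19 (ICA) + 19 (PCA) + 1 (CSP) = 67 candidate
   single-channel representations.
7. **Detector fitting per representation** (`fitDetector`), prediction on
   the test partition, and F1 scoring — 67 x 6 rows per band, 2,010 rows
   per subject over the five bands, reduced to 150 best-channel cells by
   argmax F1 (ties to the lowest channel index).

Two design points deserve emphasis:

* **Threshold calibration.** MF and TM need a decision threshold. It is
  calibrated by maximizing F1 on the *training* statistics (exhaustive
  sweep over midpoints of sorted distinct values; `statistic >= threshold`
  predicts MRCP, lowest maximizing threshold wins). Calibrating on the test
  set is optimistic model selection; it is available as an explicit opt-in
  (`thresholdOn = "test"`) for comparison, never the default.
* **Channel selection.** The best channel per cell is chosen by test F1.
  This mirrors the original benchmarking protocol and is reported as such;
  it is model selection on test data, so the 150-cell table is a relative
  comparison of configurations, not an unbiased estimate of deployment
  performance.

## The spatial representations

* **SL** uses the fixed unit-distance stencil: surrogate = working channel
  minus the mean of its montage neighbors, for the nine interior 10-20
  channels (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4). The neighbor graph (the
  customary 4-neighborhood on the 10-20 grid, 3-5 neighbors per channel) is
  shipped as `extdata/montage_1020.tsv` and is configurable; the graph is
  validated for symmetry at load.
* **ICA** is FastICA (deflation, tanh contrast) on the concatenated
  training epochs, seeded, with automatic re-initialization on
  non-convergence. Components are applied to test epochs with the training
  unmixing matrix — no test data enter the fit.
* **CSP** averages trace-normalized per-epoch covariances per class, adds a
  ridge of `1e-6 * trace/p`, and keeps the single whitened eigenvector
  maximizing the MRCP/non-MRCP variance ratio (a flag flips the favored
  class; which class the original "first row" favored is not documented).
* **PCA** takes all 19 eigenvector rows of the pooled training covariance.
* All filter rows are sign-normalized (largest-magnitude element positive)
  so repeated fits are bit-identical.

## The detectors

Feature vectors are the raw (decimated) sample vectors of the selected
representation. With 128 samples and a few dozen to a few hundred training
epochs, LDA uses a ridge/shrinkage pooled covariance (`lambda = 1e-3`
toward the average variance) rather than a plain inverse. The SVM grid is
fixed and documented — kernel in {linear, RBF}, C in {0.1, 1, 10, 100},
gamma in {1/(p·var), 0.01, 0.1} — selected by mean F1 over a seeded
stratified 3-fold inner cross-validation of the training set. DTW uses a
Sakoe-Chiba band of r = 10% with squared point costs; TM's template is the
DTW-barycenter average (DBA) of the training MRCP epochs, initialized at
the medoid, at most 10 refinement iterations with a 1e-4 relative
tolerance, and its statistic is minus the constrained DTW distance to the
template. MF's template is the arithmetic mean, and its statistic the
maximum of the same-length convolution with the time-reversed template.
Nearest-neighbor ties break toward the lowest training index.

## The synthetic generator

`generateSession` emulates the recording protocol: 19 channels of 10-20
EEG at 1024 Hz, self-paced ballistic dorsiflexion trials separated by
idle gaps drawn uniformly from 3-7 s, and one EMG channel whose bursts
(rectified white noise under a strictly positive raised-cosine envelope,
10x the baseline SD, 0.5 s) mark onsets and offsets. Each trial adds a
slow negativity ending at the onset: by default a linear descent to
`-mrcpAmplitude` over 2 s with a 0.5 s rebound (a half-cosine descent is
available), scaled per channel by a spatial spread of 1.0 at Cz, 0.6 at
the Fz/Pz/C3/C4 ring, 0.3 elsewhere. Background noise is pink (1/f) by
default, independent across channels, with SD 1; the MRCP amplitude is
therefore expressed in baseline-SD units. Defaults were chosen once so
that detector rankings are non-degenerate — zero amplitude is
indistinguishable from noise, amplitude 2+ approaches ceiling — and were
not revisited.

What the generator deliberately does **not** emulate: volume-conducted
(spatially correlated) background activity, ocular/cardiac artifacts, and
non-stationary noise. Two consequences matter for interpreting green
tests. First, with spatially independent noise the surface Laplacian
gains no noise-suppression advantage, so the synthetic benchmark does not
reproduce the empirical superiority of SL + [0.01-1] Hz on real
recordings; the grid's winning combination on synthetic cohorts is not
evidence about real EEG. Second, because epochs are z-normalized per
channel *before* spatial filtering, a very strong deflection drives every
channel toward the same normalized ramp, and the Laplacian of a diffuse
source cancels: localization experiments therefore use an explicitly
*focal* source — `focalSpatialSpread` puts 1.0 at the focus, 0.35 at its
montage neighbors, 0.1 elsewhere — at amplitude 2.5, which the SL
channel-F1 map recovers at Cz in >= 8 of 9 subjects and follows to Fz
when the focus is moved.

Event labelling on synthetic EMG replaces visual inspection with a
threshold rule (`detectEmgEvents`): rectify, smooth with a 50 ms moving
average, take maximal supra-threshold runs, merge runs closer than 0.5 s,
then refine edges on the raw rectified trace against a robust 3-MAD
baseline. On noise-free sessions this recovers the ground-truth onsets and
offsets with zero sample error; with the default noise it stays within
~0.15 s.

## The statistics stage

`rmAnova` implements the classical univariate repeated-measures
decomposition for balanced complete within-subject factorials: every
effect is tested against its own effect-by-subject interaction, and the
Greenhouse-Geisser epsilon is computed per effect from the covariance of
that effect's orthonormal contrast scores, `eps = tr(S)^2 / (q tr(S^2))`
clipped to `[1/q, 1]`. In a balanced complete design the reported Type III
sums of squares coincide with the sequential ones. Missing grid cells are
imputed by the subject's own cell mean for the ANOVA stage only
(`factorialResponse`); raw tables are never imputed. Post hoc comparisons
are paired t-tests with Bonferroni multiplication (clipped at 1) at
alpha = 0.01, and `estimatedMarginalMeans` averages over the remaining
factors with subject-level standard errors. The implementation is
cross-checked in the test suite against `aov()` error strata and
`car::Anova`'s univariate GG corrections on small designs, against the
paired-t-squared identity at two levels, and against longhand classical
formulas on a fixed five-subject dataset; under a simulated global null
(n = 9) the GG-corrected type-I error at alpha = 0.01 stays below
nominal for every effect line.

## Problem sizes and numerical choices

The shipped experiments are desk-scale by design: the full-factorial runs
use 19-channel cohorts of 16-24 trials per subject at 64 Hz decimation
(the grid's 2,010/150 cardinality is a property of the design, not of the
trial count); the localization experiments use 9 subjects x 60 trials;
ANOVA simulations use 9 x 150 response matrices with 200 replicates for
power and 2,000 for null calibration. Tie-breaks are deterministic
everywhere (first argmax for channels and thresholds, lowest index for
nearest neighbors), every random step takes an explicit seed, and repeated
runs with the same configuration are byte-identical.

## Known limitations

* Synthetic cohorts cannot validate the *empirical* ranking of bands,
  filters, and detectors on human MRCPs — only the machinery that computes
  and analyzes such rankings.
* CSP on slow non-oscillatory deflections is variance-based and known to
  be a weak representation for MRCPs; it is included for completeness of
  the factorial design.
* The EDF writer targets plain continuous 16-bit EDF and is not a general
  EDF+ implementation.
* `rmAnova` requires a balanced complete design (after imputation); it is
  not a mixed-model replacement for unbalanced data.
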