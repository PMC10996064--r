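---
title: "Wavelet-coherence interaction statistics and nested LOOCV prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-coherence interaction statistics and nested LOOCV prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and the numerical choices behind
`dynfc`: how the dynamic interaction statistics are defined, what the
synthetic-cohort generator does and does not emulate, and where the
design was genuinely open.

## Signals and preparation

The pipeline consumes per-subject network time-series: a T × N matrix
(default T = 380 volumes at TR = 1.35 s, N = 14 functional brain
networks) whose columns play the role of ICA-derived network signals.
Two preparation steps are provided.

**Multi-echo combination.** With echo times TE₁…TE₃ (defaults
11.3, 31.8, 52.3 ms), each voxel's echoes are averaged with weights

$$w_n = \frac{TE_n\,e^{-TE_n/T_2^*}}{\sum_i TE_i\,e^{-TE_i/T_2^*}},$$

where T₂\* is estimated per voxel by unweighted least squares on
ln S = ln S₀ − TE/T₂\* (`fit_t2star()`). The log-linear fit is exact for
noiseless mono-exponential decay; fits with non-positive or numerically
flat slope (≤ 1e−9 per ms) are replaced by the median T₂\* of the valid
voxels (or a user-supplied fallback) and flagged rather than dropped.
Weights are non-negative, sum to one, and are invariant to rescaling the
signals, so the combination is convex and linear.

**Temporal filtering.** A second-order zero-phase Butterworth bandpass
(0.01–0.2 Hz at the default TR; `bandpass()`) is applied
forward-backward. The series is padded by odd reflection (up to
3·(6·order + 1) samples) before `signal::filtfilt` so edge transients do
not leak into the scan; the output has exactly zero phase shift, which
the tests pin via the lag-0 cross-correlation peak. Filtering twice
attenuates pass-band amplitude by at most the square of the single-pass
gain — the filter is deliberately *not* idempotent.

## Activation features

`build_design()` convolves one boxcar per condition (rest, shapes,
faces) with a canonical double-gamma HRF (response peak 6 s, undershoot
peak 16 s, ratio 6 — the common default; the choice is not critical for
the block design used here) and appends an intercept plus any nuisance
matrix unchanged (the 25 physiological/motion regressors of the full
design give 28 modeled regressors besides the intercept). Rest is
modeled explicitly; contrasts are expressed against it (Faces > Rest)
or between conditions (Faces > Shapes). `glm_tvalues()` returns the
contrast t-statistic with residual df = T − rank(X); a numerically zero
residual variance with a non-zero contrast yields a signed infinity and
a flag instead of an error, since a perfectly fitting regressor is a
legitimate degenerate input. ROI means over 11 regions × 2 contrasts
give the 22 activation elements.

## Static and dynamic connectivity

Static FC is the Fisher transform z = atanh(r) of the full-length
Pearson correlation; |r| is capped at 1 − 1e−15 so self-pairs stay
finite. Dynamic FC slides a tapered window — a 30-TR rectangle convolved
with a Gaussian (σ = 3 TRs, truncated at ±3σ, cut to its central 30
samples, normalised) — in steps of 1 TR and computes the taper-weighted
Pearson correlation per window; the dFC statistic is the *population*
standard deviation of the window correlations (the sample variant is a
constant factor away and intentionally not the default). Window starts
run from 1 to T − width, giving 350 windows for 380 volumes, the count
the analysis design is built around. Windows with zero weighted variance
are flagged; if at most 5 % of windows are flagged their correlation is
imputed as 0, otherwise the flagged windows are excluded from the
standard deviation.

## Wavelet coherence, nCC and leadCoh

For each pair, analytic Morlet CWTs (ω₀ = 6, the standard setting
balancing time and frequency resolution) are evaluated on 50 log-spaced
Fourier periods from 2·TR to T·TR/4. The cross-spectrum and both
auto-spectra are divided by scale, smoothed in time with a
scale-proportional Gaussian (sd = scale) and across scale with a 3-bin
boxcar, and combined into magnitude-squared coherence. Smoothing is
FFT-based with zero padding and an edge-correction by a smoothed
all-ones row; the time-smoothing kernels and norms are precomputed once
per grid and shared across the 91 pairs of a subject, which dominates
the runtime budget. The cone of influence is the Morlet e-folding
distance √2·s from either edge; out-of-cone pixels are excluded from all
statistics by default (configurable). Period bins below 5 s (> 0.2 Hz)
are always discarded, matching the upstream bandpass.

Pixels with coherence ≥ threshold are classified by phase φ (positive φ
= first series leads; the convention is pinned by a test in which a
quarter-period delay of the second series produces φ = +π/2):
in-phase for |φ| ≤ π/4, lead for π/4 < |φ| < 3π/4 (direction by sign),
anti-phase for |φ| ≥ 3π/4. Boundaries are closed towards in-phase and
anti-phase; φ = ±π/2 is a lead by the open-interval convention.

* **nCC** binarises the class map (any class ≠ none → 1) and counts
  connected components by flood fill, 8-neighbour adjacency by default
  (4-neighbour available); components smaller than `min_cluster_size`
  (default 1 — a lone coherent pixel counts) are excluded. The count is
  verified against an independent graph-components oracle on 1,000
  random maps in the test suite.
* **leadCoh** sums, per retained period bin, the time (pixels × TR)
  spent in the requested lead direction and averages over retained bins;
  units are seconds.

The coherence threshold (default 0.5) is the one parameter with no
stated value in the source analyses; it is exposed prominently and the
monotonicity of coherent-pixel counts in the threshold is tested. A
Monte-Carlo surrogate threshold was considered and left out of scope:
the fixed-threshold definition is what the cluster statistic needs to be
comparable across subjects.

## Outcomes and the prediction stack

ΔHDRS is the percent change from baseline; ΔHDRS ≤ −50 (boundary
inclusive) labels a positive outcome. The printed criterion in the
source material reads "ΔHDRS ≤ 50 %", which is read as ≤ −50 % (a
decline of at least half), consistent with its own description of
responders; the boundary is test-pinned. The absolute score change is
available for sensitivity analyses; missing follow-ups exclude a subject
from that follow-up, never imputed.

The prediction stack enforces leave-one-out hygiene: per fold, feature
ranking (Kruskal-Wallis or SVM-RFE), z-scoring, SVM/OLS fitting and
probability calibration all use the training subjects only. A deliberate
`leaky = TRUE` mode ranks once on all subjects; a regression test checks
that it measurably inflates null accuracy, which is the failure the
hygiene exists to prevent.

Decisions that the source analyses left open, and how they were fixed:

* **Class weights**: per-class misclassification costs n/(2·n_c), i.e.
  inversely proportional to class frequency, so the majority/minority
  penalty ratio equals the sample-size ratio.
* **SVM probabilities**: a linear SVM has none natively; a logistic
  (Platt) calibration is fitted on training-fold decision values. Under
  perfect separation the calibrated probabilities saturate near 0/1,
  which is acceptable for soft voting.
* **SVM scale**: C = 1, features z-scored per training fold (also before
  SVM-RFE, whose weight magnitudes are otherwise scale-dependent).
* **AUC**: the rank (Mann-Whitney) form on fold-pooled calibrated
  probabilities; per-fold ROC is undefined with one test subject. The
  rank form equals trapezoidal ROC integration (oracle-tested).
* **Kruskal-Wallis in the regression pathway**: the selector needs
  groups, so it uses the training fold's binary outcome labels. The
  vectorised tie-corrected H statistic is cross-checked against
  `stats::kruskal.test` column by column.
* **Ties**: optimal K prefers the smallest K; SVM-RFE and backward
  elimination remove the higher column index first. Everything is
  deterministic given the seed.
* **Backward elimination on saturated fits**: when the residual variance
  is numerically zero (noiseless synthetic cohorts), per-coefficient
  p-values are 0/0; a predictor's p is then taken as 1 when its
  coefficient is numerically zero and 0 otherwise, so inert predictors
  leave first and the generating model is recovered exactly. Among
  steps tied on adjusted R², the smaller model wins.

Ensembles average the two members' positive-class probabilities
(label positive iff ≥ 0.5) or their predicted severity changes.
Correlation p-values use the t-transform with Holm step-down adjustment.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not fMRI physics. Per subject it draws independent unit-variance
Gaussian network noise and superposes, for each planted epoch of a pair,
a shared cosine at the planted period with relative phase 0, ±π/2 or π
(amplitude default 3, i.e. 3× the noise sd — strong, cleanly detectable
coupling). Lead is planted as a quarter-period offset, the centre of the
lead phase class. The 19-block task design is rest-separated with the
shapes/faces blocks alternating (R S F R S F … R); only the counts, not
the order, are fixed by the source description, and the order is
configurable.

Outcomes follow a linear model on *planted interaction counts*: per
pair, integer epoch counts drawn from a rounded normal with mean 13.9
and sd 3.1 (the observed group cluster-count moments), clipped to 5–25;
five pairs (SMN–pVN, pDMN–lVN2, SMN–CN, pDMN–BGN, MTN–BGN) carry the
coefficients (191; −4.51, −3.24, −2.96, −2.64, −2.54) and Gaussian noise
(default sd 10 percent points) is added. Baseline HDRS is truncated
normal (24.5, 4.59, bounds 0–52); the follow-up score is reconstructed
from the percent change and clipped to the scale bounds. Follow-up
scores are kept continuous rather than integer so that the noiseless
model is exactly recoverable by least squares — a deliberate departure
from clinical scoring in favour of testability. Demographics use the
cohort moments (age 43.8 ± 13.4, education 1.5 ± 0.88, etc.); the
anxiety and trauma questionnaire scales use plausible mid-range defaults
since only their existence, not their moments, is specified.

What the generator does **not** emulate: voxel-level 4D volumes, head
motion, physiological noise, autocorrelated (1/f) network noise,
realistic inter-feature correlation structure, or any nonlinearity
between features and outcome. Passing tests therefore demonstrate that
the statistics and the prediction stack behave correctly on data with
known structure — not that the pipeline would reach any particular
accuracy on real patients.

## Problem sizes and determinism

The test suite runs the full geometry (T = 380, N = 14) for single
subjects and scales cohort experiments to what a laptop executes in
minutes: 100-seed recovery and 20-permutation null-calibration runs at
n = 32 with the full K = 1…20 sweep, 200 simulations per planted
phase-relation property, and 1,000 random maps for the cluster-counting
oracle. The RNG is split per subject from the cohort seed (seed + 7919·i
mod 2³¹−57), so cohorts are reproducible subject by subject, including
under partial regeneration. One caveat surfaced by the null-calibration
experiments: selecting the optimal K by maximum accuracy is itself an
optimistic selection, and on label-permuted data the optimal-K accuracy
sits slightly above the majority-class rate (within the tested ±10-point
band). The same caveat applies to any K-swept result on real data.

## Known limitations

* The wavelet smoothing spans (Gaussian sd = scale in time, 3 bins in
  scale) follow common practice; nCC values shift systematically with
  the coherence threshold and the smoothing, so cluster counts are
  comparable only within a fixed configuration.
* SVM-RFE refits one SVM per eliminated column and is the slowest
  selector (91 columns × 32 folds ≈ 3k fits per sweep).
* The full-data backward-elimination model is descriptive, not
  predictive — it sees every subject, as its interface documents.
* With ~20 % responders at n = 32, LOOCV metrics have high seed-to-seed
  variance; single-cohort accuracies should be read with that in mind.
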