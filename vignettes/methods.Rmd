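---
title: "Methods: desk-scale analysis of domain-general inhibitory control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale analysis of domain-general inhibitory control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsuite)
```

## The scientific problem

`stopsuite` implements, at desk scale, the analysis chain used to ask
whether stopping actions and stopping thoughts draw on a single,
domain-general inhibitory control system in the right lateral prefrontal
cortex. The chain couples two behavioural paradigms — the stop-signal task
(stopping prepared motor actions) and the Think/No-Think task (suppressing
memory retrieval) — with four imaging analyses: brain–behaviour partial
least squares, ROI time-course modulation, cross-task multivoxel pattern
classification, and effective-connectivity model comparison. Every stage
runs on synthetic data with planted ground truth, so the full pipeline is
testable without any imaging download.

## Behavioural models

**SSRT by the integration method.** The stop-signal reaction time is
estimated under the independent race model: all go trials (correct and
incorrect) are pooled, omitted go responses are replaced by the maximum
observed go RT, and the SSRT is the *n*-th fastest go RT minus the mean
stop-signal delay (SSD) over all stop trials, with
*n* = round(N~go~ × p(respond | stop)). Rounding is half-away-from-zero and
clamped to [1, N~go~]; consensus guidelines leave the rounding open, and
this choice is symmetric around .5. The race-assumption check (mean failed
stop RT < mean correct go RT) and the stop descriptives
(p(respond | stop), go omission and choice-error rates, mean SSD) are
reported alongside. The trigger-failure-corrected SSRT is deliberately not
implemented; `race_params()` carries a `p_trigger_failure` field as the
extension hook.

**Suppression-induced forgetting (SIF).** Final recall is conditionalized
on the criterion test (unlearned pairs can be neither suppressed nor
retrieved), recall proportions are computed separately for the same-probe
and independent-probe tests and averaged, and SIF = Baseline − No-Think
recall. Filler pairs are never scored.

**Go-RT slowing.** The slowing check regresses correct go RT on run index
per subject and tests the mean slope against zero. A pooled mixed-model
coefficient is a near-equivalent alternative; the per-subject mean was
chosen because it needs no variance-structure assumptions at n = 24.

## Robust correlation decision tree

All brain–behaviour and behaviour–behaviour correlations pass through one
decision tree (`select_and_correlate()`): Pearson when there are no
outliers and both marginals pass Shapiro–Wilk at α = 0.05; the 20%
percentile-bend correlation when there are univariate outliers or
non-normality but no bivariate outliers; and the MCD-skipped Spearman
correlation when bivariate outliers are present. Univariate outliers use
the 1.5 × IQR boxplot rule; bivariate outliers use a halfspace-depth
bagplot whose fence inflates the 50% bag by a factor of 3 about the depth
median — 3 is the classical fence factor, adopted here because no other
value is standard. Two numerical choices deserve note: the discrete bag is
the ⌈n/2⌉ deepest points with depth ties broken by closeness to the depth
median, and the bag is symmetrised about the depth median before
inflation, because in small samples a single far point skews the sample
depths and would otherwise make the fence one-sided. The MCD uses
h = ⌈(n+3)/2⌉ and an exhaustive subset search for n ≤ 30 (order-invariant
and deterministic); flagged points exceed the χ²(2, 0.975) robust-distance
cut-off.

**JZS Bayes factor.** The one-sample Bayes factor uses a Cauchy(0, 0.707)
prior on the standardized effect δ, restricted to δ > 0 for one-tailed
tests, evaluated by adaptive quadrature (relative tolerance 1e-8);
posterior summaries of δ come from a dense grid (20001 points) over a
range wide enough for any n ≥ 2. B01 > 1 favours the null.

## Behavioural PLS

X (subjects × voxels, an Inhibit > Respond contrast within a mask) and Y
(subjects × behaviours: SSRT and SIF) are columnwise mean-centred; each X
row is scaled to unit sum of squares so between-subject amplitude
differences cannot masquerade as pattern differences; R is the voxel ×
behaviour correlation matrix across subjects, decomposed by SVD. "Mean
centring" is ambiguous between rows and columns in common usage; columnwise
centring is used because the subsequent correlation is columnwise.
Permutation inference permutes Y's rows and compares unrotated singular
values per latent variable with the add-one estimator
p = (1 + #{s\*≥ s}) / (1 + n~perm~) (never exactly zero); no Procrustes
rotation is applied, a known divergence risk from some PLS toolboxes that
matters mainly beyond LV1. Bootstrap resamples subjects with replacement,
sign-aligns each resample's saliences to the original by the dot-product
rule, and reports salience / SE ("bootstrap ratio", read as a z-score,
thresholded at |1.96|) and percentile 95% intervals of the
behaviour-correlation profile. Ratios are computed on singular-value
weighted saliences (the projection of R onto the behaviour weights): the
unit norm of the raw salience vector couples voxels, deflating bootstrap
SEs, and in calibration simulations the weighted form brings the
false-positive rate of the |1.96| threshold close to its nominal 5%
(residual anticonservatism of a few points remains, a known property of
PLS bootstrap ratios). Degenerate resamples are redrawn (bounded
retries).

## ROI time-courses

The modulation index is the mean of the 2, 4 and 6 s peristimulus samples
minus the 0 s sample (TR = 2 s; grid samples, no interpolation — the
simplest reading of a 2–6 s average on a 2 s grid). The region × modality
analysis is a 2 × 2 within-subject ANOVA on the Stop−Go and
No-Think−Think modulation differences; for a 2 × 2 within design every F
is exactly the squared paired t on the corresponding contrast, which is
how it is computed (and cross-checked against a sums-of-squares oracle in
the tests). Cell-wise one-sample tests against baseline are one-tailed in
the below-baseline direction and Bonferroni corrected.

## MVPA

Classification is within-subject, run-wise, two-class LDA. Because 16
patterns never outnumber voxels, the pooled within-class covariance is
shrunk toward a scaled identity with a Ledoit–Wolf intensity estimated
from the data; no regulariser is canonical for this analysis and
Ledoit–Wolf requires no tuning parameter. Pre-whitening multiplies
patterns by the inverse square root of a shrinkage-regularised residual
covariance; in synthetic mode the generator's noise is white, so identity
whitening is exact and prewhiten() is exercised with explicit covariances
in tests.

*Cross-task* (domain-general): train on Stop/Go, test on No-Think/Think
and vice versa; each voxel is z-scored across the 16 training estimates
and, separately, the 16 test estimates, leaving only the relative
Inhibit-vs-Respond contribution. *Between-task* (domain-specific):
NoThink-vs-Stop with leave-one-run-out cross-validation; each pattern is
z-scored across voxels, removing univariate intensity differences between
the tasks. Both schemes average over random 90% voxel subsets (up to the
number of unique subsets; duplicates are redrawn); z-scoring is columnwise
or rowwise respectively, so the voxelwise scheme commutes with subsetting
and is applied once. The per-run conflict-reduction curve trains the
action-stopping classifier on all Stop/Go patterns and scores each run's
No-Think/Think pair separately, honouring missing-run masks; linear
decline is tested with an ANOVA linear contrast using each subject's
available runs, and accuracy slopes are correlated with SSRT and SIF via
the robust decision tree. Group inference is a one-tailed t against the
50% chance level, Bonferroni corrected across ROIs, with the one-tailed
JZS Bayes factor reported for ROIs that do not survive correction.

## Connectivity model space and BMS

The model space holds a null model plus 72 modulatory models over rDLPFC,
rVLPFC, right hippocampus and left M1: intrinsic coupling is bidirectional
between all pairs except hippocampus–M1 (never connected), driving task
inputs enter both prefrontal nodes, and models differ in the Direction of
source–target modulation (bidirectional / top-down / bottom-up; 24 models
each), the Pathways (independent, rDLPFC-only, rVLPFC-only, parallel),
the prefrontal Interactions (none, one-directional either way,
bidirectional) and the Targets (preferred: Stop→M1, No-Think→hippocampus;
non-preferred: swapped). The printed counts (73 total, 24 per direction
family, parallel models at ids 9–12 and 21–24 within the bidirectional
family) do not uniquely determine the remaining composition; the default
resolution gives the independent and parallel pathways all four
interaction variants and the single-source pathways two (none,
bidirectional), isolated in one constructor so an alternative composition
can be injected without touching any other code.

Random-effects BMS estimates a Dirichlet posterior over model frequencies
by the standard variational iteration (subject-wise model posteriors with
digamma-corrected evidences, accumulated into the Dirichlet counts until
they change by less than 1e-6); the prior is one count per model.
Exceedance probabilities are Monte-Carlo argmax frequencies over Dirichlet
samples (default 1e5 draws, a compromise keeping the MC standard error
below ~0.002 at interactive run times); family exceedance sums sampled
mass within families before the argmax, and staged comparisons restrict
the model set exactly as the family sequence dictates.

Because full variational-Laplace inversion of hemodynamic models is out of
scope, synthetic recovery uses a least-squares evidence proxy: each node's
BOLD series is deconvolved by regularised Wiener filtering against the
canonical double-gamma HRF, the discrete-time bilinear system restricted
to the model's edges is fitted by OLS node by node, and log evidence ≈
−BIC/2. Three numerical details matter for this proxy to select models
honestly rather than absorb filtering artifacts into condition-specific
regressors: the FFT is zero-padded to twice the series length so the
deconvolution is an exact linear (non-circular) filter; the exogenous
driving regressors pass through the same convolve-then-deconvolve filter
as the data; and one HRF length is trimmed from the start of the
regression. The regularisation constant (0.005 of peak spectral power)
balances two failure modes diagnosed in development: weaker
regularisation amplifies observation noise in the recovered states, whose
condition-dependent signal-to-noise then lets modulatory regressors
improve the fit of data simulated without any modulation, while stronger
regularisation over-smooths the states and biases selection toward
sparse wrong models. The proxy is labelled as such and is a demonstration
device for synthetic data, not an inference method for real recordings.

## The synthetic-data generators

The generators define the study conditions rather than emulate them
loosely:

* **Population**: true SSRT and SIF are bivariate normal with means
  348 ms and 0.05, SDs 50 ms and 0.09, and correlation −0.5 — the group
  values and effect direction the behavioural analyses should recover.
* **Stop-signal trials**: 384 trials over 8 runs, 32% stop trials, ex-
  Gaussian go finishing times (μ 530, σ 40, τ 70 ms, giving correct go
  RTs near 600 ms), truncated-normal trial-level SSRTs, and a 50 ms SSD
  staircase starting at 250 ms (or 300; configurable) floored at zero.
  Trigger failures default to zero. Go omissions (0.002) and choice
  errors (0.04) match the observed low rates.
* **Recall**: 20 pairs per condition, learning rate 0.71, baseline recall
  0.77, No-Think recall reduced by each subject's true SIF, drawn
  independently for the two probe tests.
* **ROI patterns**: each pattern is noise plus a domain-general direction
  `u` shared by the two tasks within a subject (only the inhibition
  conditions load on it — this shared direction is what makes cross-task
  transfer possible) and a task-specific direction carrying task
  identity. The No-Think loading decays per run (conflict-reduction),
  optionally tied to the subject's true SIF. Default amplitudes
  (g = 2.0/2.1 in the prefrontal ROIs, 0 in hippocampus/M1, specific
  amplitudes 1.6–2.2, 40 voxels, unit noise) were chosen once so that
  group cross-task accuracy sits in the observed high-50s/low-60s percent
  band and between-task accuracy in the 70–80s.
* **Time-courses**: canonical HRF scaled by signed per-ROI, per-condition
  amplitudes (crossover defaults: M1 modulated by action stopping,
  hippocampus by thought suppression) plus white noise; the onset sample
  is zero by construction of the HRF.
* **Evidence matrices**: i.i.d. Gaussian noise plus a planted log-evidence
  advantage on one family. **Network series**: discrete-time bilinear
  dynamics with stability checked via the spectral radius, HRF-convolved,
  with white observation noise.

What the generators do **not** emulate: temporally autocorrelated fMRI
noise, scanner drift beyond optional slow sinusoids, spatial smoothness
of voxel noise, subject motion, or hemodynamic variability across regions.
Passing tests therefore demonstrate the correctness and calibration of the
estimators under the planted model, not robustness to every property of
real data.

Every generator is a pure function of (parameters, seed); a master seed
spawns per-subject and per-stage substreams by fixed arithmetic
(`substream_seed()`), so any stage can be reproduced in isolation and the
pipeline report is bit-identical under a fixed configuration.

## Problem sizes and numerical choices

The shipped configuration runs permutation and bootstrap inference at 500
resamples, voxel-subset averaging at 50 subsets, and exceedance sampling
at 1e5 draws; these desk-scale sizes keep a full pipeline run around a
minute while leaving all inferential calibrations intact (the full-scale
analysis would use 5000 resamples and up to 2000 subsets). Calibration
suites use 100–200 replicate datasets. Degenerate inputs are rejected
with informative errors rather than silently patched: zero-variance PLS
columns name the column, missing ANOVA cells name the subjects, evidence
matrices must be finite, and unstable network coupling (spectral radius
≥ 1) is refused.

## Known limitations

* The SSRT estimator inherits the integration method's small
  underestimation bias when go RTs drift; the blocked variant is not
  implemented.
* The bagplot uses discrete sample depths, not interpolated depth
  contours; its small-sample behaviour is symmetrised as described above.
* Permutation inference compares unrotated singular values; analyses that
  care about LV2+ under strong LV1 signal should add a rotation scheme.
* The evidence proxy assumes the generator's own HRF and white noise; it
  is not identifiable under hemodynamic mismatch and is intended only for
  synthetic demonstrations.
* Between-participant decoding and searchlight analyses are out of scope;
  classifiers are within-subject by design.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(study_config(seed = 1))
report$behavior$mean_ssrt_ms       # near 348 ms
report$mvpa$cross_task             # prefrontal ROIs above chance
report$bms$direction_families      # bidirectional family wins
```
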