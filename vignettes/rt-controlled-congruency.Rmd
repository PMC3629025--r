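---
title: "Controlling neural congruency effects for reaction time: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlling neural congruency effects for reaction time: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtbold)
```

## The problem

In distracter-interference tasks such as the multi-source interference
task (MSIT), incongruent trials produce both slower responses and larger
BOLD responses than congruent trials, most prominently in the posterior
medial frontal cortex (pMFC). Because within-condition BOLD amplitude
also rises with trial-wise reaction time (RT), a conventional
incongruent-minus-congruent contrast confounds stimulus congruency with
time on task: two conditions that differ in mean RT will differ in
frontal activity whether or not any congruency-specific process is
engaged. rtbold implements three complementary procedures that ask
whether a neural congruency effect survives control for conditional
differences in mean RT, together with a calibrated synthetic generator so
that every stage can be validated against known ground truth.

## First-level model

Each participant's data are modelled with a trial-level GLM. For each
condition of interest (correct congruent, correct incongruent) the design
holds a *main* regressor — unit impulses at stimulus onsets convolved
with the canonical double-gamma HRF — and polynomial RT modulators of
orders 1–4, whose impulse weights are powers of the mean-centred RT (in
ms) of that condition. The order-1 coefficient is therefore the RT–BOLD
slope in signal units per ms, the quantity the RT-equating procedure
consumes. Error trials and excluded trials (omissions and RT outliers)
receive their own unmodulated regressors. High-pass filtering is
implemented as per-run discrete-cosine nuisance regressors spanning
periods above the cutoff (default 128 s), which is equivalent to
residualising both sides of the model; serial correlation is handled by
estimating a single AR(1) coefficient per signal from the OLS residual
lag-1 autocorrelation and refitting after prewhitening both sides (one
Cochrane–Orcutt step). An optional 6-column head-motion series is
expanded to the standard 24-parameter set (linear, squared, within-run
derivative, squared derivative).

Trial exclusion follows the conventional correct-trial rule: omissions
and errors are set aside with their own regressors; among the remaining
correct trials, per condition, trials whose RT lies strictly more than 3
conditional sample SDs from the conditional mean are excluded as
outliers. The bounds are computed once, from the pre-exclusion
correct-trial set, in a single pass — no iterative re-computation after
removal. Conditional summaries (the mean RTs used for modulator centring
and for RT-equating) are computed on the retained trials, since those are
the trials the corresponding regressors model. Trials exactly at the
boundary are retained. A condition with fewer than two correct trials has
no defined SD; no outlier exclusion is applied there and a warning is
raised.

Two modelling choices deserve comment. First, error trials are modelled
with a single unmodulated regressor: congruent errors are so rare at
realistic error rates (~0.1%) that per-error RT modulators would be
ill-defined for most participants, and the error regressor exists only to
keep error variance out of the conditions of interest. Second, higher
polynomial orders are sequentially orthogonalized against the main column
and lower orders within their condition (the convention of the major SPM
lineage); this is switchable (`orthogonalize = FALSE`) because both
conventions are in active use, and the contrasts consumed downstream —
the condition mains and the order-1 slope — are insensitive to the choice
when the underlying RT–BOLD relation is linear.

## The three RT controls

**RT-equating** extrapolates congruent activity to the incongruent mean
RT along the within-congruent slope:

$$\widehat{C}_{eq} = \hat\beta_{cong} + \hat\beta_{RT,cong}\,
(\bar{RT}_{incong} - \bar{RT}_{cong}),$$

and contrasts incongruent activity against it,
$\hat\beta_{incong} - \widehat{C}_{eq}$. It is efficient (all trials
contribute) but assumes the RT–BOLD relation is linear; the order 2–4
modulators exist to check that assumption.

**RT-matching** pairs congruent with incongruent trials whose RTs differ
by at most a tolerance window (default 10 ms), pooling trials across
runs, maximizing the number of disjoint pairs. Among the many maximum
matchings the procedure is made deterministic: both lists are sorted by
RT (ties broken by trial id) and swept with two pointers, pairing the
heads when they are within the window and discarding the smaller head
otherwise. For this interval structure the sweep attains maximum
cardinality; an exhaustive brute-force oracle guards that claim in the
test suite. The matched classes are then contrasted in a categorical
model with four trial classes (matched congruent, matched incongruent,
other correct, errors) and no RT modulators — the point of matching is
precisely not to lean on a parametric RT model.

**RT-subsampling** is the statistical-power control: from each RT-sorted
condition list of length $n$ it keeps $k$ trials at uniform strides
(0-based indices $\lfloor jn/k \rfloor$, $j = 0..k-1$), with $k$ set to
the matched-pair count. This equates trial counts with the matched
analysis while preserving each condition's native RT distribution, so a
congruency effect that survives subsampling but not matching cannot be
blamed on trial counts. The floor-stride rule is one natural reading of
"uniform intervals"; a centred variant
($\lfloor (j+\tfrac12)n/k \rfloor$) is available behind the `centered`
flag and differs only in edge emphasis.

At the group level the package uses the summary-statistics random-effects
approach: each participant contributes one effect estimate per analysis,
tested with a two-tailed one-sample t (df = n − 1). The congruency ×
sampling-method comparison is a 2×2 within-participant ANOVA, reduced
exactly to squared paired t statistics on difference and average scores;
an age-covariate ANCOVA (effect ~ intercept + mean-centred age) separates
the congruency effect at the mean age from its age modulation. Sphere
ROIs collect all voxels whose centres lie within the radius (default 8 mm
around the pMFC coordinate x = 2, y = 16, z = 46) and are averaged
without partial-volume weighting.

## The synthetic MSIT generator

The generator emulates the study conditions the analysis is designed for:
5 runs of 24 congruent + 24 incongruent + 12 fixation trials in seeded
random order, 3 s per trial (500 ms stimulus), TR 2 s, so each run spans
exactly 180 s. RTs are ex-Gaussian — the standard descriptive RT model —
calibrated so that condition means are 686.9 ms (congruent) and 969.8 ms
(incongruent) and error rates 0.1% and 8.2%. Only the condition means and
error rates are empirically anchored; the spread parameters
(sigma = 80/90 ms, tau = 130/170 ms, giving conditional SDs of ~153 and
~192 ms) and the 0.5% omission rate are realistic values fixed once in
the defaults. With this calibration a simulated participant retains about
226 correct trials after filtering and the group congruency effect is
close to 283 ms.

BOLD ground truth: each trial contributes a neural impulse of amplitude
`baseline + rt_slope × RT + increment × (incongruent)`, convolved with
the canonical HRF on a 0.1 s microtime grid (3 s trials are not aligned
to the 2 s TR, hence the oversampling) and read out at volume onsets.
Impulses, not 500 ms boxcars, model the neural events — the dominant
convention for brief stimuli; the stimulus duration is recorded in the
events files for models that want it. The series adds within-run cosine
drift (periods 360 s and 180 s, i.e. inside the default high-pass band)
and stationary AR(1) Gaussian noise, parameterized by its marginal SD so
that `noise_sd` is directly the noise amplitude in signal units. The
defaults — `rt_slope = 0.002` signal units/ms, equal zero baselines, zero
increment, `noise_sd = 1`, `ar1 = 0.3` — give a full-data group
congruency effect of ≈ 0.57 signal units (the slope times the 283 ms RT
gap) detected at t-values comparable to empirical event-related ROI
studies. With `increment = 0` the two conditions differ *only* through
RT, which is the null the three controls are supposed to recover; setting
`increment > 0` injects a genuine congruency signal that all four
contrasts should detect.

A volumetric mode places the same signal in every voxel of a sphere on a
small world-aligned grid (default 20 × 20 × 16 voxels at
3.75 × 3.75 × 3.0 mm, centred on the pMFC coordinate) with independent
voxel noise and scanner-wide drift, so ROI extraction is exercised
without whole-brain cost. What the generator does *not* emulate:
physiological noise structure beyond AR(1) + drift, spatial noise
correlation, task-unrelated neural variability shared across voxels,
between-participant amplitude variability (all participant-level
variance in the simulated group tests comes from measurement noise), or
RT distributions of error trials differing from correct ones. Passing
tests therefore validate the estimators and their calibration under a
clean generative model, not robustness to every property of real data.

## Numerical choices and degenerate inputs

- HRF: difference of two gamma densities, parameters (6, 16, 1, 1, 1/6),
  peak-normalized to 1; kernel support 32 s at 0.1 s resolution. The
  analytic peak of this difference sits slightly before the nominal 6 s
  peak delay (≈ 5 s), which the tests assert by dense grid search.
- Impulse onsets are snapped to the nearest microtime grid point;
  convolution is a direct sparse sum of shifted kernels (trials are few,
  the kernel is short), exact to machine precision.
- AR(1) estimates are clamped to (−0.99, 0.99); the first sample of each
  run is scaled by sqrt(1 − ρ²) during prewhitening (exact stationary
  weighting). A design that loses rank is rejected with the names of the
  collinear columns rather than silently pseudo-inverted.
- Matching ties (equal RTs) are broken by trial id; subsampling sorts the
  same way. All stochastic stages take explicit seeds and the pipeline
  refuses a configuration without one; the same seed reproduces a
  dataset bit for bit.
- Degenerate cases follow the documented contracts: empty schedules give
  empty (but well-formed) tables, a condition with identical RTs gets an
  identically-zero order-1 modulator, an empty matched set degenerates
  the matched model to the remaining classes, zero-variance group effects
  raise errors rather than returning infinite t statistics (the 2×2
  ANOVA returns F = 0 when the two samplings agree exactly).

## Validation-suite problem sizes

The package's own calibration experiments are sized to be informative yet
routinely runnable: behavioural calibration uses cohorts of 28
participants at the default 5-run schedule; slope-recovery uses three
such cohorts; null calibration of the RT-equated and RT-matched
contrasts uses 500 simulated experiments of 10 participants × 3 runs
(the group t-test's calibration does not depend on cohort size, so
smaller cohorts probe it at much lower cost); and the four-contrast
detection signature uses one 28-participant cohort per generative truth
with fixed seeds. Matching optimality is verified exhaustively on
instances up to 8 trials per side, where brute-force enumeration is
feasible.

## Known limitations

- The AR(1) scheme is a single global coefficient per signal with one
  Cochrane–Orcutt pass, in the spirit of the classical approximate
  schemes; exact REML/full GLS estimation is out of scope.
- Only ROI-level inference is provided; there is no voxelwise
  multiple-comparison machinery (topological FDR, cluster correction).
- ROI membership is voxel-centre based, with no partial-volume
  weighting, and the grid must be axis-aligned in world coordinates.
- The RT-equating contrast inherits the linearity assumption; the
  package surfaces the order 2–4 coefficients so users can check it, but
  does not attempt nonlinear equating.
- Preprocessing (slice timing, realignment, normalisation, smoothing,
  physiological denoising) is assumed done upstream; the package
  consumes events plus ROI series or small volumetric grids.
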