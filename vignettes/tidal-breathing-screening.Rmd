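---
title: "Tidal-breathing screening with locally weighted ridge-logistic learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tidal-breathing screening with locally weighted ridge-logistic learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidybreathe)
```

## The problem and the model

Restful (tidal) breathing can be recorded from anyone, without the forced
expiratory maneuvers that make spirometry demanding. The flow signal TBF(t)
carries timing and shape signatures of obstruction — prolonged expiration, a
reduced inspiratory duty cycle, an early expiratory flow peak — but it also
carries a large nuisance: tidal volume rides on the subject's functional
residual capacity (FRC), which varies widely between people and shifts every
amplitude-scaled feature.

The classifier implemented here embraces that nuisance instead of
normalizing it away. Locally weighted learning (LWL) is a *lazy* learner:
training stores the feature table verbatim; each query is answered by a model
fitted on its own neighborhood. Since the k nearest neighbors of a subject in
raw feature space tend to share a similar lung capacity, a local fit sees
approximately homogeneous amplitudes, and **no feature normalization is
applied anywhere in the pipeline** — this is the method's premise, and an
automated test asserts that a z-scoring round-trip leaves predictions
untouched. Within a small neighborhood the features are strongly collinear
(they share the local lung-capacity scale), which is precisely the regime
where a ridge penalty on the logistic slopes stabilizes the fit; hence the
pairing of LWL with ridge-penalized local logistic regression.

For a query x the classifier:

1. selects the k training rows nearest in Euclidean distance on the raw
   12-dimensional features, ties broken by training-row order;
2. weights neighbor i by $w_i = 1 - d_i/h$, a linear (triangular) kernel with
   bandwidth $h$ equal to the (k+1)-th neighbor distance ($1.1\,d_k$ when the
   training set is exhausted; uniform weights when $h = 0$); tricube and
   uniform kernels are available by configuration;
3. maximizes the locality-weighted penalized log-likelihood
   $$\sum_i w_i\,[\,y_i \log p_i + (1-y_i)\log(1-p_i)\,] - R\,\lVert\beta\rVert^2 ,
   \qquad p_i = \frac{e^{\beta_0 + \beta' x_i}}{1 + e^{\beta_0 + \beta' x_i}},$$
   over $(\beta_0, \beta)$ with the intercept unpenalized;
4. labels the query a smoker when the fitted probability reaches the decision
   threshold (0.5; the boundary value maps to class 1).

Setting $R = 0$ gives the ordinary-logistic local variant; unit weights over
the full table give the global L-R/L-O comparison fits; a k-NN majority vote
(tie resolved by the single nearest neighbor) completes the comparison
family.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 5 | rows | neighborhood size; near $\sqrt{n_\text{train}}$ for 60-row tables |
| `ridge` (R) | $10^{-3}$ | — | L2 penalty on local slopes; 0 = ordinary logistic |
| `threshold` | 0.5 | probability | decision cut; ≥ maps to smoker |
| `smooth_window_s` | 0.05 | s | centered moving-average window for conditioning |
| `hysteresis_frac` | 0.05 | fraction of trial max \|flow\| | amplitude gate for accepting a phase |
| `min_phase_s` | 0.25 | s | minimum accepted phase duration |
| `folds`, `repeats` | 5, 10 | — | cross-validation layout |

The (k, R) = (5, 10⁻³) default is the tuned operating point of the `{T, k, R}
= (1/t, k, 10⁻ʳ)` hold-out grid that `grid_search()` scans (t ∈ 2…7, k ∈
5…10, r ∈ 3…8, 216 cells). The preprocessing defaults are not prescribed by
any standard; they are the values under which segmentation recovers known
generator parameters within 2% on noise-free simulator output (a property the
test suite asserts), and they are exposed in the configuration rather than
hard-coded.

## The synthetic cohort generator

No human recordings ship with the package, so the simulator defines the study
conditions: 2 × 10 subjects, three 60 s trials each at 100 Hz. Per subject it
draws a breath period, an inspiratory duty cycle, a nominal tidal volume, an
expiratory time-to-peak fraction, and an FRC-like amplitude multiplier
`frc_scale`. Each cycle is a half-sine inspiration (positive flow) followed
by a two-piece half-cosine expiration (negative) whose peak sits at the
time-to-peak fraction of expiration; amplitudes are balanced so the
noise-free per-cycle net volume is zero, reflecting how closely inspired and
expired volumes agree in restful breathing. Gaussian sensor noise and a slow
sinusoidal baseline drift are added on top.

Class structure enters only through *timing and shape*: at full separation
non-smokers breathe at period 4.0 s, duty 0.50 and expiratory peak fraction
0.45, smokers at 4.5 s, 0.40 and 0.25 (obstruction prolongs expiration,
shortens the relative inspiratory time and pushes the expiratory flow peak
early). Group means interpolate linearly in a `separation` knob; at 0 the
classes are statistically identical, which the test suite verifies feature by
feature with Kolmogorov–Smirnov tests on 200 subjects. `frc_scale` is drawn
uniformly on [0.8, 1.3] for *both* groups — lung capacity is deliberately a
pure nuisance dimension the classifier must tolerate, never a class signal.
Between-subject standard deviations (period 0.35 s, duty 0.04, expiratory
peak fraction 0.05, tidal volume 0.07 L) were chosen so the two classes form
partially overlapping clusters at full separation rather than trivially
separable ones. Noise of 0.05 L/s is roughly 10% of a typical 0.5 L/s peak
flow, in line with the accuracy reported for portable ultrasonic flow
sensors; drift (0.03 L/s over a 45 s period) exercises the volume
drift-removal. Trials of one subject share parameters up to a uniform ±5%
per-trial jitter on period and tidal volume, modelling day-to-day variation
while keeping subjects self-similar.

What the simulator does *not* emulate: cough/sneeze/movement artifacts (the
acquisition protocol it mirrors discarded such trials and repeated them),
breath-to-breath variability within a trial, irregular or periodic-breathing
patterns, and any instrument transfer function beyond additive noise and
drift. Passing tests on simulated cohorts therefore demonstrate that the
pipeline recovers the structure it assumes — not that real cohorts satisfy
those assumptions.

## Numerical choices

- **IRLS.** Newton steps $(X_a' W X_a + 2R\,I^{*})^{-1}$ on the penalized
  likelihood ($I^{*}$ zeroed at the intercept; the factor 2 is the exact
  Hessian of $-R\lVert\beta\rVert^2$), damped by step halving so the
  objective never decreases; convergence when the step's max-norm falls below
  $10^{-8}$, cap 100 iterations. Linear predictors are clipped to ±30 and
  probabilities to $[10^{-12}, 1-10^{-12}]$ throughout, so single-class
  neighborhoods saturate gracefully instead of overflowing.
- **Underdetermined local fits.** With k = 5 neighbors and 12 features the
  unpenalized ($R = 0$) likelihood has flat directions. The local design is
  centered at the query (the intercept then *is* the query's linear
  predictor) and, for $R = 0$ only, scaled by the neighborhood radius before
  a pseudo-inverse (minimum-norm) Newton step. Centering and scaling leave
  the maximum-likelihood problem unchanged by affine equivariance, but make
  the canonical minimum-norm solution invariant under a common rescaling of
  all features — so LWL+L-O predictions are exactly unchanged when every
  feature is multiplied by the same constant, as the no-normalization premise
  demands. For $R > 0$ the penalized Hessian is nonsingular and the slope
  penalty is defined in raw feature units, so no scaling is applied; ridge
  predictions vary (continuously) under common rescaling, which is inherent
  to a fixed-units penalty and documented rather than suppressed.
- **Segmentation edges.** Phases start at zero crossings; runs failing the
  amplitude hysteresis or minimum duration merge into the preceding phase. A
  phase cut by the record boundary is kept only when the boundary sample's
  |flow| is inside the hysteresis band — i.e. the phase has essentially
  returned to baseline — so a trace ending exactly at end-expiration keeps
  its final cycle while a trace cut mid-expiration drops it, keeping
  per-cycle means unbiased.
- **Volume.** Cumulative trapezoidal integration; each cycle's volume is
  linearly detrended so its end-expiratory level returns to a common anchor,
  making TBV(t) drift-free both within and across cycles. A consequence of
  exact per-cycle closure is that inspired and expired tidal volumes agree to
  numerical precision; both are reported because their definitions diverge
  under any other drift model.
- **Ambiguous feature definitions.** Peak-flow features are per-cycle means
  of the phase maxima (consistent with the "mean of all acquired phases"
  phrasing of the other features); a trial-max alternative is a configuration
  flag. The velocity features are peak flow ÷ time-to-peak per cycle (units
  L/s²), with a mean-flow-to-peak alternative behind a flag; cycles with zero
  time-to-peak are excluded from the velocity means with a warning.
  Breathing rate divides cycle count by the *segmented* span, not the nominal
  60 s, so edge-discarded breaths do not bias it.
- **Friedman statistic.** The mean-rank form
  $\chi^2_F = \frac{12N}{d(d+1)}\left[\sum_j \bar R_j^2 - \frac{d(d+1)^2}{4}\right]$
  with ties averaged; it is the unique centering under which identical
  performance gives exactly 0, and it matches `stats::friedman.test` on
  tie-free input. The critical value is the χ² quantile at the configured
  confidence with d − 1 degrees of freedom (11.34 at 99% for d = 4).
- **Hold-out sizing.** Test sets are `round(n/t)` with halves rounded up —
  the rule that yields the sequence 30, 20, 15, 12, 10, 9 for n = 60, t =
  2…7 — allocated to classes by the same nearest-integer rule.
- **F measure.** Support-weighted two-class F1 (per-class F1 also reported);
  kappa is 0 by convention when chance agreement is 1. AUC is the
  tie-corrected Mann–Whitney statistic; AUP uses plain trapezoids over
  distinct thresholds with the (1, recall 0) anchor — other PR interpolation
  conventions differ slightly and are not reconciled.

## Known limitations

- **Row-level cross-validation leaks subject identity.** The evaluation
  follows the original protocol: 60 rows = 20 subjects × 3 trials,
  cross-validated by *row*. Trials of one subject differ only by the ±5%
  day-to-day jitter plus noise, so a held-out row's two sibling trials are
  almost always among its k = 5 nearest neighbors, and the local fit can
  reproduce the subject's own label regardless of any class signal. The
  package's own null experiment measures this: with `separation = 0` (labels
  carry no information about the waveforms) repeated fivefold CV with the
  tuned classifier still scores around 70–82% across seeds, far above the
  ~50% a leakage-free design would give. Whenever repeated trials per
  subject exist, accuracy should be read with this caveat, or folds should
  be grouped by subject (as `friedman_compare()` does, holding out whole
  subjects).
- The simulator's realism is calibrated only to qualitative statements about
  tidal breathing (volume balance, timing/shape class effects, FRC baseline
  variation); no distributional ground truth for real cohorts is claimed.
- The ridge variant's predictions are not invariant to feature rescaling
  (only the $R = 0$ variant is exactly so); with mixed feature units the
  penalty's meaning depends on those units, exactly as in any fixed-R ridge
  model.
- Only binary classification is supported, and the off-the-shelf comparison
  classifiers of the original study (SVM-RBF, random forest) are out of
  scope; the built-in family is LWL±ridge, their global counterparts, and
  k-NN.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run at the study's own scale where
that is cheap — 20 subjects × 3 trials of 60 s at 100 Hz, fivefold CV
repeated 10 times, the 216-cell grid on reduced ranges, 2000 null matrices
for the Friedman calibration, 50 random problems for the optimizer oracle —
and at reduced trace lengths (10–30 s) for structural checks where waveform
length is irrelevant.
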