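---
title: "Comparing models of pain processing with default g-prior Bayes factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing models of pain processing with default g-prior Bayes factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincoding)
```

## The scientific question

When a painful stimulus is preceded by a cue that predicts it, physiological
and neural responses do not simply track the delivered stimulus. A
predictive-coding account holds that the measured response is the weighted
sum of a top-down *prediction* and a bottom-up *prediction error* (PE), each
with its own gain. In a probabilistic cueing design — three cues signalling
25%, 50% or 75% probability of painful heat, crossed with the two delivered
intensities (non-painful warm vs. painful) — the three accounts make
distinguishable predictions about the 2 × 3 grid of condition-mean
amplitudes:

* **Stimulus intensity**: `y = w S`, with `S` dummy-coding the stimulus
  (0 = warm, 1 = pain). Responses depend only on what was delivered.
* **Stimulus plus expectation**: `y = w1 S + w2 P`, with `P` the
  cue-conditional probability of pain. Expectation shifts responses
  additively; no cue-by-stimulus interaction.
* **Predictive coding**: `y = w1 P + w2 PE`. With the *pain PE*
  (`PE = 1 - P` for painful outcomes, 0 for warm), this is the only
  candidate producing a crossover interaction: for warm stimuli responses
  rise with expected pain, for painful stimuli they fall. Two further PE
  variants are encoded: the *signed* PE (`S - P`) and the *absolute* PE
  (`|S - P|`).

The factorial signature is the interaction contrast
`(warm_high - warm_low) - (pain_high - pain_low)`, which is identically zero
for the intensity, additive and signed-PE models and equals `w2 / 2` for the
pain-PE model. (The signed-PE response `w1 P + w2 (S - P)` rearranges to
`(w1 - w2) P + w2 S`: it spans exactly the same regressor subspace as the
additive model, so the two are indistinguishable by any fit statistic — the
package reports their pairwise log Bayes factor as exactly 0 rather than
hiding the tie.)

```{r patterns}
design_matrix("pc-pain")
interaction_contrast(predict_response("pc-pain", c(1, 1)))
```

## Bayesian model comparison

Candidate models are compared through Bayes factors against a shared
intercept-only null. For a linear model with `p` centered regressors fit to
`n` observations with coefficient of determination `R^2`, the default
Zellner–Siow (Cauchy mixture-of-variance) prior gives the one-dimensional
marginal-likelihood ratio

$$BF_{10} = \int_0^\infty (1+g)^{(n-1-p)/2}\,
  \bigl[1 + g(1-R^2)\bigr]^{-(n-1)/2}\, \pi(g; r)\, dg,
\qquad
\pi(g; r) = \frac{\sqrt{r^2 n/2}}{\Gamma(1/2)}\, g^{-3/2}
  e^{-r^2 n/(2g)},$$

with prior scale `r = sqrt(2)/4` (the conventional "medium" default for
regression slopes). Because this integral is one-dimensional we evaluate it
by deterministic adaptive quadrature on the log-`g` scale rather than by
MCMC: the integrand is rescaled by its maximum (found by golden-section
search on `[-40, 40]` in log `g`), integrated at a requested relative
tolerance of 1e-10, and the quadrature's error bound is returned with the
result. This makes the Bayes factors exactly reproducible and removes
sampling noise from model comparisons. The test suite checks the quadrature
against a dense-grid (10^6-point) trapezoid evaluation of the same integral
to 1e-6 relative error across randomised `(n, p, R^2)`.

Log Bayes factors are natural logs throughout, and `|log-BF| > 3`
(odds of about 20:1) is used as the strong-evidence convention.

Two properties worth noting:

* The BF depends on the data only through `(n, p, R^2)`, so it is invariant
  to rescaling the response and to invertible reparameterisation of the
  regressor columns — which is also what forces the additive/signed-PE tie.
* `log_bf_compare(a, b)` is the difference of the two null-referenced
  log-BFs and hence exactly antisymmetric.

### Subject structure

Group inference operates on condition-level amplitudes (one value per
subject and condition). By default the package removes each subject's mean
across the six conditions before fitting (`within_subject_center()`), so
between-subject level differences do not masquerade as condition structure.
Centering introduces one linear constraint per subject, so the effective
sample size `n_eff = n_obs - n_subjects + 1` is used in place of `n` in the
integral. This is an approximation to treating subject as an additive
nuisance factor in both numerator and denominator models; `center = FALSE`
disables it for data already expressed as within-subject effects.

## Amplitude scoring from raw traces

Skin conductance (100 Hz) is scored trough-to-peak: the response onset is
the first local minimum at least 1 s after cue onset, the peak is the
maximum within 10 s after cue onset, and the amplitude is their difference.
Trials without a qualifying trough–peak pair score 0 and are flagged
invalid, and by default these zeros are retained in condition means. A
local minimum is a non-positive-to-positive sign change of the first
difference after 50 ms moving-average smoothing — a deliberate choice that
makes detection robust to sample noise at 100 Hz.

Pupil diameter (1000 Hz) is cleaned before scoring: ±100 ms around each
blink is marked missing, trials with more than 50% missing are discarded,
gaps are linearly interpolated, and the trace is low-pass filtered at 2 Hz
with a zero-phase second-order Butterworth filter (forward–backward, with
odd-reflection padding to suppress edge transients) before decimation by 4
to 250 Hz — filtering first lets the 2 Hz low-pass double as the
anti-alias filter. The amplitude is the post-stimulus maximum minus the
mean of a 1 s pre-stimulus baseline; negative values are allowed and
flagged. Both modalities are then transformed with `log(1 + max(a, 0))`,
which is defined at zero, monotone, and close to the natural log for large
amplitudes.

## What the synthetic generator emulates — and what it does not

No raw data ship with the package; `simulate_condition_amplitudes()` stands
in for a study dataset. Its contract is deliberately simple: condition
amplitudes are the generating model's pattern plus a Gaussian subject
intercept (`sd_subject`) and homoscedastic Gaussian cell noise
(`sd_noise`), with every draw recorded in a truth object sufficient to
rebuild the table. Two presets fix the variance components, which real
studies do not report: `"high"` (`sd_subject` 0.3, `sd_noise` 0.1) for
recovery validation where the method should be near-perfect, and
`"study"` (`sd_subject` 0.5, `sd_noise` 0.3), a plausible regime for a
28-subject psychophysiology study in which effects of weight ~1 yield
single-digit-to-tens log-BFs.

`simulate_trial_traces()` exercises the scoring chain end-to-end with a
gamma-shaped canonical response (SCR: onset ~1.2 s after cue, peak ~1 s
later; pupil: peak ~0.9 s after stimulus onset) scaled by the condition
amplitude, plus optional Poisson blink intervals for pupil.
`simulate_voxel_grid()` builds condition estimates whose pattern blends
predictive-coding and intensity coding along the posterior-to-anterior y
axis via a monotone λ(y) (default logistic), emulating the
anterior–posterior gradient of model evidence in the insula; the default
grid is 20 × 40 × 20 voxels at 2 mm spacing.

Passing tests on these data show that the inferential machinery recovers
known structure under Gaussian, homoscedastic, temporally uncorrelated
noise. They do not certify behaviour under real-data features the generator
omits: heteroscedastic or skewed amplitudes, trial-order and habituation
effects, spatially autocorrelated fMRI noise, hemodynamic confounds, or
learned (rather than instructed) cue contingencies. The models here use the
true experimental probabilities 0.25/0.5/0.75 for `P`; no trial-by-trial
learning model is implemented.

## Group statistics

`rm_anova_2x3()` implements the within-subject 2 × 3 factorial ANOVA from
partitioned sums of squares, testing each effect against its own
subject-by-effect error stratum (stimulus: df 1, n−1; cue and interaction:
df 2, 2(n−1)); no sphericity correction is applied by default. The suite
verifies exact agreement with `aov()` error strata and a ~5% interaction
type-I error rate under a 2000-replicate null simulation at n = 20.
`paired_t()` and `fdr_bh()` wrap the standard base-R routines;
FDR correction is applied within each effect across measures.
`voxelwise_logbf()` restricts per-voxel comparisons to an omnibus pre-mask
(a one-way any-condition repeated-measures F at p < 0.005, uncorrected)
and thresholds at `|log-BF| > 3`; `pattern_expression()` computes the
masked dot product of a fixed weight map with each subject's condition
images, yielding a pain-signature-style scalar per condition.

## Design generation choices

`generate_design()` realises cue contingencies exactly — within each block
and cue, the pain-trial count equals probability × 16, not a binomial draw —
and places the 12.5% attention targets in equal numbers per cue at uniform
positions. "Pseudo-randomised" order is implemented as a uniform
within-block permutation rejected until no more than 4 consecutive trials
share a cue; this is reproducible under a seed and avoids long cue runs,
but other constraints the original randomisation may have had (e.g. on the
first trials of a block) are unknown and not imposed. The rating-delay
jitter is continuous uniform on 3–5 s. Temperature calibration inverts an
equally-weighted OLS fit of VAS ratings on temperature at VAS 30 and VAS 75
and caps both at 49.5 °C; a non-positive slope is rejected as an
implausible calibration rather than extrapolated.

## Numerical and degenerate-input policy

* Quadrature: relative tolerance 1e-10, error bound reported; `R^2 = 1` is
  rejected (the marginal likelihood diverges) rather than clamped.
* Rank-deficient designs and `n <= p + 1` are errors, not warnings.
* Span-equivalent pairs are reported as exactly 0, and ties in model
  recovery are credited to the generator's equivalence class.
* ANOVA strata with zero error variance return `F = NA` with a
  `degenerate` flag; identical paired samples return `t = 0, p = 1` with a
  `zero_variance` flag.
* Subjects with incomplete condition sets are dropped with a warning in
  both centering and ANOVA.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
make every stochastic check stable at a fixed seed: 28 subjects for
evidence and recovery simulations (100 replicates for weight-ratio and
model-recovery runs), 2000 replicates at n = 20 for ANOVA calibration, and
a 6 × 10 × 4 voxel grid with 14 subjects for the gradient profile. Larger
grids and replicate counts scale linearly and can be run with the same
functions.

## Known limitations

* The Bayes-factor regression treats subject via centering plus the
  `n_eff` correction, not as a full random effect; hierarchical posterior
  estimation of weights is out of scope.
* Real acquisition pipelines (motion correction, normalisation, HRF
  convolution, permutation inference) are upstream of this package: inputs
  are condition-level amplitudes or estimates.
* The weight positivity postulated by predictive coding is checked after
  unconstrained least squares, never enforced during fitting or in the
  prior.
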