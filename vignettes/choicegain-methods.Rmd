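---
title: "Modelling choice-induced changes in evidence weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice-induced changes in evidence weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choicegain)
```

## The scientific problem

In two-interval estimation tasks an observer sees two successive streams of
evidence — random-dot motion directions relative to a reference line, or
sequences of numbers compared against 50 — and reports a continuous estimate
of the mean evidence at the end of the trial. On *Choice* trials the
observer additionally reports a binary categorical judgment of the first
interval half-way through (clockwise/counter-clockwise, or above/below the
reference); on *No-Choice* trials the intermittent response is an
evidence-independent button press. The scientific questions this package
addresses are (i) whether committing to an intermittent choice changes the
weight the final estimation gives to evidence before and after the choice,
and (ii) whether, within Choice trials, evidence consistent with the choice
is weighted differently from inconsistent evidence (a confirmation bias).

## The model

**Choice stage.** Binary choices follow a lapse-free probit psychometric
function,

$$P(D = +1 \mid \phi_1) = \Phi(\delta + \alpha\,\phi_1),$$

with slope $\alpha$ (sensitivity) and bias $\delta$. `fit_psychometric()`
maximises the Bernoulli likelihood with a multi-start simplex and exports
$\sigma = 1/\alpha$ as the evidence-noise SD of the internal representation.

One wrinkle is worth recording: the probit equation places $\delta$ on the
probit scale, while the generative evidence model adds a bias to the
evidence itself, $X_i = \phi_i + \delta_e + N(0, \sigma^2)$. With
$\sigma = 1/\alpha$ these are consistent only if $\delta_e = \delta/\alpha$.
The fitted object therefore carries both: `delta` (probit units) and
`delta_e = delta/alpha` (evidence units), and every estimation-model formula
uses `delta_e`.

**Estimation stage.** The estimation is a weighted sum of the two noisy
representations plus Gaussian estimation noise $\xi$. The *Global Gain*
model frees $(w_1, w_2, \xi)$ separately for Choice and No-Choice trials;
the *Selective Gain* model frees them separately for Choice trials whose
interval-2 evidence is consistent ($\mathrm{sign}(\phi_2) = D$) versus
inconsistent with the choice. The confirmation-bias index is
$w_{2cc} - w_{2ic}$.

**The likelihood.** On No-Choice trials the predicted estimation is the sum
of three Gaussians and hence Gaussian:
$Y \sim N\!\big(w_1(\phi_1+\delta_e) + w_2(\phi_2+\delta_e),\;
\sigma^2(w_1^2+w_2^2) + \xi^2\big)$, evaluated in closed form. On Choice
trials the interval-1 representation is conditioned on the choice it
produced: the density of $X_1$ is zeroed on the choice-incongruent
half-line, renormalised, scaled by $w_1$, and numerically convolved with
the combined Gaussian of the weighted interval-2 representation and the
estimation noise. This truncation is what lets a single noisy
representation explain both the binary report and the estimation.

## Numerical choices

* **Grid.** Uniform, spacing one tenth of the smallest noise SD, clamped to
  0.05–0.5 evidence units; extent ±6 combined SDs, auto-extended to cover
  any observed estimation. Evaluation at observations interpolates the log
  density with a cubic spline.
* **Truncation boundary.** The grid cell straddling the truncation boundary
  is carried as an exact point mass at its analytic conditional mean, and
  the midpoint quadrature's Euler–Maclaurin boundary term is added
  analytically. Halving the grid spacing then changes per-trial log
  densities by well under $10^{-4}$ (tested), so the default spacing does
  not move fits.
* **Renormalised truncation.** The truncated density is a proper
  conditional. The normaliser depends only on $(\phi_1, \delta_e, \sigma)$,
  which are fixed during estimation-model fitting, so renormalisation
  cannot change the argmax; it only fixes the scale of reported
  log-likelihoods.
* **Caching.** Densities are computed once per unique $(\phi_1, D)$ group —
  the interval-2 mean enters only as a location shift — and evaluated at
  shifted observations. This makes a 2,070-trial perceptual fit a matter of
  a second rather than minutes.
* **Optimiser.** Each 3-parameter component (the likelihood factorises over
  trial subsets) is maximised by restarted Nelder–Mead with jittered
  multi-starts and a final re-initialised run from the incumbent, $\xi$ on
  the log scale. A subspace-searching simplex (Subplex) is not available in
  this environment; the restarted simplex is the documented fallback.
  Weights are unbounded, as nothing in the model constrains their sign.

## Synthetic observers: the stated world

The generator reproduces both task designs at their published sizes: the
perceptual task uses five directions (±20°, ±10°, 0°), 23 retained
direction combinations (the two maximally conflicting pairs are excluded),
and 90 estimation trials per combination split 45/45 between Choice and
No-Choice; the numerical task draws eight integers per interval from
triangular distributions with means 40/46/54/60 on 10–90, never repeating a
number consecutively, with 50/25/25% feedback-terminated / Choice
estimation / No-Choice estimation trials.

Where the source material is silent, values were chosen once as what a
psychophysicist would call realistic, and are not tuned:

* The triangular number distributions are under-determined (only means and
  range are stated). We solve the apex of a discrete triangular density on
  the integer support so the expectation equals the stated mean; the
  solutions land at 20/38/62/80. The skew direction follows from the apex.
* Observer sensitivity defaults to $\alpha = 0.1$/° (perceptual) and
  $0.06$/unit (numerical), which reproduce the reported choice accuracies
  of roughly 81% and 67%; generative weights centre on
  $w_{1c}=0.7, w_{2c}=0.3$ (Choice) and $w_{1nc}=w_{2nc}=0.5$ (No-Choice)
  with estimation noise $\xi = 3$, matching the published pattern of
  primacy after a choice and mild recency without one.
* Choice readout is the deterministic sign of $X_1$, so the choice and
  estimation share one representation — this is what the truncation logic
  assumes. The long-run choice probabilities still follow the probit.
* Response times are shifted log-normal and a small wrong-button rate can
  be injected; these exist solely so the exclusion rules (< 200 ms cut,
  1.5 IQR estimation fences, wrong button) are exercisable. The RT cut is
  strict (< 200 ms excluded), outlier fences pool estimation trials across
  conditions within subject, and the quantile rule is an exposed option.

A green test on this world establishes that the estimators recover the
parameters of the generative process that the model assumes, at the stated
trial counts — it does not establish anything about sequential effects,
learning, or lapses, none of which the generator emulates.

## Model-free sensitivity and inference

The ROC index between estimation distributions of adjacent interval-2
evidence levels (higher level as the signal class; ties count one half) is
trial-count-weighted within each $\phi_1$, then averaged unweighted across
$\phi_1$ — the weighting is applied only where the source specifies it.
The numerical task binarizes both intervals at the reference, with a
four-bin option.

Group inference uses paired sign-flip permutation tests (mean difference
statistic, two-sided by absolute value, exhaustive enumeration when
$2^n$ fits the budget — 1,024 patterns at $n = 10$ — and add-one-smoothed
Monte-Carlo otherwise); the 2×2 repeated-measures ANOVA interaction is
computed through its exact identity with the squared paired $t$ on the
per-subject double difference. Bootstrap correlation CIs draw one value per
subject from per-subject bootstrap distributions, 10,000 times; pooling
across tasks Fisher-transforms per-task correlations and averages with
inverse-variance weights $n-3$ (the source says only "weighted average";
this is the standard choice). The published slope-comparison scalar is not
fully specified, so `estimation_slope_test()` implements it as per-subject
OLS slopes of estimation on mean evidence, compared between conditions
with the permutation test — an interpretation, and labelled as such.

## The model-recovery control

A selective-gain effect could in principle be manufactured by the fitting
machinery itself (the truncation couples $X_1$ and the choice). The control
simulates estimations from each subject's *fitted Global Gain* parameters —
rejection-sampling $X_1$ until its sign matches the recorded choice, with
an analytic tail sampler when the acceptance probability vanishes — refits
the Selective Gain model, and correlates the recovered selective effect
with the empirical nonselective effect across subjects. In a world with no
selective effect this correlation's bootstrap CI covers zero (tested), and
a positive-control world with coupled effects yields a detectable positive
correlation.

## Pupillometry

The preprocessing chain is order-exact: linear blink interpolation (−150 to
+150 ms margins, overlapping windows merged), FIR deconvolution of blink-
and saccade-evoked responses (boxcar design, 0–6 s window at 50 ms
resolution, least squares with an intercept) removed by regression,
zero-phase second-order Butterworth band-pass 0.01–10 Hz, z-scoring per
block, decimation to 50 Hz (the 10 Hz low-pass acts as the anti-alias
filter), epoching locked to interval-1 onset (re-lockable to the estimation
response without re-filtering), truncation at the next trial or 6 s, and
baseline subtraction of the 500 ms before interval-1 onset.

Choices recorded here because the source delegates them to references or
leaves them open: zero-phase (forward–backward) filtering, which preserves
latencies at the cost of squaring the magnitude response; the deconvolution
window and resolution (0–6 s, 50 ms); the cluster-forming threshold for the
cluster-based permutation test (pointwise two-sided $\alpha = 0.05$, max
cluster-mass correction, subject-level sign flips); and the scalar-response
windows, which are configuration with defaults of 2.75–4.25 s after
interval-1 onset (the post-intermittent-response period), since the
published windows are indicated only graphically. Filters are hand-rolled
biquads (no DSP package is available here) and are verified against the
analytic Butterworth magnitude response in the test suite.

## A worked run

```{r example, eval = FALSE}
des <- perceptual_design(trials_per_combination = 20)
out <- run_pipeline(list(n_subjects = 4, design = des), seed = 11)
out$fit_table[, c("w1c", "w2c", "w1nc", "w2nc")]
out$stats$w2_perm          # Choice vs No-Choice interval-2 weights
out$stats$interaction      # interval x condition interaction
```

## Known limitations

* Group-level fitting is per-subject maximum likelihood; there is no
  hierarchical pooling.
* Model comparison is restricted to the two gain models; no information
  criteria across a wider model space.
* The pupil generator does not emulate gaze-position foreshortening or
  luminance artefacts, and EyeLink EDF files are not parsed — traces are
  consumed as annotated tables.
* $\xi$ estimates trade off against $\sigma^2(w_1^2+w_2^2)$; because
  $\sigma$ is imported from the psychometric stage, small errors in
  $\hat\alpha$ move $\hat\xi$ noticeably while leaving the weights (the
  quantities of scientific interest) stable.
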