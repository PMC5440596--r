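---
title: "Testing perceptual separability and independence with grtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing perceptual separability and independence with grtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grtkit)
```

## The model

General Recognition Theory (GRT) extends signal detection theory to
stimuli that vary on two dimensions at once. Every presentation of a
stimulus evokes a percept — a point in a two-dimensional perceptual space —
and the percepts of repeated presentations follow a bivariate Gaussian
distribution. In the 2x2 identification task the four stimuli
A1B1, A2B1, A1B2, A2B2 (all combinations of two levels on dimensions A and
B) each have their own distribution, and the observer answers by cutting
the space with two linear decision bounds, one per dimension.

Three kinds of independence are defined on this model:

* **Perceptual independence (PI)** — within one stimulus, the two percept
  coordinates are uncorrelated (`rho = 0` for that stimulus).
* **Perceptual separability (PS)** — the marginal distribution of one
  dimension is the same at both levels of the other dimension (for PS of A:
  equal x-means and x-variances across B levels).
* **Decisional separability (DS)** — the bound for a dimension is
  orthogonal to that dimension's axis (slope 0 in this package's
  parameterization: the A bound is the line x = m*y + b, and DS on A means
  m = 0).

`gaussian2d()`, `linear_bound()` and `grt_model()` build this object
directly. `region_probabilities()` turns a distribution plus the two
bounds into the four response probabilities: with discriminants
u = x - m_A y - b_A and v = y - m_B x - b_B, the pair (u, v) is again
bivariate normal and the four response regions are its quadrants, so each
probability is one bivariate-normal CDF evaluation. The CDF is computed in
compiled code with Gauss–Legendre quadrature (absolute error far below the
1e-7 the package requires of it); the test suite cross-checks it against an
independent implementation. Orientation is fixed by convention: larger x
means level 2 of A, larger y level 2 of B, which resolves the reflection
ambiguity of all fitted models.

Degenerate geometry (bounds whose discriminants are perfectly correlated,
|induced correlation| >= 1 - 1e-12) raises an error naming the bounds.
Inside likelihoods every predicted probability is floored at 1e-10, the
same constant the proportion sanitizer uses, so log-likelihoods stay
finite during optimization.

## Summary-statistics analyses

Both analyses consume a 4x4 confusion matrix in the fixed order A1B1,
A2B1, A1B2, A2B2 (rows = stimuli, columns = responses). Proportions of 0
or 1 are replaced by 1e-10 and 1 - 1e-10 (one warning per replaced value,
emitted through R's condition system rather than standard output).

**Macro-analyses** (`macro_analysis()`) compare statistics across stimuli:

* marginal response invariance (mRi): pooled two-proportion z tests of the
  level-matching response proportion between the two stimuli sharing a
  level of the tested dimension;
* equality of marginal d' and of marginal c across levels of the
  irrelevant dimension, using Gourevitch–Galanter variances
  var(d') = h(1-h)/(n_H phi(z_h)^2) + f(1-f)/(n_F phi(z_f)^2) and
  var(c) = var(d')/4.

Conclusions are coded `yes`, `NO`, `? yes`, `? no`, `?` per dimension via a
fixed decision table: an unequal marginal d' forces PS = NO and DS = ?
(criterion differences cannot be attributed); equal d' with equal c and
passing mRi gives PS = yes, DS = yes; the remaining rows grade the
evidence downward. The table is a package constant; the first two rows are
pinned down by the worked example below, the rest follow the classic
msda2-style logic in which d' is criterion-free evidence about PS while c
shifts have ambiguous attribution.

**Micro-analyses** (`micro_analysis()`) compare statistics within a
stimulus: sampling-independence z tests per response cell (observed cell
proportion against the product of the marginal response proportions) and
equality of conditional d'/c across the two conditioning response levels.
Per-stimulus PI/DS codes come from an analogous table (`si` = all four
cell tests pass, `cd`/`cc` = conditional d'/c equal): all passing gives
PI = yes, DS = yes; failing sampling independence moves PI to `? no`;
failing conditional d' moves DS to `? no`; a failing conditional c alone
degrades DS one step along yes > ? yes > ? > ? no. A degenerate
conditioning denominator (an empty response pair) yields `?` for the
affected codes rather than an error.

Two conventions matter for calibration, and the test suite measures both
under a separable, independent generator (500 replicates, 250 trials per
stimulus): the macro tests and the conditional-equality tests hold the
nominal 5% level within Monte-Carlo error; the sampling-independence test
uses the expected proportion as a fixed value in its variance, which makes
it deliberately conservative — its rejection rate stays at or below the
nominal level (near zero for low-probability cells) and is asserted in
that direction only.

## The worked example

The package ships the simulated face identification experiment used
throughout the documentation (emotion = dimension A, gender = dimension B,
250 trials per stimulus):

```{r}
cm <- grt_face_example()
summary(macro_analysis(cm))
summary(micro_analysis(cm))
```

Dimension A is not perceptually separable from B (NO) while B may be
separable from A; decisions about B look separable, those about A are
undetermined; and the micro-analysis leaves PI and DS unknown but possibly
violated.

## The traditional 12-model hierarchy

`fit_grt_hierarchy()` fits all twelve models obtained by crossing the PS
pattern (both dimensions, A only, B only, neither) with the correlation
structure (PI, one shared correlation "1_RHO", four free correlations).
All twelve assume DS, unit variances, and anchor the A1B1 mean at the
origin, leaving k = 4 free parameters at the top of the hierarchy and 12
at the bottom. Each model is fit by maximum likelihood from `n_starts = 10`
random starts — the canonical PS+PI+DS configuration (means on the unit
grid, zero correlations, bounds at 0.5) plus independent uniform
perturbations of half-width `perturb = 0.3` — with BFGS on a compiled
objective; correlations are kept inside (-0.99, 0.99) by a tanh transform.
After the multi-start pass the best solution is polished by repeated BFGS
restarts, which resets the curvature approximation and recovers from
stalls on flat stretches of the likelihood.

Models are ranked by the corrected AIC,
AICc = -2 logL + 2k + 2k(k+1)/(N - k - 1), and compared through Akaike
weights. The sample size in the correction term is N = 16, the number of
data cells a 2x2 identification design yields per participant: the
correction exists to guard against overfitting the 16-cell response
pattern, and with it the worked example selects `{1_RHO, PS(B), DS}` with
a weight that rounds to 1. (Using the total trial count instead leaves the
same winner but spreads the weights; the cell-count convention is the one
under which the package's reference results were produced.) Ties, should
they occur, break toward fewer parameters and then enumeration order.

```{r}
fit <- fit_grt_hierarchy(cm, seed = 1)
summary(fit)
```

`plot(fit)` draws the winning model: one 1-SD ellipse per stimulus, the
two bounds, marginal densities (solid vs dotted by the level of the other
dimension), and an inset of observed against predicted proportions.

## GRT-wIND

Traditional 2x2 modeling cannot test DS at all and must assume it. GRT
with individual differences (`fit_grt_wind()`) removes that limitation by
fitting one shared perceptual representation to *all* participants
simultaneously: group-level means, variances and correlations (16 free
parameters, with A1B1 anchored at the origin with unit variances), plus
per participant a global attention scalar kappa, an attention share lambda
(effective variances sx2/(kappa lambda) and sy2/(kappa (1-lambda))), and
two personal bounds with free slopes and intercepts (6 parameters each,
k = 16 + 6K in total). kappa is fitted on the log scale, lambda through a
logistic transform, correlations through the tanh transform.

`wind_lr_tests()` then tests each property by a likelihood-ratio test
against a restricted refit: PS ties the tested dimension's marginal means
*and variances* across levels of the other dimension (PS is a claim about
whole marginal distributions, not means alone; 4 constraints), PI zeroes
all four correlations (4 constraints), DS zeroes the relevant bound slope
for every participant (K constraints). Restricted fits start from random
perturbations of the full-model estimates and run `n_reps = 20` times by
default; chi-squared statistics are floored at zero, and a restricted fit
that beats the full fit by more than 0.01 log-likelihood units flags the
row and warns that the full fit should be re-run. Because restricted
starts are warm (they inherit the full fit's region of parameter space),
a restricted optimum that lives in a different near-symmetric basin can
occasionally be missed, which inflates the statistic; true-null verdicts
therefore reject somewhat above the nominal rate at small `n_reps`, and
final inferences deserve the default 20 repetitions or more.

One genuine property of this model family deserves emphasis: with bound
slopes free, an approximate gauge freedom runs through the parameter
space — a shear or rotation of the perceptual space can be largely
compensated by per-participant bound adjustments, leaving the likelihood
almost unchanged. The freedom is broken only by the axis-aligned attention
scaling (participants with different lambda scale the axes differently)
and by the anchored A1B1 distribution. Two practical consequences follow.
First, fitted parameter values should be read up to this near-symmetry;
likelihood-ratio tests, which compare likelihoods rather than raw
parameters, remain meaningful. Second, violations that a rigid remapping
of the space could absorb (for example, a perfectly uniform shift of all
x-means across B levels, or bound tilts identical across participants) are
intrinsically hard to detect. The packaged demonstration generator
(`wind_demo_model()`) was therefore built, once, with violations of the
kind the method can actually resolve and with magnitudes typical of
published applications: a B-level x-shift that differs between A levels
plus an x-variance increase (PS of A fails, PS of B holds), correlations
of -0.7 on the two off-diagonal stimuli (PI fails), bound tilts around
|m| = 0.6 whose directions alternate across the five participants (DS
fails on both dimensions), attention parameters spread over kappa 1.0–1.8
and lambda 0.25–0.72 (the lambda spread is what breaks the shear symmetry
hardest), and error rates in the moderate range that identification
analyses need. The acceptance suite re-simulates this
design (K = 5, 250 trials per stimulus, 20 replicates) and requires each
likelihood-ratio verdict to match the generator's truth in at least 80% of
replicates.

## The Garner filtering task

`garner_analysis()` implements the summary-statistics analysis of the 2x2
Garner filtering task from per-trial records (block, relevant level,
irrelevant level, accuracy, RT):

* **Garner interference** on correct-trial RT (Welch t test) and on
  accuracy (pooled z): the classical filtering-minus-baseline cost. The
  verdicts are directional — only *slower* or *less accurate* filtering
  counts as a violation — so their nominal false-alarm level is alpha/2,
  and the calibration test asserts them at that level.
* **Marginal response invariance** (per relevant level, pooled z) and
  **marginal RT invariance** (per relevant level, two-sample
  Kolmogorov–Smirnov on correct RTs), computed on filtering blocks only,
  where all four stimuli appear together. These are two-sided, and the KS
  D statistic is checked against a brute-force ECDF supremum in the tests.

The interference tests are the less diagnostic rows: a pure context
effect — slower responding in filtering blocks for reasons unrelated to
separability — also produces interference. The single-block invariance
tests are immune to it, and the simulator makes the dissociation testable:
`simulate_garner(..., context_slowdown = 80)` adds a filtering-only
slowdown to an otherwise separable model, and the analysis then flags
GI(RT) while mRTi keeps passing. Accuracy above 0.95 in either block type
raises a ceiling warning: with almost no errors the proportion-based rows
are uninformative and should be ignored in favor of the RT rows.

## The simulators

`simulate_identification()` draws percepts and classifies them with the
model's bounds; `simulate_wind()` applies each participant's attention
scaling and personal bounds first, deriving per-participant seeds from the
master seed. `simulate_garner()` runs two level-balanced baseline
sub-blocks (one per irrelevant level) and one filtering block mixing all
four stimuli, and generates response times under the RT-distance
hypothesis — percepts farther from the decision bound respond faster — via
RT = (t0 + a exp(-b d)) * exp(noise), with d the perpendicular distance to
the relevant bound and lognormal trial noise. Only the monotone decrease
with distance is theory; this particular functional form is a modeling
convenience with interpretable parameters (defaults t0 = 350, a = 300,
b = 1, sd = 0.15 on a millisecond scale, chosen to give realistic RT
distributions around 400–700 ms). All generators are pure functions of
their arguments and seed.

What the generators deliberately do not emulate: learning and sequential
effects (GRT models steady-state performance only), RT outliers and
anticipations, and non-Gaussian percept distributions. Tests passing on
synthetic data therefore certify the statistical machinery, not the
adequacy of the Gaussian model for any particular real dataset.

## Numerical choices and problem sizes

Throughout: probabilities floored at 1e-10; correlations constrained to
(-0.99, 0.99); BFGS with compiled central-difference gradients (step
1e-6 scaled), `maxit = 1000`, relative tolerance 1e-10, followed by
polish restarts; multi-start initial points generated up front from the
seed so results are independent of execution order and worker count. The
test suite runs the calibration studies at 500 replicates with 250 trials
per stimulus, Monte-Carlo agreement checks at 1e5–2e5 draws, and the
GRT-wIND recovery study at 20 replicates of K = 5 participants — sizes at
which every check is stable yet the whole suite completes comfortably on a
single core.

## Limitations

Only the 2x2 design is supported; larger factorial designs need different
bookkeeping and much more data. Wald tests and Hessian-based standard
errors are deliberately absent (likelihood-ratio tests are preferred).
Model-based analysis of response times is out of scope; the RT model in
the simulator exists to exercise the summary-statistics tests. And the
summary-statistics analyses inherit the classic caveat that they cannot
cleanly dissociate perceptual from decisional failures — for that, use the
GRT-wIND route.
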