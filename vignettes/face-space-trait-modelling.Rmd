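---
title: "Modelling and dissociating perceptual trait dimensions in face space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and dissociating perceptual trait dimensions in face space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`facespace` works with faces represented as points in a 100-dimensional
coordinate space: 50 shape dimensions and 50 reflectance dimensions, with
the average face of the generating population at the origin and each axis
expressed in population-SD units. A perceived attribute such as
attractiveness or sexual dimorphism (masculinity/femininity) is modelled as
a *trait direction*: the vector $\beta \in \mathbb{R}^{100}$ that best
predicts standardized mean ratings by ordinary least squares,

$$z_f \approx \beta_0 + \beta \cdot x_f,$$

where $x_f$ are face $f$'s coordinates and $z_f$ is the per-face mean
Likert rating (1–9 scale, averaged over raters, then z-scored across faces
with the $n-1$ SD). The fit is well-posed only when there are more faces
than dimensions; the package refuses to fit with $n \le 100$.

**SD units of exaggeration.** The rating data give no natural length for
$\beta$, so the package defines one exaggeration level as the displacement
that raises the *predicted standardized score* by exactly one:
$u = \beta / (\beta \cdot \beta)$ (`scaleToSDUnits()`). Moving a face by
$k\,u$ changes its predicted score by $k$, which makes validation slopes
directly interpretable (a perfectly calibrated rating experiment would show
about one rating-SD of change per level). An alternative convention —
normalising $\beta$ to unit coordinate length — would leave the predicted
score gain arbitrary; we document this choice rather than assert it is the
one used in any particular stimulus set.

**Orthogonalization.** To exaggerate one percept while holding another
constant, the target direction is purged of the nuisance direction by
Gram–Schmidt projection in the plain Euclidean metric of the coordinates:

$$\beta_\perp = \beta_t - \frac{\beta_t \cdot \beta_n}{\beta_n \cdot \beta_n}\,\beta_n,$$

then rescaled to SD units again. Because the nuisance model is linear,
moving along $\beta_\perp$ leaves the nuisance's predicted score unchanged
*exactly* — the dissociation identity, checked to 1e-10 in the test suite.
The Euclidean metric is the natural one here since the coordinate axes are
constructed to be orthogonal features. Rescaling after projection keeps
"+1 level = +1 SD of the target score" even though projection shortens the
vector; without it the target slope would shrink by the squared sine of the
angle between the directions.

Note what the identity does and does not claim: it is exact for
*model-predicted* scores. Whether human ratings of transformed faces
actually dissociate is an empirical question, which the validation
experiment (and its in-silico analogue below) addresses.

## Rating model and validation

Ratings of exaggerated faces are analysed with a hierarchical Gaussian
regression of the 1–9 rating on the exaggeration level (linear and
quadratic), face sex, rater sex and their interactions, with by-participant
and by-face random intercepts and slopes. Sex factors are dummy-coded with
male as the reference, so the `level` coefficient is the male-face linear
slope and `level:face_sexF` the female–male difference. Model selection
over the lattice of fixed-effect sets (always containing the linear term;
quadratic never without linear) uses WAIC,
$-2(\mathrm{lppd} - p_\mathrm{WAIC})$, computed from pointwise
log-likelihood draws.

Sampling is done with JAGS (via `rjags`), with the `glm` module loaded so
the Gaussian linear block is sampled jointly — without it, correlated
design columns (the intercept, `level2`, sex dummies) mix far too slowly.
Priors are weakly informative: normal(0, 5) on fixed effects,
half-Student-t(3, 0, 2.5) on all scale parameters, and a Wishart(I, K+1)
prior on each random-effect precision matrix, which implies marginally
uniform correlations between random effects. The treatment of ratings as
continuous Gaussian outcomes mirrors common practice for 9-point scales;
an ordinal likelihood is out of scope.

Defaults follow the full estimation settings (13,000 iterations, 3,000
burn-in, 4 chains); all shipped tests and the acceptance script use
desk-scale settings (2,000 iterations, 500 burn-in, 2 chains), which on the
validation-scale data (2,240 trials per cell) already give Rhat ≤ 1.01 for
every parameter. Convergence is summarised by the Gelman–Rubin Rhat per
parameter and a warning is raised whenever any exceeds 1.01. If a maximal
random structure will not converge, drop random correlations first, then
quadratic random slopes (`maximalRandomStructure()` builds the maximal
structure; `modelSpec()` takes any reduction).

**Bayesian correlations.** The correlation between two percepts' mean
ratings is estimated with a rank transform followed by a bivariate-normal
model. Under the Jeffreys prior the posterior of the covariance matrix is
inverse-Wishart in closed form, so the package draws 10,000 exact iid
posterior samples of $\rho$ instead of running MCMC; the EAP agrees with
the classical Spearman coefficient to well within Monte-Carlo error. A
minimal ridge (1e-10 of the average diagonal) keeps the scatter matrix
invertible when inputs are exactly collinear. Differences between two
independent correlations are formed draw-wise.

**Reliability.** Cronbach's alpha treats raters as items. ICC(2,1) is the
Shrout–Fleiss two-way random-effects, single-rater, absolute-agreement
intraclass correlation, with the consistency F-test on
$(n-1, (n-1)(k-1))$ degrees of freedom and the F-based 95% confidence
interval. Both are checked against explicit variance-decomposition oracles
in the tests, and the implementation was cross-validated against an
independent ICC implementation during development.

## What the synthetic generator emulates

`sampleFaces()` draws iid standard-normal coordinates — the idealisation of
a balanced computer-generated stimulus population. `makeGroundTruth()`
creates two unit-norm true directions whose cosine is controlled exactly;
the defaults (−0.4 for male-like simulations, −0.7 for female-like ones)
are round numbers near the negative masculinity–attractiveness rating
correlations the method is designed to confront. Ratings arise from

$$\ell_{pf} = b_0 + (b_1 + u^{(1)}_p)\,s_f + b_2 s_f^2 + u^{(0)}_p + w_f + \varepsilon_{pf},$$

with $s_f$ the face's true percept, rater random intercepts and slopes,
a face random effect and trial noise, followed by an affine map onto the
Likert scale (centre 5, gain 1) with rounding and clipping to 1–9. The
noise defaults (rater intercept 0.5, rater slope 0.2, face 0.3, residual
0.5) were chosen once so that simulated inter-rater reliability lands in
the moderate-to-high range typical of such rating studies (alpha ≈ 0.98,
ICC(2,1) ≈ 0.6 at 400 faces × 20 raters) and the ±3-level latent range
covers ratings of roughly 2–8, keeping floor/ceiling effects mild.

`simulateExperiment2()` reproduces the validation design: 20 base faces ×
7 levels (−3…+3) × 2 orthogonalized transformations = 280 stimuli, rated
by disjoint participant groups per task × transformation cell
(between-subjects). Crucially, the percepts driving simulated ratings come
from the *true* directions while the transformations use the *fitted*
ones, so estimation error leaks into nuisance-task ratings exactly as it
would in a real validation — with perfect estimation the nuisance slope is
zero by the dissociation identity, with finite-sample estimation it is
merely small.

What the generator does **not** emulate: real faces are not iid in feature
space, human raters drift and anchor, percepts need not be linear in the
coordinates, and Likert responses are ordinal rather than rounded Gaussian.
Passing tests therefore demonstrate that the estimation and validation
machinery is correct and well-calibrated under the stated model, not that
any particular human dataset will reproduce these numbers.

## Numerical choices and degenerate inputs

- Faces CSV serialization uses 17 significant digits, so
  `readFaces(writeFaces(S))` reproduces coordinates bit-exactly; direction
  JSON artifacts round-trip to ~1e-15 relative.
- Orthogonalizing a direction against a (near-)parallel one (relative
  residual norm < 1e-12) is an error, as is scaling a zero direction,
  standardizing ratings with zero variance of face means, or computing
  ICC on an incomplete matrix (no imputation).
- `fitTraitDirection()` refuses $n \le 100$ (underdetermined) and checks
  face-id alignment; per-face-sex fits need more than 100 faces per sex.
- All generator functions take explicit seeds, restore the caller's RNG
  state, and are bit-reproducible; MCMC chains get Mersenne-Twister seeds
  derived from the control seed.
- WAIC's log-mean-exp is computed with the max-shift trick.

## Problem sizes used in tests

The shipped tests run the model-building simulation at the study scale
(400 faces × 20 raters), the validation analogue at its design size (2,240
trials per cell) with desk-scale MCMC, a 20-replicate coverage study of the
linear-term credible interval on a deliberately small design (6
participants × 4 faces × 7 levels), and oracle comparisons on toy matrices.
These sizes were chosen as the smallest designs at which each property is
informative.

## Known limitations

- The Gaussian likelihood ignores the ordinal, bounded nature of ratings;
  slopes near the scale ends are attenuated.
- WAIC is computed from MCMC draws and inherits their Monte-Carlo error;
  ladders whose WAICs differ by less than a few units should be read as
  ties (the validation data themselves produce such ties).
- The "SD unit" convention ties exaggeration to predicted score SD; other
  stimulus pipelines may define it differently, so absolute slopes are
  comparable only within a convention.
- Rank-based Bayesian correlation treats ranks as bivariate normal; with
  heavy ties (coarse Likert means at small n) the CrI is approximate.
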