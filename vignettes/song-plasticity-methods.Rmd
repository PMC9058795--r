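---
title: "Models and methods for individual plasticity in birdsong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for individual plasticity in birdsong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songplast)
```

## The scientific problem

Territorial songbirds adjust their song from moment to moment: after a rival
or a potential mate disappears, successive songs within a recording may
lengthen or shift in frequency, and a bird singing high in the canopy faces
different transmission conditions and predation risk than one near the
ground.  `songplast` implements a reaction-norm analysis of such plasticity
for three song-level traits — song length (SL, seconds), maximum frequency
(MF, Hz; the largest per-syllable mean frequency within a song) and
short-term complexity (distinct syllable types divided by syllable count) —
asking three questions:

1. Do traits change, at the population level, with the within-recording
   order of songs (a proxy for time since a social stimulus) and with the
   relative singing position (0% ground to 100% canopy top)?
2. Do individuals *differ* in these responses (non-zero random-slope
   variance), and do responses covary across gradients and traits?
3. Are individual differences in plasticity *repeatable* across recordings
   made on different days?

## The random-regression model

For trait value $y_{ij}$ of song $j$ by individual $i$ (all continuous
variables z-transformed over the rows entering the fit),

$$
y_{ij} = \mathbf{x}_{ij}^\top \beta
       + u_{0,i} + u_{1,i}\, z(\text{order}_{ij})
       + u_{2,i}\, z(\text{position}_{ij})
       + y_{\text{year}(j)} + e_{ij},
$$

with fixed effects $\beta$ for date, age class (binary), z(order), z(singing
position), social-context dummies (female stimulus and no stimulus, against
the male-stimulus reference) and order-by-context interactions.  The
individual deviations $(u_{0,i}, u_{1,i}, u_{2,i})$ — per trait in the
bivariate SL + MF model, so a 6-dimensional vector there — follow a
multivariate normal with a free covariance matrix $G_c$ *estimated
separately for each social context* $c$; cross-context covariances are
structurally zero because each bird enters one context (one recording per
bird).  Year enters as a random intercept with covariance across traits, and
residuals are drawn jointly across traits with free covariance $R$.  Linear
reaction norms only: no quadratic gradients are fitted.

Rows with a missing singing position are listwise-deleted (the deletion
count is recorded on the design object), and by default only each
individual's first recording is retained, matching the single-recording
structure the covariance partition assumes.

## Gibbs sampler and priors

`gibbsSample()` runs a blocked Gibbs sampler (C++ core):

1. all location effects (fixed + every random level) are drawn jointly from
   their multivariate-normal full conditional — fixed-effect priors are
   independent normals with variance $10^8$, effectively flat on the
   z-scale;
2. each $G_c$, the year covariance and $R$ are drawn from inverse-Wishart
   full conditionals;
3. under the default *parameter-expanded* family, each random block
   additionally receives a Gaussian update of redundant multiplicative
   working scales $\alpha$ (one per trait-effect combination, prior
   $N(0, 1000)$): the block effects are rescaled as
   $u = \alpha \odot v$, $G = \mathrm{diag}(\alpha)\,\Psi\,
   \mathrm{diag}(\alpha)$.  This reparameterisation dramatically improves
   mixing, and reduces prior-induced bias, for variance components near
   zero; a plain inverse-Wishart family is available to check prior
   sensitivity and, as expected, yields somewhat larger variance estimates
   near zero.

Default hyperparameters follow the weakly-informative convention of the
mixed-model MCMC literature: per-block scale matrix $0.002\,I$ with degrees
of belief $\dim - 0.998$ (and likewise for the residual).  Two properties
motivated this over unit scale matrices: the conditional update stays proper
even when a context block has fewer levels than its dimension, and on
stage-2 repeatability models (small samples, variances around 0.1–0.3) unit
prior scales measurably biased the variance ratio downward while the weak
convention did not.  All hyperparameters are exposed on `modelSpec()`.

Chains are deterministic given the seed (the C++ core consumes R's RNG).
`publishedChains()` reproduces the published single-chain settings — 510,000
iterations, 10,000 burn-in, thinning 500, hence exactly 1000 retained draws
— while `fastChains()` defaults to four shorter chains so that the
rank-normalised split Gelman–Rubin statistic (`gelmanRubin()`) can be
computed; the split/rank-normalised variant was chosen because it is
strictly more conservative than the classic statistic (it also saturates:
even disjoint chains yield values near 1.8 rather than arbitrarily large
ones, so the conventional 1.1 threshold remains the reference point).

Numerical choices: location initialisation at 0, covariances at identity; a
one-shot diagonal jitter retry if a conditional precision loses positive
definiteness, then a hard abort naming the iteration; inverse-Wishart draws
via Bartlett decomposition.

## Posterior summaries

`summarizeFixedEffects()` reports posterior means, equal-tailed 95% credible
intervals (type-7 linear-interpolation quantiles — the convention is a
package choice; the original study does not state one), the probability of
direction $pd$ (share of draws with the median's sign, zeros split evenly)
and its two-sided analogue $2(1 - pd)$.  An effect is flagged significant
exactly when its CI excludes 0.  Variance CIs cannot cross zero, so
`summarizeVarianceComponents()` flags diagonal elements NA and reports
instead the posterior mass below a negligible-variance threshold (default
0.01 on the z-scale) as a reproducible stand-in for visual inspection of the
posterior.  Covariances are compared via `varianceContrast()` (posterior of
the difference) and transformed to correlations per draw with
`covToCorrelation()` (non-positive variance draws dropped and counted).

## Repeatability of plasticity

`slopeRepeatability()` implements the two-step estimator.  Stage 1 keeps
individuals whose first two recordings (by date) share a social context,
fits one model to the first and one to the second recordings (random
intercept plus the target gradient's slope), and extracts every retained
posterior draw of each individual's slope.  Stage 2 models the slope
estimates with recording order as a fixed factor and individual identity as
a random intercept and reports $R = V_{\text{ind}} / (V_{\text{ind}} +
V_{\text{res}})$.

Whether the retained draws should enter stage 2 stacked into a single
model or as one model per draw is a genuine design choice, and the two are
*not* equivalent.  Stacking all draws as rows of one model
(`method = "stacked"`) makes the individual intercept absorb the mean of the
two recording-level slopes, which allocates half of any between-recording
slope drift to the among-individual component: in generator experiments the
stacked estimate sits near 0.5 regardless of the true repeatability.  The
default (`method = "per_draw"`) therefore fits one stage-2 model per aligned
pair of stage-1 draws (a short Gibbs chain each, posteriors pooled), which
tracks the true ratio and propagates stage-1 uncertainty into the interval;
a moment-based ICC per draw (`method = "moment"`) gives a fast deterministic
approximation.  Because stage-1 slope estimates are shrunken and each draw
carries posterior noise, the estimator is attenuated — roughly 10–15
percentage points at the scales below — and R is a pragmatic, not
likelihood-exact, quantity; the same caveat applies to the published
procedure.  With ~11 individuals the credible intervals are necessarily wide
(width above 0.5), as in the original study.

## The synthetic-data generator

The generator inverts the model above so every stage is testable against
known truth.  Defaults emulate the study design: 185 focal males; context
frequencies 85/45/66 (male/female/none); 9–126 songs per recording (uniform
— only the observed span is reported); twelve study years with i.i.d.
multivariate-normal year effects; singing positions from a symmetric Beta on
[0, 100] (no distribution is published; positions are always generated, then
masked missing with probability 0.15, since an unobserved perch is still a
perch); 20% of birds with a second recording, 65% of those in the same
context.  Fixed-effect defaults are the published population-level
estimates, *including* date and age.  The random-effect covariance defaults
are the package's own realistic choice (the published matrices are not part
of the machine-readable record): intercept variances 0.25, order/position
slope variances 0.05–0.15 concentrated in the male and no-stimulus
contexts, negative order–position slope correlations in the male context
mirroring the reported trade-offs, residual variances around 0.6 with
cross-trait correlation 0.3 — all on the z-scale.

Trait values are emitted on the model (z) scale with the noiseless linear
predictor saved alongside; fixed affine maps to natural units (seconds, Hz,
ratio) support the syllable-level generator, which plants well-separated
Gaussian clusters in the 5-feature space, matches each song's complexity
target within rounding, and tiles the song length exactly with syllable
onsets and durations.

Recording-level slope drift with standard deviation `repeatNoiseSd` gives a
tunable true slope repeatability $R = \sigma^2_{\text{slope}} /
(\sigma^2_{\text{slope}} + \text{repeatNoiseSd}^2)$; the default is 0 (no
drift), so repeatability scenarios set it explicitly.

What the generator does *not* emulate: acoustic measurement error and
segmentation mistakes, temporal autocorrelation of successive songs beyond
the linear order trend, context choice that depends on the bird, unbalanced
missingness (missingness is completely at random) and non-linear reaction
norms.  Passing tests therefore demonstrate correctness of the machinery
under the model's own assumptions, not robustness to their violation.

## Syllable typing

`fitSyllableTypes()` clusters the five spectro-acoustic features (duration,
minimum/maximum frequency, bandwidth, mean frequency) with k-means, K = 200
by default as in the original study, using k-means++ seeding and the best
of several restarts by within-cluster sum of squares — plain random starts
visibly degrade label recovery at K above ~20.  Features are clustered on
their raw scales by default (the original feature scaling is unstated); a
`standardize` switch is provided.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments are run at reduced but
informative sizes chosen by the package: calibration over 20 replicate
cohorts of 60 birds x 20 songs with 26,000/1,000/25 chains; slope-variance
recovery at 200 birds x 40 songs; repeatability at 40 birds x 30 songs x 2
recordings (and a study-sized 11-bird cohort); prior-moment recovery at
50,000 draws.  Full-scale bivariate fits (185 birds, all contexts) run in
minutes to tens of minutes per chain and are left to the user.

## Known limitations

- One or two responses only; no three-trait model (the original study also
  could not fit one).
- No REML/ML path, no stimulus-identity random effect, no
  position-by-context interactions (out of scope by design).
- The stage-2 repeatability model treats slope draws as exchangeable
  observations; R is attenuated by shrinkage and posterior noise as
  discussed above.
- Listwise deletion assumes positions are missing completely at random,
  which is exactly true only for the generator.
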