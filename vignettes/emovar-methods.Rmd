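---
title: "Momentary emotion differentiation and regulation variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Momentary emotion differentiation and regulation variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emovar)
```

## The scientific problem

Experience-sampling (ESM) studies beep adolescents several times a day and ask
them to rate their current emotions and the regulation strategies they used
since the last beep. Two within-person quantities are of central interest:

* **Momentary emotion differentiation** — how distinctly same-valence emotions
  move at a given assessment. When all negative emotions rise and fall in
  lockstep, the person is treating them as one undifferentiated blob; when
  they deviate from their person means in different directions, the person is
  differentiating.
* **Momentary emotion regulation variability** — how much the profile of
  strategy use at one assessment deviates from the person's other
  assessments, either because strategies were swapped (switching) or because
  overall strategy endorsement changed (endorsement change).

The package computes these indices, fits the lagged multilevel models that
link them (with equivalence testing for the "no reverse effect" hypothesis),
and estimates a stacked within-person 1-1-1 mediation from lagged
differentiation through regulation variability to emotion intensity. Because
the five original datasets are external, the package ships synthetic
generators with known ground truth; every estimator is validated by parameter
recovery rather than by reproducing published coefficients.

## The momentary differentiation index

For one person with ratings `x[t, j]` (moments `t = 1..T`, items
`j = 1..k`), item-center the matrix, `d[t, j] = x[t, j] - mean_t x[t, j]`,
and let `rbar[t]` be the mean deviation at moment `t`. The index is

```
ED[t] = -k * rbar[t]^2 / MS_E,
MS_E  = sum((d[t, j] - rbar[t])^2) / ((T - 1) * (k - 1)).
```

`MS_E` is the residual (moment-by-item interaction) mean square of the
two-way layout; the numerator is the moment's contribution to the between-
moment mean square `MS_R = k * sum(rbar[t]^2) / (T - 1)`. The index is an
assessment-level decomposition of the average-measures consistency ICC,
`(MS_R - MS_E) / MS_R`: the person mean of `ED[t]` is a strictly decreasing
function of `MS_R / MS_E`, so persons with high consistency ICC
(undifferentiated emotions) have strongly negative mean `ED`. The index has
an upper bound of 0 (attained exactly when a moment's item deviations average
zero) and no lower bound.

The published description of the index pins these properties — the upper
bound, the person-level denominator, lockstep moments scoring low — without
printing the closed form, so the formula above is the unique ANOVA-consistent
choice satisfying all of them. It is isolated in `momentary_ed()` so an
alternative denominator can be swapped in; the property tests (bound,
zero-attainment, ICC monotonicity, shift and scale invariance) hold for any
positive person-level denominator.

Moments with a missing item are excluded from the decomposition and receive a
missing index: the ICC-style arithmetic is not defined for partial rows, and
the source studies used forced response so partial rows do not arise in the
target data. Perfectly parallel items (`MS_E = 0`) make the index undefined;
the person gets all-missing values and a warning rather than infinities.

## Regulation variability: Bray-Curtis with Baselga's partition

For two strategy profiles `u`, `v` (nonnegative), with
`A = sum(pmin(u, v))`, `B = sum(pmax(u - v, 0))`, `C = sum(pmax(v - u, 0))`:

```
full = (B + C) / (2A + B + C)         # Bray-Curtis dissimilarity
bal  = min(B, C) / (A + min(B, C))    # balanced variation  (strategy switching)
gra  = full - bal                     # abundance gradient  (endorsement change)
```

All three lie in [0, 1] and `full = bal + gra` exactly. The momentary index
at assessment `t` averages the pairwise values between `t` and every other
usable assessment of the same person (each component averaged separately, so
additivity is preserved), then multiplies by 10 to give a 0-10 range.
A constant 0.001 is added to every regulation rating first, so two all-zero
moments — both strategies unused — remain comparable instead of dividing by
zero. The constant is applied to regulation items only; the differentiation
index is shift-invariant so it would be a no-op there. A `successive` mode
(compare `t` with `t - 1` only) is available for sensitivity analysis.

`momentary_erv()` computes all pairs through a Manhattan-distance identity
(`A = (s_t + s_s - L1)/2` etc.), keeping the `T x T` work in compiled code;
the scalar kernel `bray_curtis_pair()` is the reference implementation the
vectorised path is tested against, alongside the direct
`sum|u - v| / sum(u + v)` oracle and `vegan::vegdist`.

## Preprocessing conventions

* Items are linearly rescaled to 0-10 from their instrument bounds.
* Person-level exclusions: zero variance in the pooled items of the
  positive-emotion, negative-emotion, or regulation scale (the zero-variance
  test is scale-level — the stacked item vector — because the exclusion is
  described at the scale level; an item-level reading would exclude more
  persons), and mean reaction time strictly below 500 ms.
* Within/between decomposition: `raw = grand mean + (person mean - grand
  mean) + (raw - person mean)`, with person means over all available
  observations and the grand mean over the pooled sample (the analyses pool
  datasets, with dataset-level terms absorbing level differences). Components
  are computed **before** lagging.
* Time is centered at the design midpoint, observation 35.5 of 70.
* Lags shift by one *answered* assessment within person and never cross
  persons or datasets. They cross day boundaries by default, since the models
  lag by assessment with no stated day break; `break_at_day = TRUE` gives the
  alternative. Unanswered beeps are absent rows, so a lag can span a gap; the
  equal-interval treatment below already accepts this approximation.

## The cross-lag models

Outcomes at assessment `t` are regressed on person-centered (within)
predictors — entered as fixed effects and person-level random slopes with a
freely estimated covariance matrix — plus between-person components, centered
time, grand-mean-centered age and a female indicator. Persons are nested in
datasets; the dataset term is a random intercept by default, or fixed
indicator columns (with five datasets the two are numerically close; the fit
records which was used). The frame of reference makes regulation variability
(rated "since the last beep") precede the differentiation index of the same
assessment, so the variability-to-differentiation model uses same-assessment
pairs while the differentiation-to-variability model uses the lagged index.
Regulation intensity enters the latter concurrently (it is the intensity from
which the same-assessment variability is computed); a configuration switch
allows the lagged alternative.

Residuals can carry an AR(1) structure ordered by observation index, treating
intervals as equal. Estimation uses `nlme::lme` when AR(1) is requested and
`lme4::lmer` otherwise — the two agree on white-noise data (tested), and the
lme4 path is roughly an order of magnitude faster, which matters for the
replicated simulations. Non-convergence triggers staged simplification
(covariances dropped, then slopes), each step logged in the fit's `notes`;
a fit that still fails is returned flagged, never silently. Wald confidence
intervals are used throughout: 95% for effect tests, 90% for equivalence.
Constant (zero-information) fixed-effect columns are dropped with a note, so
a degenerate moderator reduces to the unmoderated model; genuinely collinear
designs raise an error naming the offending columns.

Equivalence testing follows the two one-sided tests (TOST) logic:
equivalence is concluded when the 90% CI lies strictly inside ±0.187, the
reference slope of the pooled design's power analysis.

## Stacked 1-1-1 mediation

Each complete analysis row is split into a mediator row (`s_m = 1`,
outcome = regulation variability) and an outcome row (`s_y = 1`,
outcome = emotion intensity). One mixed model on the stacked data estimates
simultaneously the a-path (lagged within-person differentiation on the
mediator side), and the b- and c'-paths (variability and lagged
differentiation on the outcome side), with covariates entered
selector-specifically on both sides. Person-level random a and b slopes have
an estimated covariance `sigma_ab`, and the within-person indirect effect is

```
indirect = a * b + sigma_ab
```

— the covariance term captures person-level co-moderation: if persons with a
stronger a-path systematically have a weaker b-path, `sigma_ab` can offset
the product and annihilate the average mediation.

Defaults: random selector intercepts plus random a and b (intercept block
diagonal, slope block fully covarying); random c' is omitted — it does not
enter the indirect effect and costs identifiability at realistic N — but can
be added via the model options. With the nlme engine the two row types get
selector-specific residual variances (`varIdent`), appropriate because
mediator and outcome are on different scales; the lme4 engine is
homoscedastic and is the fast path used in replicated simulations.

The Monte-Carlo interval draws `(a*, b*)` from the bivariate normal of the
fixed effects, and `sigma_ab*` from a normal with its asymptotic SE; each
draw's indirect effect is `a* b* + sigma_ab*`, and the CI is the 2.5/97.5
percentile range of 20,000 draws (seed mandatory). Draws implying
`|rho| > 1` given the estimated path SDs are clipped to the boundary and
counted in the diagnostics. The asymptotic SE of `sigma_ab` comes from the
fitted model's variance-parameter covariance: with nlme, from `apVar` in its
natural parametrisation (log-SDs and `2*atanh(rho)`) by the delta method;
with lme4, from a central-difference Hessian of the ML deviance in
`(theta, log sigma)` followed by the same delta method. When neither is
available the fit is flagged, the CI ignores the covariance uncertainty, and
a warning is raised.

## The synthetic generators

No generative model for the original five datasets is published; both
generators are stand-ins whose latent mechanisms are package choices, and
they are labelled as such.

**Index-level** (`sim_index_data()`): per person, paths
`(a_i, b_i)` are bivariate normal around `(a, b)` with SDs `(sd_a, sd_b)`
and correlation `rho_ab`; an exogenous differentiation stand-in `D_t` is a
stationary AR(1) (marginal SD 1); then `M_t = a_i D_{t-1} + e_M` and
`Y_t = b_i M_t + cprime D_{t-1} + e_Y`. The true indirect effect is
`a*b + rho_ab*sd_a*sd_b`. Defaults: `a = -0.3`, `b = 0.4`, `cprime = 0.1`,
`sd_a = sd_b = 0.1`, `rho_ab = 0`, `phi = 0.3`, unit residual SDs — effect
and heterogeneity sizes in the range ESM cross-lag studies report, large
enough to be detectable at N = 200 x 70 but far from deterministic.
Optional `gamma_a`/`gamma_b` make the person paths depend linearly on a
standard-normal person covariate, giving a known co-moderation structure.
This generator carries the exact ground truth used by the recovery,
coverage and co-moderation tests; its cross-lag truth is the primary
recovery surface because the derived indices are nonlinear in items, so no
exact item-level truth propagates to the index scale.

**Item-level** (`sim_esm_items()`): the five-dataset pooled design (N = 83,
97, 202, 178, 218; 10x7 or 5x14 = 70 scheduled beeps; item counts per
dataset as published). Same-valence emotion items load on a person-specific
AR(1) affect factor with loadings perturbed per moment (`het`), so the
differentiation index genuinely fluctuates — at `het = 0` items move in
lockstep and the index collapses toward its floor. Regulation items follow a
Markov chain over strategy-emphasis regimes (switching) plus a person-level
endorsement random walk (endorsement change), so both Bray-Curtis
subcomponents fluctuate by construction. Assessments are missing completely
at random with a per-person answering probability drawn from a Beta
distribution with mean `1 - missing_rate` (default 0.74) and SD 0.23,
matching the pooled compliance statistics; MCAR is the simplest mechanism
consistent with a reported compliance rate. Default latent parameters were
calibrated once so per-item intraclass correlations fall inside the
published 0.19-0.64 band; `item_iccs()` recomputes and can warn when a
configuration leaves it. Ratings are clipped to the instrument scale (0-10
for all default designs). What the generator does *not* emulate: circadian
structure and the semi-random beep schedules, unequal intervals,
non-random missingness, item-specific response styles. Passing tests
therefore demonstrate estimator correctness under a plausible ESM-like
process, not agreement with the original datasets.

Seeding: one global seed expands to per-person substreams
(`seed * 69069 + counter, mod 2^31 - 1`), so adding persons or datasets
never reshuffles earlier persons' draws and runs are bit-reproducible.

## Numerical choices and degenerate inputs

* `full = bal + gra` holds to machine precision by construction; tests
  assert 1e-12.
* `MS_E = 0`, all-zero strategy pairs without the shift, fewer than 3 usable
  moments, fewer than 2 items, single-observation persons, duplicated
  observation indices, out-of-bounds ratings and rank-deficient designs all
  have explicit, tested behaviors (missing values with warnings, or errors
  naming the offender) rather than silent propagation.
* The Monte-Carlo interval is percentile-based; its degenerate limit (all
  variances zero) is a point interval.
* Replicated simulations in the test suite use the lme4 engine without
  random intercepts when the generating truth has none; problem sizes are
  N = 200 persons x 70 beeps with 200 replicates (cross-lag recovery and
  type-I error), 300 replicates (mediation coverage) and 60 replicates at
  N = 100 (co-moderation null), chosen to keep Monte-Carlo error on
  coverage around one percentage point while the whole suite stays desk-
  scale.

## Known limitations

* Published coefficient tables from the original pooled analysis are not
  reproduction targets: they require the original datasets and solver
  parity. The package validates by ground-truth recovery instead.
* Equal intervals are assumed wherever lags or AR(1) structures appear.
* The exact random-effects layout of the original stacked mediation and its
  covariance-draw treatment are not fully published; the defaults above are
  documented assumptions, adjustable through the fitting options.
* The three-level AR(1) + random-slopes combination can be slow and fragile
  in nlme at pooled-sample size; the staged-simplification path and the
  lme4 alternative are the pragmatic remedies, and each fit records what it
  actually estimated.
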