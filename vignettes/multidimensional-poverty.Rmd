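---
title: "Measuring multidimensional poverty with afpoverty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring multidimensional poverty with afpoverty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afpoverty)
```

## The measurement problem

Income alone is a poor yardstick for deprivation in largely non-monetary
rural economies: where half of households report no cash income at all, an
income line classifies nearly everyone as poor and differentiates nothing.
The counting approach of Alkire and Foster instead asks, indicator by
indicator, whether a household is deprived — in schooling, child health,
diet, electricity, water, sanitation, housing, cooking fuel, assets — and
aggregates the *breadth* of deprivation into a single decomposable index.
This package implements that estimator for household surveys with a
stratified, clustered sampling design, together with the spatial smoothing
and asset-based wealth scoring that typically accompany it in baseline
assessments of development programs.

## The Alkire–Foster estimator

Let $g^0$ be the $n \times 11$ binary deprivation matrix produced by
`deprivation_matrix()`: $g^0_{ij} = 1$ when household $i$ fails indicator
$j$'s deprivation cut-off. Indicators sit in three dimensions weighted
equally (education, health, living standard), with weights nested equally
inside each dimension *except* that health splits its share as
$(1/6, 1/12, 1/12)$ across its three indicators; the full weight vector is

$$w = \left(\tfrac16,\tfrac16,\tfrac16,\tfrac1{12},\tfrac1{12},
\tfrac1{18},\tfrac1{18},\tfrac1{18},\tfrac1{18},\tfrac1{18},\tfrac1{18}\right).$$

Every weight is an exact multiple of $1/36$, and the package stores and
sums them as integer numerators over that common denominator. The weighted
deprivation score $c_i = \sum_j w_j g^0_{ij}$ is therefore computed in
integer arithmetic, which matters at the identification step: with poverty
cut-off $k = 1/3$, a household deprived in exactly $12/36$ of the weighted
indicators lies *on* the cut-off, and floating-point summation of elevenths
and eighteenths would classify such ties unpredictably. Identification is
inclusive by default (poor iff $c_i \ge k$; `inclusive = FALSE` gives the
strict rule), a consequential choice precisely because $k$ is attainable.

Scores of the non-poor are then censored to zero and aggregated with the
sampling weights $s_i$ (inverse household selection probabilities):

$$H = \frac{\sum s_i \mathbf{1}[c_i \ge k]}{\sum s_i}, \qquad
A = \frac{\sum s_i c_i \mathbf{1}[c_i \ge k]}{\sum s_i \mathbf{1}[c_i \ge k]},
\qquad M_0 = H \times A,$$

with $A \equiv 0$ when $H = 0$ so the product identity always holds. $M_0$
equals both the weighted mean censored score and
$\sum_j w_j \mathrm{CH}_j$, where the censored headcount $\mathrm{CH}_j$
is the weighted share of households simultaneously poor and deprived in
indicator $j$; the three-way identity is verified to $10^{-12}$ in the test
suite against a brute-force per-household oracle. Indicator contributions
$w_j \mathrm{CH}_j / M_0$ sum to one whenever $M_0 > 0$ and are reported as
`NA` (undefined) when no household is poor. The index is additively
decomposable: `af_by()` returns subgroup fits whose population-share
weighted $M_0$ recombines exactly to the pooled value.

### Indicator rules worth flagging

Three rules involve judgment calls that the package resolves explicitly:

* **Child enrollment.** The deprivation is a school-aged child (7–14) not
  attending school. Households with no school-aged child are non-deprived
  on this indicator, the usual convention for non-applicable indicators.
* **Water.** Deprived when the source is a river *or* water is more than
  30 minutes away *and* fetched on foot; a long motorised trip does not
  count. The rule's operator precedence follows the plain-language
  description of the deprivation, not the ambiguous comma placement a
  questionnaire rendering can produce.
* **Missing data.** Any missing field required by a rule raises an error;
  nothing is imputed. Surveys analysed with this package are expected to be
  restricted to complete interviews first.

### The robustness grid

`af_robustness()` re-estimates $H$ over a grid of cut-offs. For the default
weights the attainable positive scores are every multiple of $1/36$ from
$2/36$ upward except $1/36$; the conventional reporting grid for this
11-indicator index, however, runs 11.1%, 16.7%, then every multiple of
$1/36$ from 22.2% through 66.7% — 19 cut-offs, skipping the attainable but
rarely tabulated values $5/36$ and $7/36$. We default to the 19-value
reporting grid for comparability with published robustness tables and
expose `attainable_scores()` so users can krige the full attainable set;
with any non-default weight vector the default grid *is* the attainable
set, computed by exact subset-sum enumeration.

## Design-based variance

All confidence intervals are Taylor-linearized under the standard
with-replacement approximation for two-stage designs: the linearized score
of each estimator (mean, proportion, or ratio for $A$) is totalled per
primary sampling unit (the enumeration area), and between-PSU variation is
accumulated within strata ($\hat V = \sum_h \frac{n_h}{n_h-1}
\sum_c (z_{hc} - \bar z_h)^2$), with no finite-population correction.
Intervals use a normal reference rather than $t$: designs in this setting
have hundreds of PSUs, where the difference is negligible. A stratum
containing a single PSU cannot contribute a variance estimate and is
treated as a certainty unit (zero contribution) with a warning — a
deliberate, slightly anti-conservative convention that the warning makes
auditable.

One limitation deserves emphasis. The with-replacement variance treats PSU
effects as independent. When area-level poverty is spatially autocorrelated
— which is exactly what the kriging module exists to exploit — a single
spatial realisation carries less information than independent PSUs would,
and the design-based interval understates the uncertainty of
superpopulation parameters. Our coverage experiment (below) therefore
validates the estimator under the sampling model it actually assumes.

## The synthetic survey generator

No suitable public microdata accompanies this class of baseline survey, so
the package ships a generator whose output exercises every downstream
stage. Its defaults are the study conditions the estimators assume: 259
EAs of 15 households each (≈3,885 households), 96% of EAs rural, four
districts laid out as contiguous bands of a 100×100 planar region, and
indicator deprivation targets equal to the 11 standard marginal rates
(14.7%, 17.6%, 21.5%, 15.4%, 30.4%, 95.1%, 29.7%, 75.6%, 92.5%, 95.9%,
43.2%).

The data-generating process is a probit threshold model. Each EA receives
a poverty propensity $a_e$ drawn from a zero-mean Gaussian process with
exponential covariance $\sigma^2 e^{-d/\rho}$ (defaults $\sigma^2 = 0.3$,
$\rho = 10$ distance units — an intra-class correlation of 0.23, high but
defensible for infrastructure indicators that cluster at village level);
household $i$ in EA $e$ is deprived on indicator $j$ iff
$a_e + \varepsilon_{ij} < t_j$ with $\varepsilon_{ij} \sim N(0,1)$ and
$t_j = \Phi^{-1}(p_j)\sqrt{1+\sigma^2}$ (`calibrate_threshold()`), so each
marginal rate equals its target in expectation while households within an
EA — and nearby EAs — are positively correlated. Raw survey fields are then
drawn uniformly inside the deprived or non-deprived region of each rule,
so the rule engine reconstructs exactly the simulated deprivations;
within-category detail (a literacy score of 7 versus 12) is cosmetic, since
only the binary outcome enters the index.

The remaining blocks: sampling probabilities follow a two-stage design
(EAs proportional to a synthetic size measure, households
equal-probability within EA; stratum = district × urban/rural); monetary
income is zero with probability 0.49 and lognormal
($\mu = \log 300$, $\sigma = 1$ meticais/month) otherwise; household size
is $1 + \mathrm{Poisson}(3.5)$ (median 4); and 37 binary asset items follow
a one-factor probit model on a latent wealth score negatively correlated
with the EA poverty propensity, with loadings $U(0.5, 1.5)$ and thresholds
$U(-1.5, 1.5)$.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: indicator-specific intra-class correlations
(a single shared EA effect drives all eleven indicators), systematic
district-level differences (district effects are zero by default, so the
generator will not reproduce any particular district ranking), item
nonresponse, interviewer effects, or the quadrant-walk household selection
of field practice. The generator validates the *estimators*; it is not a
population model of any real province.

### The coverage experiment

Confidence-interval coverage for $H$ is measured over 500 replicate
two-stage samples (60 EAs × 8 households — sizes chosen to keep the whole
experiment a few seconds while leaving the PSU count realistic) against
the analytic superpopulation headcount, computed exactly by Gauss–Hermite
quadrature over the EA effect and dynamic programming over the integer
score distribution (`expected_headcount()`). Replicates use a negligible
spatial range, i.e. independent EA effects: that is the with-replacement
sampling model under which the Taylor variance is derived. Under the
spatially correlated default the same intervals cover at roughly 70% —
the limitation discussed above, reproducible by changing one argument.

## Kriging

`ea_headcounts()` aggregates the censored scores to EA-level $M_0$ values;
`krige_ok()` smooths them over a grid by ordinary kriging, solving at each
node the usual system with the Lagrange unbiasedness constraint (weights
sum to one; verified to $10^{-8}$). The semivariogram is estimated by the
classical binned estimator and fitted by weighted least squares (weights =
pair counts) over nugget, partial sill and range, with box constraints for
non-negativity; the family defaults to exponential — smooth at small lags
and the common default for this kind of area-level smoothing — with
spherical and Gaussian selectable. Degenerate fits fall back to a
nugget-only model with a warning. With a zero nugget the predictor
interpolates the data exactly; a numerically singular system receives a
single $10^{-10}$ ridge before failing. Predictions are kept raw in the
data product and clamped to $[0,1]$ only in the display column, since a
proportion's kriged value can legitimately exit the unit interval. The
pipeline kriges district by district (default 40×40 nodes per district),
matching how such maps are read; a pooled surface is a one-call variant.

## The wealth index

The permanent-income score reduces, for dichotomous items, to a one-factor
binary-probit latent-trait model: item $l$ is owned with probability
$\Phi(\alpha_l + \beta_l z)$, $z \sim N(0,1)$. `wealth_fit()` maximises the
marginal likelihood by EM over a 21-node Gauss–Hermite grid: the E-step
assigns each household posterior weight over nodes; the M-step refits each
item's $(\alpha_l, \beta_l)$ by weighted probit likelihood on the node
grid, with $\beta_l$ bounded below by zero so that ownership indicates
wealth. The observed-data log-likelihood is checked non-decreasing across
iterations; items owned by everyone or no one are dropped with a warning.
Households are scored by their expected a-posteriori $z$, min–max rescaled
to $[0,1]$ over the scored sample — the scale on which such indices are
conventionally tabulated. The lowest-quintile flag uses the weighted 20th
percentile (smallest value whose cumulative weight share reaches 0.2),
flagging all boundary ties. The $1.25/day comparator converts monthly
meticais at 30 MZN/USD over 30.44 days/month, per capita; all three
constants are arguments.

## Numerical choices, at a glance

* Weights and scores: exact integer arithmetic over the least common
  denominator; cut-off comparisons use a $10^{-9}$ guard so attainable
  boundary scores classify exactly under either identification rule.
* $A = 0$ (and contributions `NA`) when $H = 0$; no `NaN` ever propagates.
* Variance: with-replacement linearization, no FPC, normal reference,
  lonely PSUs as certainty units.
* Variogram WLS: L-BFGS-B with tight convergence (`factr = 10`), so
  noiseless model bins are recovered to ~$10^{-6}$.
* EM convergence: absolute log-likelihood change below $10^{-6}$,
  cap 200 iterations, non-convergence flagged not hidden.
* Test problem sizes: engine identities on 100–250×11 matrices, calibration
  on a 200-EA × 15-household survey, coverage on 500 × (60×8) replicates,
  variogram recovery on 10 × 500-point fields, wealth recovery on
  2,000×37 items — each the smallest size at which the property under test
  is comfortably identified.

## Limitations

Beyond the generator caveats above: the package estimates $M_0$ only (the
censored-headcount member of the AF family — the natural one for binary
indicators), not the depth- or severity-adjusted members; kriging is
isotropic ordinary kriging, with no trend or anisotropy modelling; the
wealth model is single-factor with item independence given the trait; and
design-based intervals inherit the with-replacement approximation's
optimism when PSUs are few or spatially correlated.
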