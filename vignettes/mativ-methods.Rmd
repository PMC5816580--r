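---
title: "Methods: linking catchment land use to estuarine benthic vegetation"
author: "mativ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking catchment land use to estuarine benthic vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mativ)
```

## The scientific problem

Nutrient over-enrichment shifts the benthic vegetation of shallow estuaries
from seagrass towards fast-growing macroalgae. The ratio of macroalgal area
to total vegetated area,

$$\mathrm{MA{:}TV} = \frac{A_{\mathrm{MA}}}{A_{\mathrm{MA}} + A_{\mathrm{SG}}} \in [0, 1],$$

is a practical eutrophication indicator that can be mapped from aerial
imagery, and `mativ` provides the statistical machinery to relate it to
catchment descriptors in a small survey of estuaries: which of several
candidate predictors (catchment:estuary area ratio, flushing time,
population, land-use proportions, areal nitrogen load) matter, how much
variance each explains on its own, and where along the percent-fertilized
gradient the vegetation balance tips.

A survey of this kind has few estuaries (on the order of 14) and several
correlated, strongly right-skewed predictors, which drives every design
choice below: heavy predictor screening before model fitting, Bayesian
model averaging rather than a single selected model, and an exact (not
approximated) variance decomposition.

## Predictor screening and transformation

`pairwise_correlations()` computes the Pearson correlation matrix of the
raw predictors. `screen_collinearity()` then treats pairs with
$|r| > 0.7$ (the `screening_threshold`, unitless, default 0.7) as edges of
a graph; each connected component is an inter-correlated set, of which a
single member is retained: the one with the smallest sum of absolute
correlations to the predictors *outside* the set, i.e. the member least
entangled with the rest of the design. Ties are broken by column order and
every decision is written to an audit log. Absolute correlations are used
throughout because the sign of a correlation is irrelevant to collinearity.

Right-skewed predictors are taken onto the natural-log scale by
`log_transform_skewed()`. The default is an explicit list — C:E ratio,
% urbanized, % fertilized, areal DIN load — matching the predictors a
land-use table of this kind has strongly right-skewed; an automatic mode
transforms any column whose adjusted Fisher–Pearson sample skewness
exceeds 1. Zeros in percentage columns make a plain log undefined, so an
opt-in `offset` flag switches to $\ln(x+1)$; it is off by default so the
package never silently alters data. Finally `standardize()` centres and
scales each column to mean 0, sample SD 1 (the $n-1$ denominator),
recording the means and SDs so coefficients can be mapped back.

## Stochastic-search variable selection

Variable selection is Bayesian, by Gibbs sampling over binary inclusion
indicators (the Kuo–Mallick spike-and-slab form):

$$y_i \sim \mathrm{Normal}\!\left(\beta_0 + \textstyle\sum_j g_j\,
\theta_j\, z_{ij},\ \sigma\right),\qquad
g_j \sim \mathrm{Bernoulli}(p_0),\qquad
\theta_j \sim \mathrm{Normal}(0, \tau^2).$$

The indicator-times-slab form is used because it matches a stochastic
search over models directly: the posterior mean of $g_j$ *is* the
posterior inclusion probability $\Pr(\mathrm{Inc})_j$, with an exact,
uninformative prior of $p_0 = 0.5$. Importance is judged on the posterior
odds ratio

$$\mathrm{POR}_j = \frac{p_j/(1-p_j)}{p_0/(1-p_0)},$$

which equals exactly 3 at $\Pr(\mathrm{Inc}) = 0.75$ — the conventional
cut-off; `important` in the output is equivalent to either formulation.
Reported coefficients are model-averaged (draws with $g_j = 0$ contribute
zeros), so unimportant terms show near-zero $\beta$ with small SD rather
than a conditional estimate.

Tunables, all on the standardized predictor scale: slab SD $\tau = 1$
(an included standardized coefficient of order one is plausible a priori),
intercept prior Normal(0, sd 10), residual SD prior Half-Normal(0, 1) —
weakly informative for a response bounded in $[0,1]$. None of these is
critical at the default settings and all are arguments. While a term is
excluded its slab coefficient is refreshed from the prior, which keeps the
indicator chain mixing. The sampler runs 3 chains of 12 000 iterations
with 5 000 burn-in by default; a fixed `sigma` argument makes the model
fully conjugate, which the test suite uses to compare the sampler against
exact enumeration of all $2^k$ models.

The three-way interaction model (`build_interaction_design()`) expands
C:E ratio, flushing time and % fertilized into seven terms — three mains,
three pairwise products, the triple product — forming products on the
transformed+standardized scale and re-standardizing, so all terms share
the prior scale.

## Hierarchical partitioning

`hier_part()` decomposes goodness-of-fit exactly. With OLS $R^2$ as the
fit measure, the independent contribution of predictor $j$ is its Shapley
value over the $2^k$ subset fits,

$$I_j = \sum_{S \subseteq P\setminus\{j\}}
\frac{|S|!\,(k-|S|-1)!}{k!}\left[R^2(S\cup\{j\}) - R^2(S)\right],$$

equivalently the mean of $j$'s incremental $R^2$ over all $k!$ predictor
orderings (the test suite checks this equivalence to $10^{-10}$ for
$k \le 5$). The joint contribution is $J_j = R^2(\{j\}) - I_j$ and may be
negative under suppression; it is reported, never clipped. Shapley
efficiency guarantees $\sum_j I_j = R^2_{\mathrm{full}}$, and the
percentages reported are $100\,I_j/\sum_k I_k$, which sum to exactly 100
before rounding. The enumeration is guarded at $k \le 13$ (8192 OLS fits);
beyond that the user must reduce the predictor set, which screening
normally has done already.

## The change-point model

The relationship between MA:TV and percent catchment fertilization $F$
(raw 0–100 scale, deliberately untransformed — its prior lives on that
scale) is modelled as two linear segments meeting at a change-point
$\gamma$:

$$\mathrm{MA{:}TV}_i \sim \mathrm{Normal}(\mu_i, \sigma),\qquad
\mu_i = \alpha\,\delta(F_i-\gamma) + \beta_1\,\delta(\gamma-F_i)\,F_i +
\beta_2\,\delta(F_i-\gamma)\,F_i,$$

with $\delta(u) = 1$ for $u \ge 0$ and 0 otherwise. Below $\gamma$ the
ratio rises from zero with slope $\beta_1$; at and above $\gamma$ it jumps
to intercept $\alpha$ with slope $\beta_2$. `piecewise_mean()` evaluates
this formula literally, including the corner case $F = \gamma$ where both
indicators are 1 and both slope terms contribute — a deliberate fidelity
to the model as specified rather than a smoothed variant.

Priors: $\alpha, \beta_1, \beta_2 \sim \mathrm{Normal}(0, \mathrm{sd}=2)$
(the 2 is an SD, not a variance), $\gamma \sim \mathrm{Uniform}(0, 100)$,
and — unstated by the model's provenance, so a package choice —
$\sigma \sim \mathrm{HalfNormal}(0, 1)$, weakly informative for a
$[0,1]$-bounded response. Sampling is Metropolis-within-Gibbs: given
$\gamma$ the model is linear, so $(\alpha,\beta_1,\beta_2)$ get a
conjugate multivariate-normal draw; $\gamma$ and $\log\sigma$ move by
random-walk Metropolis whose step sizes adapt during burn-in towards an
acceptance rate of 0.3–0.5 and are frozen afterwards (so the retained
chain is a valid fixed-kernel sampler). Chains start from dispersed
change-points (prior quantiles at $c/(C+1)$ for chain $c$) with zero
coefficients. Defaults: 3 chains × 12 000 iterations, 5 000 burn-in.

Convergence is monitored by the Gelman–Rubin potential scale reduction
factor per parameter,
$\hat R = \sqrt{\left(\frac{n-1}{n}W + \frac{B}{n}\right)/W}$
with $W$ the mean within-chain variance and $B$ the between-chain variance
of chain means scaled by $n$; the pipeline flags any $\hat R > 1.05$.
A `prior_only` mode disables the likelihood so the sampler machinery can
be validated against the priors themselves (the $\gamma$ draws must pass a
Kolmogorov–Smirnov test against Uniform(0, 100)).

The reported $R^2$ is the plug-in value $1 - SS_{res}/SS_{tot}$ at the
posterior-mean parameters. A posterior-predictive $R^2$ would also be
defensible; the plug-in form is chosen for transparency and is labelled as
such wherever reported.

Degenerate inputs behave predictably rather than erroring: a constant
response is fitted exactly by pushing $\gamma$ below the data range with
$\beta_2 = 0$, leaving $\beta_1$ at its prior (no data identify it) and
collapsing $\sigma$; the tests pin this behaviour down.

## Habitat areas and export summaries

`coverage_weighted_areas()` implements the density weighting used when
mapping habitat from imagery: sparse/medium coverage counts as 50%
vegetation, dense as 100%, and for a single-class cell the unvegetated
remainder accrues to bare sediment (10 m² of medium seagrass → 5 m²
seagrass + 5 m² bare), conserving total area. Cells may carry several
classes (seagrass with epiphytic macroalgae); each class then receives its
own weighted area, so multi-membership areas can overlap and no bare
remainder is imputed once the weighted vegetated area reaches the cell
area. `compute_mativ()` turns class areas into the MA:TV ratio.

`quartile_export_stats()` ranks catchments by percent fertilized area and
summarises the $k = \lceil n/4 \rceil$ least- and most-fertilized ones
(mean and range of TN and NOx export rates, kg ha⁻¹ yr⁻¹). Membership is
rank-based, not threshold-based: for the packaged 15-catchment table this
puts four systems in each group, which is the grouping that reproduces the
group means; ties straddling a cut pull in all tied records, logged.

## The synthetic survey generator

`generate_dataset()` exists so every downstream stage is testable without
the original survey table, which is not redistributable. Its defaults
*are* the survey conditions the analysis targets: 14 estuaries;
MA:TV generated from the piecewise model with
$\alpha = 0.675,\ \beta_1 = 0.024,\ \beta_2 = 0.002,\ \gamma = 24.3$; and
a DIN-concentration column correlated $r = 0.84$ with % fertilized so the
screening stage has a real collinear pair to resolve, plus a weaker
($r = 0.3$) correlation with % modified so that — as in the survey the
generator emulates — DIN concentration is the member with the larger
external correlation sum and hence the one screened out.

Predictors are drawn through a Gaussian copula: a latent multivariate
normal with unit marginals is transformed through each predictor's
quantile function (uniform for the percent covers, log-normal for C:E
ratio, flushing time, DIN load and concentration, beta for the population
proportion). Because monotone marginal transforms attenuate Pearson
correlation, the latent correlation for each declared pair is calibrated
numerically (common-random-numbers root-find) so the *realized* Pearson
correlation matches the declared target; targets beyond what the marginals
can jointly attain, and non-positive-semi-definite latent matrices, raise
configuration errors.

The residual noise SD defaults to 0.08, chosen by simulation so that the
plug-in $R^2$ of a refit at $n = 14$ scatters around 0.9, matching the
fit quality the analysis is meant to exhibit at survey scale. Noise that
would leave $[0,1]$ is clipped, not resampled — the response is a measured
proportion, and clipping is a property of the generator, not of the fitted
model. This has a visible consequence: at low $F$ the mean is near 0, so
clipping inflates low-$F$ responses slightly and biases the recovered
$\beta_1$ upward; at large $n$ (where posterior SDs are small) this shows
up as slightly-below-nominal 2-SD recovery for $\beta_1$ specifically.
The tests measure and tolerate exactly this.

What the generator does *not* emulate: spatial structure among estuaries,
measurement error in the predictors, temporal dynamics of loads, or any
dependence of MA:TV on predictors other than % fertilized. Passing
recovery tests on synthetic data therefore demonstrates correctness of the
samplers and estimators under the model's own assumptions — not that the
model is right for any particular real survey.

## Reproducibility and problem sizes

Every stochastic function takes an integer seed; chain $c$ of a sampler
uses `seed + c - 1`, so runs are bit-reproducible and chains are
independently re-runnable. `run_full_analysis()` derives fixed per-stage
offsets from one global seed so stages stay reproducible in isolation.

The test suite exercises the samplers at deliberately modest sizes —
recovery at $n = 200$ with 2–3 chains of a few thousand iterations,
enumeration cross-checks at $k \le 3$ with 50 000 retained draws,
coverage over 50 replicates at $n = 50$ — sizes at which the checks are
sharp but a full run stays in the order of a minute. The defaults users
get (12 000 iterations, 5 000 burn-in, 3 chains) are larger than any of
these because a real analysis is run once, not hundreds of times.

## Known limitations

* The piecewise likelihood ignores the $[0,1]$ bounds of the response; for
  surveys with many estuaries near the bounds a truncated or beta
  likelihood would be more faithful.
* Hierarchical partitioning is exact but exponential in the number of
  predictors; it is intended for the post-screening predictor set.
* With $n$ as small as 14, the screening decision inside a near-
  exchangeable collinear pair ($r \approx 0.9$) is sensitive to sampling
  noise; the audit log always records which member was kept and why.
* The spike-and-slab sampler assumes a Gaussian response; no other GLM
  families are provided.
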