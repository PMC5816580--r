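# mativ

Statistical analysis linking catchment land use to the benthic vegetation of
small estuaries.

Nutrient over-enrichment shifts shallow estuaries from seagrass-dominated to
macroalgae-dominated vegetation. The **macroalgae-to-total-vegetation
ratio**,

    MA:TV = A_MA / (A_MA + A_SG)  ∈ [0, 1],

is an easily mapped eutrophication indicator, and this package implements
the full analysis chain for relating it to catchment descriptors in a small
estuary survey:

* **Predictor screening** — pairwise Pearson correlations; within each set
  of predictors linked by |r| > 0.7, retain the member with the lowest sum
  of absolute correlations to the predictors outside the set; natural-log
  transform of right-skewed predictors; standardization to mean 0 / SD 1.
* **Bayesian variable selection** by stochastic search (Kuo–Mallick
  spike-and-slab Gibbs sampler): `y ~ N(β₀ + Σ gⱼθⱼzⱼ, σ)` with
  `gⱼ ~ Bernoulli(0.5)`, `θⱼ ~ N(0, τ²)`. Reports posterior inclusion
  probabilities Pr(Inc), model-averaged coefficients, and the posterior odds
  ratio `[p/(1−p)] / [p₀/(1−p₀)]`, with POR ≥ 3 (equivalently
  Pr(Inc) ≥ 0.75) flagging an important predictor. Includes the full
  three-way interaction expansion of C:E ratio × flushing time ×
  % fertilized.
* **Hierarchical partitioning** — exact Shapley decomposition of OLS R²
  over all 2^k predictor subsets into independent (I) and joint (J)
  contributions, with % independent shares summing to 100.
* **Bayesian change-point regression** of MA:TV on % catchment
  fertilization F:

      MA:TV_i ~ Normal(μ_i, σ)
      μ_i = α·δ(F_i−γ) + β₁·δ(γ−F_i)·F_i + β₂·δ(F_i−γ)·F_i

  with priors α, βᵢ ~ N(0, sd 2), γ ~ Uniform(0, 100), σ ~ HalfNormal(0, 1),
  fitted by Metropolis-within-Gibbs (conjugate coefficient draws, adaptive
  random-walk moves for γ and σ) with Gelman–Rubin convergence checks and a
  plug-in R².
* **Habitat and export statistics** — coverage-weighted habitat areas
  (sparse/medium = 50 % vegetation, dense = 100 %), the MA:TV statistic,
  and quartile summaries of catchment nutrient-export rates from the
  packaged 15-catchment table.
* **A seeded synthetic survey generator** (Gaussian-copula predictors with
  calibrated Pearson correlations; MA:TV from the piecewise model), so the
  whole pipeline is testable end-to-end.

## Worked example

```r
library(mativ)

## a 14-estuary survey drawn from the generator's default conditions
survey <- generate_dataset(synthetic_spec(seed = 1))

## variable selection over the seven candidate predictors
Z <- standardize(log_transform_skewed(
  survey[, c("ce_ratio", "tf", "pop_prop_1", "pct_modified",
             "pct_urbanized", "pct_fertilized", "areal_din_load")]))
fit_ssvs(survey$mativ, Z, n_chains = 2, n_iter = 6000, burn_in = 2000,
         seed = 1)
#>            term pr_inc   beta sd_beta post_odds_ratio important
#>        ce_ratio  0.041 -0.001   0.008           0.042     FALSE
#>              tf  0.032  0.000   0.006           0.033     FALSE
#>      pop_prop_1  0.212  0.011   0.024           0.269     FALSE
#>    pct_modified  0.032  0.000   0.006           0.033     FALSE
#>   pct_urbanized  0.044 -0.001   0.008           0.045     FALSE
#>  pct_fertilized  1.000  0.249   0.028             Inf      TRUE
#>  areal_din_load  0.031  0.000   0.007           0.032     FALSE
```

Only percent fertilized catchment area is selected: its inclusion
probability is ~1 (posterior odds ratio far above the importance cut-off
of 3) with a model-averaged standardized coefficient of ~0.25, while every
other predictor stays near-zero.

```r
fit_changepoint(survey$mativ, survey$pct_fertilized, n_chains = 2,
                n_iter = 8000, burn_in = 3000, seed = 1)
#>  parameter    mean      sd    q2.5   q97.5   rhat
#>      alpha  0.5326  0.1621  0.2067  0.7935 1.0033
#>      beta1  0.0214  0.4711 -0.2930  0.2089 0.9999
#>      beta2  0.0042  0.0023  0.0004  0.0092 1.0038
#>      gamma 26.0055 12.4618  3.4163 49.4923 1.0046
#>      sigma  0.0899  0.0307  0.0525  0.1737 1.0111
#> Plug-in R-squared: 0.901
```

The posterior places the change-point γ around 26 % catchment
fertilization: below it MA:TV rises at ~0.02 per percentage point, above
it the vegetation is already macroalgae-dominated (intercept ~0.5–0.7) and
nearly flat. All R-hat values sit near 1, and the piecewise fit explains
~90 % of the response variance.

```r
quartile_export_stats(read_export_table(export_fixture_path()))
#> lower quartile (4 systems): Wingan River, Cann River, Genoa River, Aire River
#>   TN  mean 0.885 (range 0.22-1.7) kg/ha/yr
#>   NOx mean 0.247 (range 0.06-0.74) kg/ha/yr
#> upper quartile (4 systems): Tarwin River, Curdies River, Bass River, Moyne River
#>   TN  mean 4.525 (range 1.9-7.7) kg/ha/yr
#>   NOx mean 1.923 (range 0.7-3.1) kg/ha/yr
```

The least-fertilized quartile of catchments exports ~0.9 kg TN and
~0.25 kg NOx per hectare per year; the most-fertilized quartile ~4.5 and
~1.9 — a five- to eight-fold difference across the land-use gradient.

`run_full_analysis()` chains every stage (screening → selection →
partitioning → interaction model → change-point) from one
`analysis_config()` and writes a reproducible report via `write_report()`;
a thin command-line wrapper with `simulate | preprocess | ssvs | hierpart |
changepoint | exports | run-all` subcommands is installed at
`system.file("cli", "mativ.R", package = "mativ")`.

## The methods vignette

`vignettes/mativ-methods.Rmd` documents the models, priors, samplers,
numerical choices and the generator's scope and limitations.
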