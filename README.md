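# marshequiv

Multi-metric functional-equivalence scoring for constructed **living
shorelines** against their paired **natural fringing marshes**.

Living shorelines — marshes created from sand fill, planted cordgrass and a
seaward rock sill — are the leading nature-based alternative to shoreline
armoring. Restoration ecologists and coastal managers need to know whether
they deliver the same ecosystem functions as the natural marshes they
emulate. `marshequiv` implements the full analysis for paired designs of
this kind, emulating a 13-pair Chesapeake Bay study with 18 ecological
metrics spanning soils, invertebrates, plants, nekton, herons and
diamondback terrapins:

* **Replicate-level simulation** of the whole study design (soil cores,
  low-marsh and sill quadrats, fyke/minnow catches across two years,
  camera and visual surveys), with per-metric true effect sizes and noise
  families that respect each metric's support.
* **Site summaries** per metric: depth-weighted soil cores, quadrat
  densities with zone eligibility, nekton biomass/abundance aggregates,
  abundance-weighted taxonomic distinctness (Δ\*), and effort-adjusted
  heron and terrapin use.
* **Paired Z-scores**: for metric *m* and pair *i*,
  *Z* = (LS − NM) / σ, where σ is a *local* pooled SD
  √((σ²_LS + σ²_NM)/2) from within-site replicates (soils, invertebrates,
  plants) or a *regional* pooled SD from among-pair site means (nekton,
  herons, terrapins). |Z| < 1 flags functional equivalence; the mean of a
  pair's scores is its **net functional equivalence score**.
* **Bayesian age model**: net score ~ Normal(β₀ + β₁ ln(age), σ) with
  priors β₀ ~ N(0,1), β₁ ~ N(0.25, 0.75), σ ~ Gamma(1,1); adaptive MCMC,
  split-Rhat/ESS diagnostics, PSIS-LOO model comparison against an
  intercept-only null (with an exact leave-one-out refit as a
  cross-check), and posterior predictive checks.
* **Point-transect distance sampling** for terrapins: 5% distance
  truncation, half-normal and hazard-rate detection functions with series
  expansions and covariates on the scale, AIC selection with a χ²
  goodness-of-fit guard, and the effective detection radius
  ρ = √(2∫₀ʷ r g(r) dr) with a bootstrap CI.

Everything is tibble-in/tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, so results drop straight into dplyr/ggplot2
workflows.

## A worked example

```r
library(marshequiv)

# a full 13-pair study with the reference design and effect sizes
obs <- simulate_study(study_design(seed = 42), effect_spec())
eq  <- equivalence_table(summarize_sites(obs))
eq
#> <equivalence_table> 13 pairs x 19 metrics (net score over 18)
#> grand mean Z = -0.56 +/- 1.60 (SD over pair x metric scores)
#> 14 / 18 net-score metrics equivalent (|mean Z| < 1)
```

The four metrics that miss equivalence are the soil metrics (organic
matter, C, N, P): living shorelines are built from clean, low-organic
sand, so soil composition lags the reference marshes by about two pooled
SDs while everything else sits within one SD of parity — exactly the
pattern the default effect sizes emulate.

```r
net <- dplyr::inner_join(eq$net_scores,
                         tibble::tibble(pair = 1:13, age = reference_ages()),
                         by = "pair")
fit  <- fit_age_model(net, seed = 1)
null <- fit_null_model(net, seed = 1)
tidy(fit)
#> # A tibble: 3 x 6
#>   parameter    mean     sd   q2.5  median  q97.5
#> 1 beta0     -0.441  0.236  -0.906 -0.442  0.0303
#> 2 beta1     -0.0580 0.115  -0.288 -0.0585 0.170
#> 3 sigma      0.249  0.0611  0.162  0.239  0.398
prob_overlap_zero(fit)        # fraction of beta1 draws <= 0
#> [1] 0.70
attr(compare_loo(fit, null), "delta_looic")
#> [1] 2.06
```

With 13 pairs and near-flat simulated age structure, the age slope's
credible interval spans zero and the logarithmic model sits within a few
LOOIC units of the null — weak evidence either way, which is the expected
behaviour at this sample size.

```r
# terrapin detectability: truncate, fit candidate keys, report the radius
sim  <- simulate_terrapin_distances(terrapin_sim_spec(), 60, seed = 42)
kept <- truncate_distances(sim$distance_m)          # drops farthest 5%
cand <- fit_detection_set(sim[attr(kept, "index"), ], covariates = "wind_mps")
effective_radius(cand$selected, n_boot = 199, seed = 1)
#> <effective_radius> rho = 35.5 m (95% CI: [33.0 m - 38.9 m], 199 bootstrap resamples)
```

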