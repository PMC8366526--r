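---
title: "Scoring functional equivalence of living shorelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring functional equivalence of living shorelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshequiv)
library(dplyr)
```

## The problem

Living shorelines — created marshes built from clean sand fill, planted
cordgrass and a seaward rock sill — are the preferred nature-based
alternative to armoring an eroding shoreline. Whether they actually deliver
the ecosystem functions of the natural fringing marshes they stand in for
is an empirical question that spans many very different measurements: soil
nutrient stocks, bivalve and periwinkle densities, cordgrass stems, nekton
biomass and diversity, heron foraging time, terrapin use. `marshequiv`
implements a complete analysis pipeline for paired designs of this kind:
each constructed site is paired with a nearby reference marsh, every metric
is reduced to one site-level value per site, and the paired difference is
standardized to a dimensionless Z-score so that all metrics can be read on
one scale and averaged into a per-pair *net functional equivalence score*.
The package defaults emulate a 13-pair design in Chesapeake Bay with 18
scored metrics plus one auxiliary variant.

## The Z-score model

For metric $m$ and pair $i$, the site-level living-shoreline value minus
the natural-marsh value is divided by a pooled SD:

$$Z_{im} = \frac{\bar{x}^{LS}_{im} - \bar{x}^{NM}_{im}}{\sigma_{im}},$$

with $\sigma$ taken in one of two ways.

* **Local (within-pair)**: $\sigma_{L_i} = \sqrt{(\sigma^2_{LS_i} +
  \sigma^2_{NM_i})/2}$, the root mean square of the two sites' replicate
  SDs. Used for metrics whose sampling has identical effort and
  replication at both members of a pair: soils (3 cores), benthic
  invertebrates and cordgrass (fixed quadrat counts).
* **Regional (among-pair)**: $\sigma_R = \sqrt{(\sigma^2_{LS} +
  \sigma^2_{NM})/2}$, pooling the SD of living-shoreline site means across
  pairs with that of natural-marsh site means. One shared value per
  metric. Used for nekton (mixing fyke-net and minnow-trap catches
  precludes a within-site SD), heron use and terrapin counts, which reduce
  to a single effort-adjusted number per site.

Positive scores mean the living shoreline provides the higher level of
function. A metric is called *functionally equivalent* when its mean
absolute Z-score across pairs is below 1 — one pooled SD — and the mean of
a pair's included metric scores is its net score. The auxiliary
low-marsh-only mussel density (`mussels_lm`), which isolates the role of
the rock sill, is reported but never enters the net score. A degenerate
(zero) pooled SD excludes that pair from that metric with a warning rather
than emitting an infinite score.

```{r score}
obs <- simulate_study(study_design(seed = 42), effect_spec())
eq <- equivalence_table(summarize_sites(obs))
eq
glance(eq)
```

## Site-level aggregation rules

Each metric carries a fixed aggregation rule from replicate observations to
the site value entering the Z-score:

* **Soils** (% organic matter, C, N, P): each 20-cm core is sectioned at
  0–5, 5–10 and 10–20 cm and collapsed by thickness weighting,
  $(5v_1 + 5v_2 + 10v_3)/20$; site mean and SD are computed across the
  three cores. Thickness weights are a deliberate choice — mass
  (bulk-density) weighting would need per-section bulk densities, which
  the standard field protocol does not always retain; `soil_profile_mean()`
  accepts any contiguous sectioning should one want different weights.
* **Quadrat densities**: counts in 0.25-m² quadrats are converted to
  per-m² densities. The main bivalve metrics (mussels, oysters) average
  over low-marsh *and* sill quadrats at living shorelines (the sill is
  where bivalves concentrate) but only low-marsh quadrats at natural
  marshes, which have no sill; periwinkles, crab burrows, cordgrass and
  the auxiliary `mussels_lm` variant are low-marsh-only everywhere.
* **Nekton**: biomass of fish, blue crabs and shrimp is summed across both
  gears and both study years; fish abundance (all, juvenile, forage) is
  totalled per year and averaged across years; diversity is computed per
  year and averaged, with a warning when a year is missing.
* **Diversity** is abundance-weighted taxonomic distinctness
  $\Delta^* = \sum_{i<j} \omega_{ij} x_i x_j / \sum_{i<j} x_i x_j$ with
  equal step lengths between taxonomic levels scaled so the maximal (root)
  separation is 100. Species joined at the first shared rank; a
  presence/absence variant ($\Delta^+$) is available via
  `weighted = FALSE`. A one-species community has no defined distinctness
  and propagates as missing.
* **Herons**: total observed seconds (de-duplicated across simultaneous
  cameras) over total recording seconds — a use ratio in [0, 1].
* **Terrapins**: unique head counts within the effective detection radius
  per observation hour.

## The Bayesian age model

Do older living shorelines score closer to their reference marshes? The
net score $y_i$ of pair $i$ is regressed on the log of the living
shoreline's age $x_i$ (years since construction):

$$y_i \sim \mathrm{Normal}(\beta_0 + \beta_1 \ln x_i,\ \sigma),\qquad
\beta_0 \sim \mathrm{N}(0,1),\ \ \beta_1 \sim \mathrm{N}(0.25, 0.75),\ \
\sigma \sim \mathrm{Gamma}(1,1).$$

The logarithmic mean approximates an asymptotic approach to equivalence
over a small age range (2–16 years) with a single slope parameter — a
deliberate economy at $n = 13$. The $\beta_1$ prior (mean 0.25, SD 0.75)
encodes a modest expectation that function accrues with age; the
Gamma(1, 1) prior on $\sigma$ (shape–rate, i.e. Exponential(1)) and the
standard-normal intercept prior are weakly informative on the Z-score
scale. Both prior conventions (SD not variance; rate not scale) follow the
usual Bayesian-regression software conventions and are asserted by the
prior-recovery test.

Sampling uses an adaptive random-walk Metropolis sampler on
$(\beta_0, \beta_1, \log\sigma)$: during warmup the proposal covariance is
the running (Welford) covariance of the chain history and the global scale
is tuned toward a 0.234 acceptance rate; after warmup the proposal is
frozen. Defaults are 4 chains of 50,000 iterations including 5,000 warmup
draws each — `iter_includes_warmup = FALSE` switches to the other reading
of an iteration budget, since both conventions are common. Split-Rhat and
autocorrelation-based effective sample sizes are reported per parameter,
and a seeded fit is bit-reproducible.

```{r age}
ages <- tibble::tibble(pair = 1:13, age = reference_ages())
net <- dplyr::inner_join(eq$net_scores, ages, by = "pair")
fit <- fit_age_model(net, chains = 2, iter = 6000, warmup = 1000, seed = 1)
tidy(fit)
prob_overlap_zero(fit)
```

The intercept-only null (`fit_null_model()`) shares the $\beta_0$ and
$\sigma$ priors. Model comparison uses LOOIC $= -2\,\mathrm{elpd}_{loo}$
computed by Pareto-smoothed importance sampling from the pointwise
log-likelihood matrix; the tail of each observation's importance ratios is
stabilized by a generalized-Pareto fit (profile-posterior estimator with a
weak shape prior) and shapes above 0.7 are flagged. At $n = 13$ the exact
alternative — refitting with each pair left out — is cheap, and
`loo_exact_refit()` provides it; the test suite holds the two routes
together within Monte Carlo error. Posterior predictive checks replicate
the data from posterior draws and locate the observed mean and SD within
the replicated distributions.

## Distance sampling for terrapins

Terrapin surveys record radial distances to surfaced heads. Availability
grows linearly with radius while detectability decays, so sighting
distances have density $f(r) \propto r\,g(r)$ on $(0, w]$, with $g$ the
detection function ($g(0) = 1$). The package fits half-normal
$g(r) = \exp(-r^2/2\sigma^2)$ and hazard-rate
$g(r) = 1 - \exp(-(r/\sigma)^{-b})$ keys by maximum likelihood, each
optionally multiplied by cosine, simple-polynomial or Hermite-polynomial
series adjustments (0–2 terms, rescaled to keep $g(0) = 1$ and constrained
non-negative), and covariates enter the scale as
$\sigma_i = \exp(\beta_0 + \beta^\top z_i)$ with z-scored covariates for
optimizer stability. Per-observation normalizing integrals use 61-node
Gauss–Legendre quadrature (the suite checks it against adaptive
quadrature to 1e-8).

Before fitting, the farthest 5% of observations are dropped:
$\max(1, \lfloor 0.95 n \rfloor)$ sightings are retained (178 detections
retain 169), since the sparse right tail destabilizes the scale estimate.
Candidate models are compared by AIC among fits whose equal-count-bin
chi-square goodness-of-fit test is non-significant ($p \ge 0.05$); if
nothing passes, the lowest-AIC fit is returned flagged. Six equal-count
bins are a package decision, as is the 0–2 adjustment-term budget per
series.

The *effective detection radius* is the distance at which as many animals
are expected to be missed inside as detected beyond:
$\rho = \sqrt{2\int_0^w r\,g(r)\,dr}$, with $\rho = \sigma\sqrt{2}
\sqrt{1 - e^{-w^2/2\sigma^2}}$ in closed form for the half-normal key and
$\rho \to w$ under perfect detection. Its confidence interval is a
nonparametric percentile bootstrap over sightings (999 resamples by
default), refitting the selected model on each resample.

```{r distance}
sim <- simulate_terrapin_distances(
  terrapin_sim_spec("hazard-rate", sigma = 25, shape = 3, w = 80),
  n_surveys = 40, seed = 3)
kept <- truncate_distances(sim$distance_m)
fit_hr <- fit_detection(kept, key = "hazard-rate", w = max(kept))
effective_radius(fit_hr, n_boot = 0)
```

## What the simulator emulates — and what it does not

`simulate_study()` reproduces the *replication structure* of the 13-pair
design: 3 soil cores (drawn section-wise and depth-weighted), 12 low-marsh
quadrats plus 6 sill quadrats at living shorelines, 2 fyke nets and 10
minnow traps over 2 years, and 3–6 heron/terrapin surveys with explicit
effort. Noise families respect each metric's support — normal for
percentages and diversity, negative binomial for counts, lognormal for
biomass, gamma for observation times, Poisson for heads — because the
published record gives only means and SDs, not distributional forms; the
families are package choices, not inferences about the original data.

Effects are specified as true standardized offsets `delta` (LS − NM, in
units of the SD that standardizes the metric downstream). The defaults are
the published metric-level scores of the motivating study, so a default
draw shows the study's signature: soils lagging by roughly two SDs,
everything else near equivalence. For the zoned bivalve metrics the
low-marsh offset `delta_lm` (defaults −0.8 for mussels, matching the
published low-marsh-only score, and −1.5 for oysters, which occurred
almost exclusively on sills) applies to low-marsh quadrats, and the sill
is enriched by exactly the factor that restores the whole-site offset —
so an all-zero effect specification makes living shorelines and reference
marshes fully exchangeable. That exchangeability is what the 500-study
null-calibration test leans on: the grand mean Z must sit within Monte
Carlo error of zero.

A single integer seed drives the whole draw, with per-metric substreams
derived from hashed metric names so adding a metric never perturbs
another's values. What the simulator does *not* emulate: spatial structure
within sites, species identities beyond what distinctness needs,
gear-selectivity differences, inter-annual environmental trends, or
measurement error in ages and efforts. Passing tests on simulated data
demonstrate that the pipeline's arithmetic, calibration and inferential
machinery behave as claimed — not that any particular field system matches
the generator's families.

Small-sample standardization has one consequence worth knowing: with three
cores per site, the local pooled SD is noisy and $E[1/S] > 1/E[S]$, so
metric-level mean Z-scores are inflated away from zero by roughly 25%
relative to the generating offset. The published scores carry the same
small-sample geometry, so emulation is qualitative, not exact.

## Numerical and design choices

* Sample SDs use the $n-1$ denominator everywhere; a single replicate
  yields a missing SD, handled downstream as degenerate.
* The net score averages the 18 included metrics; the grand mean is
  reported with both SDs — over all pair-by-metric scores and over
  metric-level means (they share the mean when the design is balanced).
* Tie-break in truncation: ties at the cutoff retain earlier-indexed
  records; a one-observation input is never emptied.
* Hazard-rate shape is parameterized as $b = 1 + e^\zeta$ to honour
  $b > 1$; a fit at the boundary warns.
* MCMC problem sizes in the tests (chains × iterations) are scaled to the
  precision each check needs — e.g. the dense-grid-oracle comparison runs
  4 × 100,000 iterations so Monte Carlo error is well inside the 2%-of-SD
  band being asserted.
* The age-model grid oracle, exact-refit LOO, quadrature cross-checks and
  brute-force distinctness sums live in the test helpers, deliberately
  independent of the package's computational paths.

## Limitations

The equivalence criterion $|Z| < 1$ is a descriptive convention, not a
hypothesis test; no multiple-testing adjustment or TOST-style equivalence
testing is attempted. Nekton metrics forced to the regional SD lose
pair-level precision by design. The distance-sampling stage covers point
transects only — no line transects, no mark–recapture augmentation, no
density surfaces. And with 13 pairs the age model has little power: wide
credible intervals on $\beta_1$ and LOOIC ties with the null are the
expected outcome unless age effects are strong.
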