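#' Registry of the ecological metrics entering the equivalence analysis
#'
#' The analysis standardizes 18 ecological metrics plus one auxiliary
#' variant. Each metric carries the aggregation rule that turns replicate
#' observations into a site value, the pooled-SD mode used to standardize the
#' paired living-shoreline minus natural-marsh difference, and whether it
#' contributes to the per-pair net equivalence score.
#'
#' Soils, benthic invertebrates and plants are sampled with identical effort
#' and replication at both members of a pair, so their Z-scores use a local
#' (within-pair) pooled SD. Nekton catches combine gear types (fyke nets and
#' minnow traps), which precludes a meaningful within-site SD, and heron and
#' terrapin metrics are single effort-adjusted site totals; all of these use
#' the regional (among-pair) pooled SD. The auxiliary low-marsh-only mussel
#' density (`mussels_lm`) isolates the contribution of the rock sill to
#' bivalve habitat and is excluded from the net score.
#'
#' @return A tibble with one row per metric: `metric`, `group` (soil,
#'   invertebrate, plant, nekton, heron, terrapin), `sd_mode` (`"local"` or
#'   `"regional"`), `in_net_score` (logical), `units`, and `aggregation`
#'   (identifier of the site-level aggregation rule).
#' @examples
#' metric_definitions()
#' @export
metric_definitions <- function() {
  tibble::tribble(
    ~metric,           ~group,         ~sd_mode,   ~in_net_score, ~units,            ~aggregation,
    "mussels",         "invertebrate", "local",    TRUE,  "ind m^-2",        "quadrat_density",
    "mussels_lm",      "invertebrate", "local",    FALSE, "ind m^-2",        "quadrat_density_lm",
    "oysters",         "invertebrate", "local",    TRUE,  "ind m^-2",        "quadrat_density",
    "periwinkles",     "invertebrate", "local",    TRUE,  "ind m^-2",        "quadrat_density_lm",
    "burrows",         "invertebrate", "local",    TRUE,  "burrows m^-2",    "quadrat_density_lm",
    "cordgrass",       "plant",        "local",    TRUE,  "stems m^-2",      "quadrat_density_lm",
    "organic_matter",  "soil",         "local",    TRUE,  "%",               "core_mean",
    "carbon",          "soil",         "local",    TRUE,  "%",               "core_mean",
    "nitrogen",        "soil",         "local",    TRUE,  "%",               "core_mean",
    "phosphorus",      "soil",         "local",    TRUE,  "%",               "core_mean",
    "fish_biomass",    "nekton",       "regional", TRUE,  "g",               "biomass_sum",
    "crab_biomass",    "nekton",       "regional", TRUE,  "g",               "biomass_sum",
    "shrimp_biomass",  "nekton",       "regional", TRUE,  "g",               "biomass_sum",
    "fish_abundance",  "nekton",       "regional", TRUE,  "ind",             "year_mean",
    "juvenile_fish_abundance", "nekton", "regional", TRUE, "ind",            "year_mean",
    "forage_fish_abundance",   "nekton", "regional", TRUE, "ind",            "year_mean",
    "fish_diversity",  "nekton",       "regional", TRUE,  "distinctness",    "year_mean",
    "heron_use",       "heron",        "regional", TRUE,  "s s^-1",          "effort_ratio",
    "terrapin",        "terrapin",     "regional", TRUE,  "heads h^-1",      "effort_ratio"
  )
}

#' Ages of the 13 constructed living shorelines in the reference design
#'
#' Years since construction (as of the 2018 field season) for each of the 13
#' living shorelines of the Chesapeake Bay pair design that this package's
#' defaults emulate. These ages form the predictor grid of the logarithmic
#' age model and the default [study_design()].
#'
#' @return Integer vector of length 13, one age per pair in pair order.
#' @examples
#' reference_ages()
#' @export
reference_ages <- function() {
  c(7L, 4L, 2L, 7L, 10L, 9L, 12L, 7L, 3L, 16L, 9L, 6L, 16L)
}

#' Published metric-level Z-scores of the reference study
#'
#' Metric-level mean Z-scores (mean over the 13 pairs of the standardized
#' living-shoreline minus natural-marsh difference) reported for the
#' reference field comparison. The auxiliary low-marsh-only mussel variant is
#' included with `in_net_score = FALSE`. These values serve two purposes:
#' recomputing the published overall mean from its printed components, and
#' providing realistic default effect sizes for [effect_spec()].
#'
#' @return A tibble with columns `metric`, `z` and `in_net_score`.
#' @examples
#' scores <- reference_metric_scores()
#' mean(scores$z[scores$in_net_score])
#' @export
reference_metric_scores <- function() {
  tibble::tribble(
    ~metric,                   ~z,    ~in_net_score,
    "mussels",                 -0.20, TRUE,
    "mussels_lm",              -0.80, FALSE,
    "oysters",                  0.28, TRUE,
    "periwinkles",             -0.12, TRUE,
    "burrows",                  0.02, TRUE,
    "cordgrass",               -0.14, TRUE,
    "organic_matter",          -1.86, TRUE,
    "carbon",                  -2.61, TRUE,
    "nitrogen",                -2.60, TRUE,
    "phosphorus",              -1.76, TRUE,
    "fish_biomass",             0.85, TRUE,
    "crab_biomass",             0.46, TRUE,
    "shrimp_biomass",           0.28, TRUE,
    "fish_abundance",           0.48, TRUE,
    "juvenile_fish_abundance",  0.06, TRUE,
    "forage_fish_abundance",    0.09, TRUE,
    "fish_diversity",          -0.12, TRUE,
    "heron_use",                0.49, TRUE,
    "terrapin",                 0.27, TRUE
  )
}
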