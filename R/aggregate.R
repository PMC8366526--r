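#' Construct a sectioned soil-core profile
#'
#' Cores are sectioned into 0-5, 5-10 and 10-20 cm intervals; the three
#' sections must be contiguous and span the full 0-20 cm profile.
#'
#' @param values Numeric vector of section values (e.g. percent carbon),
#'   one per section, all >= 0.
#' @param tops,bottoms Section boundaries in cm; defaults are the standard
#'   0-5, 5-10, 10-20 sectioning.
#' @param id Optional core identifier.
#' @return An object of class `soil_core`.
#' @examples
#' soil_core(c(4, 2, 1))
#' @export
soil_core <- function(values, tops = c(0, 5, 10), bottoms = c(5, 10, 20),
                      id = NULL) {
  if (length(values) != length(tops) || length(tops) != length(bottoms)) {
    abort("`values`, `tops` and `bottoms` must have equal length.")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("Section values must be finite and >= 0.")
  }
  structure(list(values = as.numeric(values), tops = as.numeric(tops),
                 bottoms = as.numeric(bottoms), id = id),
            class = "soil_core")
}

#' Depth-weighted mean of a 0-20 cm soil-core profile
#'
#' Collapses a sectioned core to a single standing-stock weight percentage
#' by weighting each section value by its thickness: with the standard
#' sectioning, (5 v1 + 5 v2 + 10 v3) / 20.
#'
#' @param core A [soil_core()].
#' @return The thickness-weighted mean (same units as the section values).
#' @examples
#' soil_profile_mean(soil_core(c(4, 2, 1)))  # 2
#' @export
soil_profile_mean <- function(core) {
  if (!inherits(core, "soil_core")) abort("`core` must be a soil_core.")
  th <- core$bottoms - core$tops
  if (any(th <= 0)) abort("Section bottoms must exceed tops.")
  ord <- order(core$tops)
  tops <- core$tops[ord]; bottoms <- core$bottoms[ord]
  if (tops[1] != 0 || bottoms[length(bottoms)] != 20 ||
      any(tops[-1] != bottoms[-length(bottoms)])) {
    gaps <- paste0(sprintf("%g-%g cm", tops, bottoms), collapse = ", ")
    abort(sprintf(
      "Incomplete profile: sections (%s) must tile 0-20 cm contiguously.",
      gaps))
  }
  sum(core$values * th) / sum(th)
}

#' Mean, sample SD and replicate count of site-level replicate values
#'
#' @param values Numeric vector of replicate values, length >= 1.
#' @return A tibble with one row: `mean`, `sd` (n-1 denominator, `NA` for a
#'   single replicate), `n`.
#' @examples
#' site_summary(c(1, 2, 3))
#' @export
site_summary <- function(values) {
  if (length(values) == 0) abort("Cannot summarize an empty replicate set.")
  if (any(!is.finite(values))) abort("Replicate values must be finite.")
  tibble::tibble(mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else NA_real_,
                 n = length(values))
}

#' Bivalve (or other quadrat) density per square metre
#'
#' Quadrat counts are converted to densities using the 0.25 m^2 quadrat
#' area. At natural marshes only low-marsh quadrats exist; at living
#' shorelines the main bivalve metrics average over low-marsh plus sill
#' quadrats, while the auxiliary low-marsh-only variant (and the
#' periwinkle/burrow/cordgrass metrics) restrict to the low marsh.
#'
#' @param counts Numeric vector of per-quadrat counts.
#' @param zones Character vector (`"low_marsh"` or `"sill"`), same length.
#' @param site_type `"LS"` or `"NM"`.
#' @param include_sill Should sill quadrats enter the average at living
#'   shorelines? `TRUE` for the main bivalve metrics.
#' @param quadrat_area Quadrat area in m^2 (default 0.25).
#' @return A tibble with `mean` (ind m^-2), `sd` (ind m^-2), `n` quadrats.
#' @examples
#' bivalve_density(rep(1, 12), rep("low_marsh", 12), "NM")  # 4 per m^2
#' @export
bivalve_density <- function(counts, zones, site_type,
                            include_sill = TRUE, quadrat_area = 0.25) {
  if (length(counts) != length(zones)) {
    abort("`counts` and `zones` must have equal length.")
  }
  if (!all(zones %in% c("low_marsh", "sill"))) {
    abort("`zones` must be 'low_marsh' or 'sill'.")
  }
  if (any(counts < 0)) abort("Quadrat counts must be >= 0.")
  site_type <- match.arg(site_type, c("LS", "NM"))
  if (site_type == "NM" && any(zones == "sill")) {
    abort("Natural marshes have no sill zone; sill quadrats supplied for NM.")
  }
  keep <- if (site_type == "LS" && include_sill) rep(TRUE, length(zones))
          else zones == "low_marsh"
  dens <- counts[keep] / quadrat_area
  site_summary(dens)
}

#' Effort-adjusted heron observation time
#'
#' Total heron observation seconds (summed across surveys and years, after
#' de-duplicating simultaneous multi-camera detections) divided by total
#' camera recording seconds, giving a dimensionless use ratio in \[0, 1\].
#'
#' @param observed_seconds,recorded_seconds Per-survey totals (vectors are
#'   summed); recording time must be positive.
#' @return The use ratio.
#' @examples
#' heron_adjusted_time(1800, 36000)  # 0.05
#' @export
heron_adjusted_time <- function(observed_seconds, recorded_seconds) {
  obs <- sum(observed_seconds)
  rec <- sum(recorded_seconds)
  if (rec <= 0) abort("Total recording time must be > 0.")
  if (any(observed_seconds < 0)) abort("Observed time must be >= 0.")
  if (obs > rec) {
    abort("Observed time exceeds recording time; simultaneous detections must be de-duplicated upstream.")
  }
  obs / rec
}

#' Terrapin head count per observation hour
#'
#' @param heads Count of unique individuals detected within the effective
#'   radius surveyed (vectors are summed across surveys).
#' @param hours Observation effort in hours (summed); must be positive.
#' @return Heads per hour.
#' @examples
#' terrapin_cpue(6, 3)  # 2
#' @export
terrapin_cpue <- function(heads, hours) {
  h <- sum(hours)
  if (h <= 0) abort("Observation effort must be > 0 hours.")
  if (any(heads < 0)) abort("Head counts must be >= 0.")
  sum(heads) / h
}

#' Site-level nekton aggregates from catch records
#'
#' Biomass of fish, blue crabs and shrimp is summed across both gears and
#' both years; fish abundance (all, juvenile, forage) and diversity are
#' computed per year and then averaged across years. Diversity present in
#' only some years is averaged over the available years with a warning.
#'
#' @param catch A tibble of catch records with columns `year`, `gear`,
#'   `group` (`"fish"`, `"crab"`, `"shrimp"`), `count`, `biomass_g`, and
#'   logical `juvenile` and `forage` flags (fish only), plus optionally
#'   `diversity` (a per-year site value, constant within year).
#' @return A one-row tibble of site-level metric values: `fish_biomass`,
#'   `crab_biomass`, `shrimp_biomass`, `fish_abundance`,
#'   `juvenile_fish_abundance`, `forage_fish_abundance`, and
#'   `fish_diversity` if diversity was supplied.
#' @export
nekton_aggregates <- function(catch) {
  req <- c("year", "gear", "group", "count", "biomass_g")
  missing_cols <- setdiff(req, names(catch))
  if (length(missing_cols)) {
    abort(sprintf("Catch records lack columns: %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(catch$year))) abort("Catch records must carry a year tag.")

  biomass <- catch |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(biomass = sum(.data$biomass_g), .groups = "drop")
  get_b <- function(g) {
    v <- biomass$biomass[biomass$group == g]
    if (length(v)) v else 0
  }

  fish <- dplyr::filter(catch, .data$group == "fish")
  if (!"juvenile" %in% names(fish)) fish$juvenile <- FALSE
  if (!"forage" %in% names(fish)) fish$forage <- FALSE
  per_year <- fish |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      abundance = sum(.data$count),
      juvenile = sum(.data$count[.data$juvenile]),
      forage = sum(.data$count[.data$forage]),
      .groups = "drop")

  out <- tibble::tibble(
    fish_biomass = get_b("fish"),
    crab_biomass = get_b("crab"),
    shrimp_biomass = get_b("shrimp"),
    fish_abundance = mean(per_year$abundance),
    juvenile_fish_abundance = mean(per_year$juvenile),
    forage_fish_abundance = mean(per_year$forage))

  if ("diversity" %in% names(catch)) {
    dv <- catch |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(d = unique(.data$diversity)[1], .groups = "drop")
    if (any(is.na(dv$d))) {
      warn("Diversity missing for some years; averaging over available years.")
    }
    out$fish_diversity <- mean(dv$d, na.rm = TRUE)
  }
  out
}

#' Collapse replicate observations to site-by-metric summaries
#'
#' Applies each metric's aggregation rule to a replicate-level observation
#' table (as produced by [simulate_study()] or read from a matching CSV)
#' and returns the site-by-metric summary records that feed the Z-score
#' stage: a mean, a within-site sample SD (local-SD metrics only; regional
#' metrics report `NA`), and the replicate count.
#'
#' Aggregation rules by metric: soil cores and quadrat densities take the
#' mean and sample SD across replicates (quadrat counts are first converted
#' to per-m^2 densities, with the sill included only for the main bivalve
#' metrics at living shorelines); nekton biomass is summed over gears and
#' years; fish abundance and diversity are totalled (or taken) per year and
#' averaged across years; heron use is total observed over total recorded
#' time; terrapin use is total heads over total observation hours.
#'
#' @param observations Replicate-level tibble with columns `pair`,
#'   `site_type`, `metric`, `replicate`, `zone`, `year`, `value`, `effort`.
#' @param quadrat_area Quadrat area in m^2 for density conversion.
#' @return A tibble with columns `pair`, `site_type`, `metric`, `mean`,
#'   `sd`, `n`.
#' @examples
#' obs <- simulate_study(study_design(seed = 1), effect_spec())
#' summarize_sites(obs)
#' @export
summarize_sites <- function(observations, quadrat_area = 0.25) {
  validate_replicates(observations, stop_on_error = TRUE)
  defs <- metric_definitions()
  obs <- dplyr::left_join(observations,
                          defs[, c("metric", "aggregation")], by = "metric")

  by_rule <- split(obs, obs$aggregation)
  pieces <- list()

  if (!is.null(by_rule$core_mean)) {
    pieces$core <- by_rule$core_mean |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n = dplyr::n(), .groups = "drop")
  }
  for (rule in c("quadrat_density", "quadrat_density_lm")) {
    part <- by_rule[[rule]]
    if (is.null(part)) next
    # the sill zone counts toward the main bivalve metrics at living
    # shorelines only; every other quadrat metric is low-marsh only
    keep <- if (rule == "quadrat_density") {
      part$zone == "low_marsh" | part$site_type == "LS"
    } else {
      part$zone == "low_marsh"
    }
    pieces[[rule]] <- part[keep, ] |>
      dplyr::mutate(density = .data$value / quadrat_area) |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric) |>
      dplyr::summarise(mean = mean(.data$density), sd = sd(.data$density),
                       n = dplyr::n(), .groups = "drop")
  }
  if (!is.null(by_rule$biomass_sum)) {
    pieces$biomass <- by_rule$biomass_sum |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric) |>
      dplyr::summarise(mean = sum(.data$value), sd = NA_real_,
                       n = dplyr::n(), .groups = "drop")
  }
  if (!is.null(by_rule$year_mean)) {
    ym <- by_rule$year_mean
    if (anyNA(ym$year)) abort("year_mean metrics require a year tag.")
    per_year <- ym |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric,
                      .data$year) |>
      dplyr::summarise(
        v = if (.data$metric[1] == "fish_diversity") mean(.data$value)
            else sum(.data$value),
        n = dplyr::n(), .groups = "drop")
    pieces$year <- per_year |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric) |>
      dplyr::summarise(mean = mean(.data$v), sd = NA_real_,
                       n = sum(.data$n), .groups = "drop")
  }
  if (!is.null(by_rule$effort_ratio)) {
    er <- by_rule$effort_ratio |>
      dplyr::group_by(.data$pair, .data$site_type, .data$metric) |>
      dplyr::summarise(obs_total = sum(.data$value),
                       eff_total = sum(.data$effort),
                       n = dplyr::n(), .groups = "drop")
    over <- er$metric == "heron_use" & er$obs_total > er$eff_total
    if (any(over)) {
      abort(sprintf(
        "Observed time exceeds recording time for pair(s) %s; de-duplicate simultaneous detections upstream.",
        paste(unique(er$pair[over]), collapse = ", ")))
    }
    pieces$effort <- er |>
      dplyr::mutate(mean = .data$obs_total / .data$eff_total,
                    sd = NA_real_) |>
      dplyr::select("pair", "site_type", "metric", "mean", "sd", "n")
  }

  dplyr::bind_rows(pieces) |>
    dplyr::arrange(.data$metric, .data$pair, .data$site_type)
}
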