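test_that("soil profile means are thickness-weighted", {
  expect_equal(soil_profile_mean(soil_core(c(3, 3, 3))), 3)
  expect_equal(soil_profile_mean(soil_core(c(4, 2, 1))), 2)  # (20+10+10)/20
  expect_error(soil_profile_mean(soil_core(c(4, 2), tops = c(0, 5),
                                           bottoms = c(5, 10))),
               "Incomplete profile")
  # always between the extreme section values
  for (i in 1:20) {
    v <- runif(3, 0, 30)
    m <- soil_profile_mean(soil_core(v))
    expect_gte(m, min(v))
    expect_lte(m, max(v))
  }
})

test_that("site summaries use the sample SD and reject empty input", {
  expect_equal(site_summary(c(2, 2, 2)),
               tibble::tibble(mean = 2, sd = 0, n = 3L))
  expect_equal(site_summary(c(1, 2, 3))$sd, 1)
  expect_true(is.na(site_summary(5)$sd))
  expect_error(site_summary(numeric(0)), "empty")
  # two-pass streaming oracle
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(sample(3:50, 1), sd = 10)
    s <- site_summary(v)
    m1 <- sum(v) / length(v)
    ss <- sum((v - m1)^2) / (length(v) - 1)
    expect_equal(s$mean, m1, tolerance = 1e-12)
    expect_equal(s$sd, sqrt(ss), tolerance = 1e-12)
  }
})

test_that("bivalve density converts quadrat counts with zone eligibility", {
  expect_equal(bivalve_density(rep(1, 12), rep("low_marsh", 12), "NM")$mean, 4)
  # 12 low-marsh zeros + 6 sill fives at a living shoreline
  counts <- c(rep(0, 12), rep(5, 6))
  zones <- c(rep("low_marsh", 12), rep("sill", 6))
  main <- bivalve_density(counts, zones, "LS", include_sill = TRUE)
  expect_equal(main$mean, (30 / 18) / 0.25)
  lm_only <- bivalve_density(counts, zones, "LS", include_sill = FALSE)
  expect_equal(lm_only$mean, 0)
  # oysters only on the sill leave the low-marsh variant at zero
  expect_equal(bivalve_density(c(rep(0, 12), rep(3, 6)), zones, "LS",
                               include_sill = FALSE)$mean, 0)
  expect_error(bivalve_density(1:3, c("low_marsh", "sill", "sill"), "NM"),
               "sill")
  # main metric dominates the low-marsh variant when the sill is richer
  set.seed(1)
  for (i in 1:10) {
    lm <- rpois(12, 3)
    sill <- rpois(6, 3) + max(lm)
    cc <- c(lm, sill)
    expect_gte(bivalve_density(cc, zones, "LS", TRUE)$mean,
               bivalve_density(cc, zones, "LS", FALSE)$mean)
  }
})

test_that("heron use is observed over recorded time with a dedup bound", {
  expect_equal(heron_adjusted_time(0, 1000), 0)
  expect_equal(heron_adjusted_time(1800, 36000), 0.05)
  expect_equal(heron_adjusted_time(c(600, 1200), c(18000, 18000)), 0.05)
  expect_error(heron_adjusted_time(100, 0), "> 0")
  expect_error(heron_adjusted_time(5000, 4000), "de-duplicated")
})

test_that("terrapin CPUE is heads per pooled hour", {
  expect_equal(terrapin_cpue(6, 3), 2)
  expect_equal(terrapin_cpue(0, 10), 0)
  expect_error(terrapin_cpue(3, 0), "> 0")
  # additivity across surveys and sites: 41 pooled heads = 24 + 17
  expect_equal(terrapin_cpue(c(24, 17), c(10, 10)),
               (24 + 17) / 20)
})

test_that("nekton aggregates sum biomass and average per-year abundance", {
  one_year <- tibble::tibble(
    year = 2018, gear = c("fyke1", "minnow1", "fyke1"),
    group = c("fish", "fish", "crab"),
    count = c(10, 5, 2), biomass_g = c(500, 100, 300),
    juvenile = c(TRUE, FALSE, FALSE), forage = c(TRUE, TRUE, FALSE))
  both <- dplyr::bind_rows(one_year,
                           dplyr::mutate(one_year, year = 2019))
  agg <- nekton_aggregates(both)
  expect_equal(agg$fish_biomass, 2 * 600)
  expect_equal(agg$crab_biomass, 2 * 300)
  expect_equal(agg$fish_abundance, 15)   # identical years: one-year value
  expect_equal(agg$juvenile_fish_abundance, 10)
  expect_equal(agg$forage_fish_abundance, 15)

  two <- tibble::tibble(year = c(2018, 2019), gear = "fyke1",
                        group = "fish", count = c(10, 20),
                        biomass_g = c(1, 1))
  expect_equal(nekton_aggregates(two)$fish_abundance, 15)

  partial_div <- dplyr::mutate(two, diversity = c(80, NA))
  expect_warning(out <- nekton_aggregates(partial_div), "available years")
  expect_equal(out$fish_diversity, 80)

  expect_error(nekton_aggregates(dplyr::mutate(two, year = NA)), "year")
  expect_error(nekton_aggregates(two[, c("year", "count")]), "lack columns")
})

test_that("summarize_sites applies each metric's aggregation rule", {
  obs <- simulate_study(study_design(seed = 21), effect_spec())
  s <- summarize_sites(obs)
  expect_setequal(unique(s$metric), metric_definitions()$metric)
  expect_equal(nrow(s), 19 * 13 * 2)

  # spot-check against the scalar operations
  carbon_ls1 <- dplyr::filter(obs, metric == "carbon", pair == 1,
                              site_type == "LS")
  expect_equal(
    dplyr::filter(s, metric == "carbon", pair == 1, site_type == "LS")$mean,
    mean(carbon_ls1$value))
  mus <- dplyr::filter(obs, metric == "mussels", pair == 2,
                       site_type == "LS")
  expect_equal(
    dplyr::filter(s, metric == "mussels", pair == 2, site_type == "LS")$mean,
    bivalve_density(mus$value, mus$zone, "LS")$mean)
  her <- dplyr::filter(obs, metric == "heron_use", pair == 3,
                       site_type == "NM")
  expect_equal(
    dplyr::filter(s, metric == "heron_use", pair == 3,
                  site_type == "NM")$mean,
    heron_adjusted_time(her$value, her$effort))
  ter <- dplyr::filter(obs, metric == "terrapin", pair == 5,
                       site_type == "LS")
  expect_equal(
    dplyr::filter(s, metric == "terrapin", pair == 5,
                  site_type == "LS")$mean,
    terrapin_cpue(ter$value, ter$effort))
  # regional metrics carry no within-site SD
  expect_true(all(is.na(s$sd[s$metric == "fish_biomass"])))
  expect_false(anyNA(s$sd[s$metric == "carbon"]))
})
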