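test_that("pooled SDs follow the root-mean-square formulas", {
  expect_equal(pooled_sd_local(2, 2), 2)
  expect_equal(pooled_sd_local(3, 4), sqrt(12.5))
  expect_error(pooled_sd_local(0, 0), "Degenerate")
  expect_equal(pooled_sd_regional(c(1, 2, 3), c(2, 4, 6)),
               sqrt((1 + 4) / 2))
  expect_error(pooled_sd_regional(rep(2, 5), rep(2, 5)), "Degenerate")
  expect_error(pooled_sd_regional(1, 2), "at least 2")
  # equal spread on both sides returns that spread
  set.seed(3)
  base <- rnorm(8)
  expect_equal(pooled_sd_regional(base, 5 + base), sd(base))
  # direct-formula oracle on random inputs
  for (i in 1:25) {
    a <- runif(1, 0.01, 10); b <- runif(1, 0.01, 10)
    expect_equal(pooled_sd_local(a, b), sqrt((a^2 + b^2) / 2),
                 tolerance = 1e-12)
    x <- rnorm(13); y <- rnorm(13)
    expect_equal(pooled_sd_regional(x, y), sqrt((var(x) + var(y)) / 2),
                 tolerance = 1e-12)
  }
})

test_that("z-scores subtract the natural marsh from the living shoreline", {
  expect_equal(z_score(5, 5, 2), 0)
  expect_equal(z_score(7, 5, 2), 1)   # LS higher => positive
  expect_equal(z_score(5, 7, 2), -1)
  expect_error(z_score(1, 2, 0), "> 0")
})

test_that("the equivalence table wires SD modes and net scores correctly", {
  s <- make_summaries()
  eq <- equivalence_table(s)
  z <- eq$z
  expect_equal(z$sd_mode[z$metric == "carbon"], rep("local", 3))
  expect_equal(z$sd_mode[z$metric == "fish_biomass"], rep("regional", 3))
  # local pair 1: (1 - 2) / sqrt((0.4^2 + 0.3^2)/2)
  expect_equal(z$z[z$metric == "carbon" & z$pair == 1],
               -1 / sqrt((0.16 + 0.09) / 2))
  # regional: one shared SD across pairs
  ls <- c(100, 150, 120); nm <- c(80, 90, 160)
  ps <- sqrt((var(ls) + var(nm)) / 2)
  expect_equal(z$z[z$metric == "fish_biomass"], (ls - nm) / ps)
  expect_equal(unique(z$pooled_sd[z$metric == "fish_biomass"]), ps)
  # net score = mean of the pair's included Z-scores
  expect_equal(eq$net_scores$net_score,
               tapply(z$z, z$pair, mean)[as.character(eq$net_scores$pair)],
               ignore_attr = TRUE)
})

test_that("identical site types give all-zero scores flagged equivalent", {
  s <- make_summaries()
  nm <- dplyr::filter(s, site_type == "NM")
  s_equal <- dplyr::bind_rows(nm, dplyr::mutate(nm, site_type = "LS"))
  eq <- equivalence_table(s_equal)
  expect_true(all(eq$z$z == 0))
  expect_true(all(eq$net_scores$net_score == 0))
  expect_true(all(eq$metric_means$equivalent))
})

test_that("relabelling LS and NM negates every score exactly", {
  obs <- simulate_study(study_design(seed = 31), effect_spec())
  s <- summarize_sites(obs)
  eq <- suppressWarnings(equivalence_table(s))
  swapped <- dplyr::mutate(
    s, site_type = ifelse(site_type == "LS", "NM", "LS"))
  eq_sw <- suppressWarnings(equivalence_table(swapped))
  expect_identical(eq$z[, c("pair", "metric")],
                   eq_sw$z[, c("pair", "metric")])
  expect_equal(eq_sw$z$z, -eq$z$z)
  expect_equal(eq_sw$net_scores$net_score, -eq$net_scores$net_score)
})

test_that("z-scores are invariant to rescaling a metric's units", {
  obs <- simulate_study(study_design(seed = 33), effect_spec())
  s <- summarize_sites(obs)
  eq <- suppressWarnings(equivalence_table(s))
  for (m in c("carbon", "fish_biomass")) {
    for (c_mult in c(0.01, 7)) {
      s2 <- dplyr::mutate(
        s,
        mean = ifelse(metric == m, mean * c_mult, mean),
        sd = ifelse(metric == m, sd * c_mult, sd))
      eq2 <- suppressWarnings(equivalence_table(s2))
      expect_equal(eq2$z$z[eq2$z$metric == m], eq$z$z[eq$z$metric == m],
                   tolerance = 1e-12)
    }
  }
})

test_that("grand mean equals the mean of metric means when balanced", {
  obs <- simulate_study(study_design(seed = 35), effect_spec())
  eq <- suppressWarnings(equivalence_table(summarize_sites(obs)))
  mm <- eq$metric_means
  expect_equal(eq$grand_mean, mean(mm$mean_z[mm$in_net_score]),
               tolerance = 1e-12)
  # the |Z| < 1 flag re-derives from the stored matrix
  rechecked <- tapply(eq$z$z, eq$z$metric, mean, na.rm = TRUE)
  expect_equal(abs(rechecked[mm$metric]) < 1, mm$equivalent,
               ignore_attr = TRUE)
  # the auxiliary low-marsh mussel variant never enters the net score
  expect_false(mm$in_net_score[mm$metric == "mussels_lm"])
})

test_that("gaps and degenerate SDs are reported, not propagated", {
  s <- make_summaries()
  expect_error(equivalence_table(s[-1, ]), "carbon")
  s_deg <- dplyr::mutate(
    s, sd = ifelse(metric == "carbon" & pair == 2, 0, sd))
  expect_warning(eq <- equivalence_table(s_deg), "pair\\(s\\) 2")
  expect_true(is.na(eq$z$z[eq$z$metric == "carbon" & eq$z$pair == 2]))
  expect_false(anyNA(eq$z$z[eq$z$metric == "carbon" & eq$z$pair != 2]))
  expect_error(
    equivalence_table(dplyr::mutate(s, metric = replace(
      metric, 1:2, "unheard_of"))),
    "without definitions")
})

test_that("tidy, glance and autoplot expose the table", {
  eq <- equivalence_table(make_summaries())
  expect_identical(tidy(eq), eq$z)
  g <- glance(eq)
  expect_equal(g$n_pairs, 3)
  expect_s3_class(autoplot(eq), "ggplot")
})
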