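test_that("truncation retains the floor((1-p) n) nearest sightings", {
  set.seed(1)
  expect_length(truncate_distances(runif(178)), 169)
  expect_length(truncate_distances(runif(20)), 19)
  expect_length(truncate_distances(runif(1)), 1)
  expect_error(truncate_distances(numeric(0)), "No distances")
  # ties at the cutoff keep earlier-indexed records
  d <- c(5, 9, 9, 1, 9, 2, 3, 4, 6, 7, 8, 9, 9, 9, 9, 9, 9, 9, 9, 9)
  kept <- truncate_distances(d)  # 19 of 20
  idx <- attr(kept, "index")
  expect_length(kept, 19)
  expect_false(20 %in% idx)      # the last of the tied 9s is dropped
  expect_true(all(idx[kept < 9] < 20))
})

test_that("quadrature normalizers match adaptive integration", {
  cases <- list(list(key = "half-normal", sigma = 15, shape = NULL),
                list(key = "hazard-rate", sigma = 20, shape = 2.5))
  w <- 50
  gl <- marshequiv:::gauss_legendre(61, 0, w)
  for (cs in cases) {
    mine <- marshequiv:::normalizer_by_sigma(gl, w, cs$key, cs$sigma,
                                             cs$shape, "none", numeric(0))
    oracle <- integrate(function(u) {
      u * marshequiv:::key_g(u, cs$key, cs$sigma, cs$shape)
    }, 0, w, rel.tol = 1e-12)$value
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("the half-normal scale is recovered from simulated distances", {
  spec <- terrapin_sim_spec("half-normal", sigma = 20, w = 60,
                            encounter_rate = 40)
  sim <- simulate_terrapin_distances(spec, 50, seed = 17)
  expect_gt(nrow(sim), 1500)
  fit <- fit_detection(sim$distance_m, key = "half-normal", w = 60)
  # SE(sigma-hat) is about sigma / (2 sqrt n) here, so 3 SE ~ 0.7 m
  expect_lt(abs(fit$sigma - 20), 3 * 20 / (2 * sqrt(nrow(sim))) + 0.2)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$k)
})

test_that("uniform detection saturates the effective radius at w", {
  r <- withr::with_seed(3, 50 * sqrt(runif(800)))  # g identically 1
  fit <- fit_detection(r, key = "half-normal", w = 50)
  edr <- effective_radius(fit, n_boot = 0)
  expect_gt(edr$rho / 50, 0.95)
  expect_gt(fit$sigma, 50)  # scale runs away to flatness
})

test_that("effective radius matches the half-normal closed form", {
  for (sigma in c(5, 20, 45)) {
    for (w in c(30, 60, 120)) {
      expect_equal(marshequiv:::edr_value(w, "half-normal", sigma),
                   edr_halfnormal_closed(sigma, w), tolerance = 1e-10)
    }
  }
  # perfect detection: rho = w
  expect_equal(marshequiv:::edr_value(50, "half-normal", 1e8), 50,
               tolerance = 1e-6)
  # monotone in sigma
  rhos <- vapply(seq(5, 60, by = 5), function(s) {
    marshequiv:::edr_value(50, "hazard-rate", s, shape = 2.5)
  }, numeric(1))
  expect_true(all(diff(rhos) >= 0))
})

test_that("the miss/detect balance identity holds for fitted models", {
  spec <- terrapin_sim_spec("hazard-rate", sigma = 20, shape = 3, w = 70,
                            encounter_rate = 25)
  sim <- simulate_terrapin_distances(spec, 40, seed = 23)
  fit <- fit_detection(sim$distance_m, key = "hazard-rate", w = 70)
  rho <- effective_radius(fit, n_boot = 0)$rho
  g <- function(r) marshequiv:::detection_g(r, fit$w, fit$key, fit$sigma,
                                            fit$shape, fit$expansion,
                                            fit$adj)
  missed_inside <- integrate(function(r) 2 * pi * r * (1 - g(r)), 0, rho,
                             rel.tol = 1e-12)$value
  detected_beyond <- integrate(function(r) 2 * pi * r * g(r), rho, fit$w,
                               rel.tol = 1e-12)$value
  expect_equal(missed_inside, detected_beyond, tolerance = 1e-8)
  expect_gt(rho, 0)
  expect_lte(rho, fit$w)
})

test_that("AIC selection respects the goodness-of-fit guard", {
  fake <- function(logL, k, gof_p, key = "half-normal") {
    structure(list(key = key, expansion = "none", n_adj = 0,
                   logLik = logL, k = k, AIC = -2 * logL + 2 * k,
                   gof_p = gof_p, converged = TRUE),
              class = "detection_fit")
  }
  # equal log-likelihood: the smaller model wins by 2 AIC
  sel <- select_detection(list(fake(-100, 3, 0.5), fake(-100, 2, 0.5)))
  expect_equal(sel$k, 2)
  # selection is invariant to a shared constant in the log-likelihood
  sel_shift <- select_detection(list(fake(-100 + 55, 3, 0.5),
                                     fake(-100 + 55, 2, 0.5)))
  expect_equal(sel_shift$k, sel$k)
  # a failing GoF removes a model from contention
  sel2 <- select_detection(list(fake(-99, 2, 0.01), fake(-100, 2, 0.6)))
  expect_equal(sel2$logLik, -100)
  expect_false(sel2$gof_failed)
  # no model passing: lowest AIC returned, flagged
  expect_warning(sel3 <- select_detection(list(fake(-99, 2, 0.01),
                                               fake(-100, 2, 0.02))),
                 "goodness-of-fit")
  expect_true(sel3$gof_failed)
  expect_equal(sel3$logLik, -99)
  # single fit passes through
  single <- fake(-50, 2, 0.8)
  expect_equal(select_detection(list(single))$logLik, -50)
  expect_error(select_detection(list()), "No converged")
})

test_that("hazard-rate data select the hazard-rate key most of the time", {
  wins <- vapply(1:3, function(i) {
    spec <- terrapin_sim_spec("hazard-rate", sigma = 25, shape = 3, w = 80,
                              encounter_rate = 40)
    sim <- simulate_terrapin_distances(spec, 50, seed = 40 + i)
    fits <- list(
      fit_detection(sim$distance_m, key = "half-normal", w = 80),
      fit_detection(sim$distance_m, key = "hazard-rate", w = 80))
    suppressWarnings(select_detection(fits)$key) == "hazard-rate"
  }, logical(1))
  expect_gte(sum(wins), 2)
})

test_that("covariates shift the detection scale in the simulated direction", {
  spec <- terrapin_sim_spec("half-normal", sigma = 25, w = 80,
                            encounter_rate = 25, wind_effect = -0.4)
  sim <- simulate_terrapin_distances(spec, 80, seed = 19)
  fit <- fit_detection(sim, key = "half-normal", covariates = "wind_mps",
                       w = 80)
  expect_lt(unname(fit$beta["wind_mps"]), 0)
  expect_equal(fit$k, 2)
  expect_error(fit_detection(sim, covariates = "no_such_column"),
               "missing")
})

test_that("bootstrap intervals bracket the point estimate", {
  spec <- terrapin_sim_spec("half-normal", sigma = 20, w = 60,
                            encounter_rate = 10)
  sim <- simulate_terrapin_distances(spec, 25, seed = 29)
  fit <- fit_detection(sim$distance_m, key = "half-normal", w = 60)
  edr <- effective_radius(fit, n_boot = 40, seed = 5)
  expect_true(edr$ci[1] <= edr$rho && edr$rho <= edr$ci[2])
  expect_identical(effective_radius(fit, n_boot = 0)$rho, edr$rho)
})

test_that("degenerate inputs are rejected with clear messages", {
  expect_error(fit_detection(runif(5, 0, 10)), "At least 10")
  expect_error(fit_detection(c(runif(20, 0, 10), 50), w = 30), "exceed")
  expect_error(fit_detection(runif(30, 0, 10), expansion = "fourier",
                             n_adj = 1), "expansion")
})
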