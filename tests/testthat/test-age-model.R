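make_age_data <- function(seed = 1, n = 13, b0 = -0.3, b1 = 0.25,
                          sigma = 0.3) {
  withr::with_seed(seed, {
    age <- rep_len(reference_ages(), n)
    tibble::tibble(age = age,
                   net_score = rnorm(n, b0 + b1 * log(age), sigma))
  })
}

test_that("seeded fits are bit-reproducible and inputs are validated", {
  d <- make_age_data()
  a <- suppressWarnings(
    fit_age_model(d, chains = 2, iter = 1500, warmup = 400, seed = 5))
  b <- suppressWarnings(
    fit_age_model(d, chains = 2, iter = 1500, warmup = 400, seed = 5))
  expect_identical(a$draws, b$draws)
  expect_identical(suppressWarnings(psis_loo(a)$looic),
                   suppressWarnings(psis_loo(b)$looic))
  expect_error(fit_age_model(dplyr::mutate(d, age = age - 10)), "Ages")
  expect_error(fit_age_model(d[1:2, ]), "At least 3")
  expect_error(fit_age_model(d, iter = 150, warmup = 100), "100 post-warmup")
})

test_that("with the likelihood off the posterior returns the priors", {
  fit <- fit_age_model(make_age_data(), chains = 2, iter = 8000,
                       warmup = 1500, seed = 2, prior_only = TRUE)
  s <- fit$summary
  expect_equal(s$mean[s$parameter == "beta1"], 0.25, tolerance = 0.06)
  expect_equal(s$sd[s$parameter == "beta1"], 0.75, tolerance = 0.06)
  expect_equal(s$mean[s$parameter == "beta0"], 0, tolerance = 0.08)
  expect_equal(s$mean[s$parameter == "sigma"], 1, tolerance = 0.08)
})

test_that("the null model matches a dense-grid posterior on stable data", {
  d <- tibble::tibble(age = reference_ages(),
                      net_score = withr::with_seed(30, rnorm(13, 0.8, 0.3)))
  fit <- fit_null_model(d, chains = 4, iter = 12000, warmup = 2000,
                        seed = 3)
  oracle <- grid_posterior(d$net_score, d$age, null = TRUE)
  s <- fit$summary
  # posterior concentrates near the sample mean, shrunk toward the prior 0
  expect_lt(s$mean[s$parameter == "beta0"], mean(d$net_score))
  expect_equal(s$mean[s$parameter == "beta0"],
               unname(oracle$mean["beta0"]), tolerance = 0.01)
  expect_equal(s$mean[s$parameter == "sigma"],
               unname(oracle$mean["sigma"]), tolerance = 0.02)
})

test_that("convergence diagnostics accompany every parameter", {
  fit <- fit_age_model(make_age_data(), chains = 4, iter = 4000,
                       warmup = 1000, seed = 7)
  expect_setequal(fit$diagnostics$parameter, c("beta0", "beta1", "sigma"))
  expect_true(all(fit$diagnostics$rhat < 1.05))
  expect_true(all(fit$diagnostics$ess > 100))
  expect_true(all(fit$draws$sigma > 0))
  s <- fit$summary
  expect_true(all(s$q2.5 <= s$median & s$median <= s$q97.5))
})

test_that("the probability of a non-positive age effect counts draws", {
  fit <- suppressWarnings(
    fit_age_model(make_age_data(), chains = 2, iter = 1500,
                  warmup = 400, seed = 5))
  pos <- fit
  pos$draws$beta1 <- abs(pos$draws$beta1) + 0.01
  expect_equal(prob_overlap_zero(pos), 0)
  sym <- fit
  sym$draws$beta1 <- withr::with_seed(1, rnorm(nrow(fit$draws)))
  expect_equal(prob_overlap_zero(sym), 0.5, tolerance = 0.05)
  null_fit <- suppressWarnings(
    fit_null_model(make_age_data(), chains = 2, iter = 1500,
                   warmup = 400, seed = 5))
  expect_error(prob_overlap_zero(null_fit), "beta1")
})

test_that("posterior predictive checks flag misfit and pass on-model data", {
  d <- make_age_data(seed = 42)
  fit <- fit_age_model(d, chains = 2, iter = 6000, warmup = 1000, seed = 6)
  ppc <- posterior_predictive_check(fit, n_reps = 500, seed = 1)
  expect_true(ppc$quantiles["mean"] > 0.01 && ppc$quantiles["mean"] < 0.99)
  expect_true(ppc$quantiles["sd"] > 0.01 && ppc$quantiles["sd"] < 0.99)

  # data this posterior cannot describe: one gross outlier pushes the
  # observed SD into the far tail of the replicated SDs
  fit_h <- fit
  fit_h$data$net_score[1] <- 25
  ppc_h <- posterior_predictive_check(fit_h, n_reps = 500, seed = 1)
  expect_gt(ppc_h$quantiles["sd"], 0.99)
})

test_that("tidy, glance and autoplot summarize a fit", {
  fit <- suppressWarnings(
    fit_age_model(make_age_data(), chains = 2, iter = 1500,
                  warmup = 400, seed = 5))
  expect_identical(tidy(fit), fit$summary)
  g <- suppressWarnings(glance(fit))
  expect_equal(g$model, "log_age")
  expect_true(is.finite(g$looic))
  expect_s3_class(autoplot(fit), "ggplot")
})
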