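# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Dense-grid posterior for the logarithmic age model (or its intercept-only
# null): direct Riemann integration of prior x likelihood over a 3- (or 2-)
# dimensional grid. Returns posterior means and SDs.
grid_posterior <- function(y, age, null = FALSE,
                           n_beta = 201, n_sigma = 150) {
  lx <- log(age)
  n <- length(y)
  ols <- if (null) lm(y ~ 1) else lm(y ~ lx)
  se <- summary(ols)$coefficients[, 2]
  ctr <- coef(ols)
  span <- pmax(8 * se, 0.5)
  b0_grid <- seq(ctr[1] - span[1], ctr[1] + span[1], length.out = n_beta)
  s_grid <- seq(1e-3, max(4 * sd(y), 0.5), length.out = n_sigma)
  lp_prior_s <- dgamma(s_grid, 1, 1, log = TRUE)

  if (null) {
    sse <- vapply(b0_grid, function(b0) sum((y - b0)^2), numeric(1))
    lp <- outer(sse, s_grid, function(ss, s) -n * log(s) - ss / (2 * s^2))
    lp <- lp + dnorm(b0_grid, 0, 1, log = TRUE)  # recycles down rows
    lp <- sweep(lp, 2, lp_prior_s, "+")
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    wb0 <- rowSums(w)
    ws <- colSums(w)
    means <- c(beta0 = sum(wb0 * b0_grid), sigma = sum(ws * s_grid))
    sds <- c(beta0 = sqrt(sum(wb0 * b0_grid^2) - means[1]^2),
             sigma = sqrt(sum(ws * s_grid^2) - means[2]^2))
    return(list(mean = means, sd = sds))
  }

  b1_grid <- seq(ctr[2] - span[2], ctr[2] + span[2], length.out = n_beta)
  # SSE over the (b0, b1) plane
  sse <- outer(b0_grid, b1_grid, Vectorize(function(b0, b1) {
    sum((y - b0 - b1 * lx)^2)
  }))
  lp_b <- outer(dnorm(b0_grid, 0, 1, log = TRUE),
                dnorm(b1_grid, 0.25, 0.75, log = TRUE), "+")
  acc <- matrix(0, 3, 2, dimnames = list(c("beta0", "beta1", "sigma"),
                                         c("m1", "m2")))
  tot <- 0
  lp_max <- NULL
  # two passes: find max, then accumulate
  lp_s_part <- function(s) -n * log(s) - sse / (2 * s^2) + lp_b +
    dgamma(s, 1, 1, log = TRUE)
  lp_max <- max(vapply(s_grid, function(s) max(lp_s_part(s)), numeric(1)))
  for (k in seq_along(s_grid)) {
    w <- exp(lp_s_part(s_grid[k]) - lp_max)
    sw <- sum(w)
    tot <- tot + sw
    acc["beta0", "m1"] <- acc["beta0", "m1"] + sum(rowSums(w) * b0_grid)
    acc["beta0", "m2"] <- acc["beta0", "m2"] + sum(rowSums(w) * b0_grid^2)
    acc["beta1", "m1"] <- acc["beta1", "m1"] + sum(colSums(w) * b1_grid)
    acc["beta1", "m2"] <- acc["beta1", "m2"] + sum(colSums(w) * b1_grid^2)
    acc["sigma", "m1"] <- acc["sigma", "m1"] + sw * s_grid[k]
    acc["sigma", "m2"] <- acc["sigma", "m2"] + sw * s_grid[k]^2
  }
  means <- acc[, "m1"] / tot
  sds <- sqrt(acc[, "m2"] / tot - means^2)
  list(mean = means, sd = sds)
}

# Closed-form effective detection radius for a half-normal key with finite
# truncation distance.
edr_halfnormal_closed <- function(sigma, w) {
  sigma * sqrt(2) * sqrt(1 - exp(-w^2 / (2 * sigma^2)))
}

# Brute-force abundance-weighted taxonomic distinctness: explicit double
# sum over all unordered species pairs.
distinctness_brute <- function(counts, w) {
  num <- den <- 0
  for (i in seq_along(counts)) {
    for (j in seq_along(counts)) {
      if (j <= i) next
      num <- num + w[i, j] * counts[i] * counts[j]
      den <- den + counts[i] * counts[j]
    }
  }
  num / den
}

# A small hand-built site-summary table: 3 pairs, one local-SD metric and
# one regional-SD metric, with both site types present.
make_summaries <- function() {
  tibble::tibble(
    pair = rep(1:3, each = 2, times = 2),
    site_type = rep(c("LS", "NM"), 6),
    metric = rep(c("carbon", "fish_biomass"), each = 6),
    mean = c(1.0, 2.0, 2.0, 2.5, 3.0, 3.1,
             100, 80, 150, 90, 120, 160),
    sd = c(0.4, 0.3, 0.5, 0.5, 0.2, 0.6,
           rep(NA_real_, 6)),
    n = c(rep(3L, 6), rep(24L, 6)))
}
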