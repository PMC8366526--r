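#' Truncate the farthest sighting distances
#'
#' Distance-sampling practice discards the farthest observations before
#' fitting a detection function because the sparse right tail carries
#' little information about the detection scale. The rule retains the
#' `max(1, floor((1 - p) * n))` smallest distances; ties at the cutoff are
#' broken by retaining earlier-indexed records.
#'
#' @param distances Numeric vector of radial distances (>= 0), length >= 1.
#' @param p Proportion of the farthest observations to drop (default 0.05).
#' @return The retained distances in their original order, with an
#'   attribute `index` giving the retained positions.
#' @examples
#' length(truncate_distances(runif(178)))  # 169
#' @export
truncate_distances <- function(distances, p = 0.05) {
  n <- length(distances)
  if (n == 0) abort("No distances supplied.")
  if (any(distances < 0) || any(!is.finite(distances))) {
    abort("Distances must be finite and >= 0.")
  }
  keep_n <- max(1L, floor((1 - p) * n))
  ord <- order(distances)          # stable: ties keep earlier index first
  idx <- sort(ord[seq_len(keep_n)])
  out <- distances[idx]
  attr(out, "index") <- idx
  out
}

# Detection (key) functions, g(0) = 1.
key_g <- function(r, key, sigma, shape = NULL) {
  if (key == "half-normal") {
    exp(-r^2 / (2 * sigma^2))
  } else {
    ifelse(r == 0, 1, 1 - exp(-(r / sigma)^(-shape)))
  }
}

# Series adjustment value (unnormalized multiplier - 1 part), scaled
# distance x = r / w. Orders follow common distance-sampling defaults.
adj_terms <- function(x, expansion, n_adj) {
  if (n_adj == 0) return(matrix(0, length(x), 0))
  orders <- seq(2, length.out = n_adj)
  switch(expansion,
    cosine = sapply(orders, function(j) cos(j * pi * x)),
    poly = sapply(orders, function(j) x^(2 * j)),
    hermite = sapply(orders, function(j) hermite_poly(2 * j, x)),
    abort(sprintf("Unknown expansion '%s'.", expansion))) |>
    matrix(nrow = length(x))
}

hermite_poly <- function(ord, x) {
  # physicists' Hermite via recurrence
  h0 <- rep(1, length(x)); h1 <- 2 * x
  if (ord == 0) return(h0)
  for (k in 2:ord) {
    h2 <- 2 * x * h1 - 2 * (k - 1) * h0
    h0 <- h1; h1 <- h2
  }
  h1
}

# Full detection function with adjustments, rescaled so g(0) = 1.
detection_g <- function(r, w, key, sigma, shape, expansion, adj) {
  base <- key_g(r, key, sigma, shape)
  if (length(adj) == 0) return(base)
  base * adj_factor(r / w, expansion, adj)
}

# Multiplicative series adjustment, rescaled to 1 at r = 0; independent of
# the scale parameter, so it factors out of per-covariate integrals.
adj_factor <- function(x, expansion, adj) {
  if (length(adj) == 0) return(rep(1, length(x)))
  A <- adj_terms(x, expansion, length(adj))
  A0 <- adj_terms(0, expansion, length(adj))
  (1 + drop(A %*% adj)) / (1 + drop(A0 %*% adj))
}

# int_0^w u g(u; sigma) du for each sigma in a vector, sharing one set of
# quadrature nodes (nodes x sigmas key matrix).
normalizer_by_sigma <- function(gl, w, key, sigmas, shape, expansion, adj) {
  K <- if (key == "half-normal") {
    exp(-outer(gl$nodes^2, 2 * sigmas^2, "/"))
  } else {
    1 - exp(-outer(gl$nodes, sigmas, "/")^(-shape))
  }
  av <- adj_factor(gl$nodes / w, expansion, adj)
  colSums(gl$weights * gl$nodes * av * K)
}

#' Fit a point-transect detection function by maximum likelihood
#'
#' Radial sighting distances r on (0, w] have density f(r) proportional to
#' r g(r), where g is the detection function (probability of detecting an
#' animal at distance r, g(0) = 1). Two keys are supported — half-normal
#' g(r) = exp(-r^2 / (2 sigma^2)) and hazard-rate
#' g(r) = 1 - exp(-(r/sigma)^-b) with shape b > 1 — optionally multiplied
#' by a cosine, simple-polynomial or Hermite-polynomial series with up to
#' `n_adj` adjustment terms (rescaled to keep g(0) = 1, with g
#' constrained non-negative). Covariates enter the scale as
#' sigma_i = exp(beta0 + beta' z_i) with z-scored covariate columns. The
#' per-observation normalizing integral is evaluated by Gauss-Legendre
#' quadrature.
#'
#' @param sightings A data frame with column `distance_m` (plus any
#'   covariate columns), or a bare numeric vector of distances. Distances
#'   are assumed already truncated (see [truncate_distances()]).
#' @param key `"half-normal"` or `"hazard-rate"`.
#' @param expansion `"none"`, `"cosine"`, `"poly"` or `"hermite"`.
#' @param n_adj Number of adjustment terms (0-2; ignored for
#'   `expansion = "none"`).
#' @param covariates Character vector of covariate column names entering
#'   the log scale, or `NULL`.
#' @param w Truncation distance; defaults to the largest observed distance.
#' @param n_bins Equal-count distance bins for the chi-square
#'   goodness-of-fit test.
#' @return An object of class `detection_fit`: parameter estimates
#'   (`sigma` and `shape` at the covariate reference, covariate
#'   coefficients), `logLik`, `AIC`, `k` free parameters, goodness-of-fit
#'   (`gof_stat`, `gof_df`, `gof_p`), `w`, and the data used.
#' @examples
#' sim <- simulate_terrapin_distances(
#'   terrapin_sim_spec("half-normal", sigma = 20, w = 60), 60, seed = 2)
#' fit_detection(sim$distance_m, key = "half-normal", w = 60)
#' @export
fit_detection <- function(sightings, key = c("half-normal", "hazard-rate"),
                          expansion = "none", n_adj = 0, covariates = NULL,
                          w = NULL, n_bins = 6) {
  key <- match.arg(key)
  if (expansion == "none") n_adj <- 0L
  if (n_adj > 0 && !expansion %in% c("cosine", "poly", "hermite")) {
    abort("`expansion` must be 'cosine', 'poly' or 'hermite' when n_adj > 0.")
  }
  df <- if (is.data.frame(sightings)) tibble::as_tibble(sightings)
        else tibble::tibble(distance_m = as.numeric(sightings))
  if (!"distance_m" %in% names(df)) abort("`sightings` needs a `distance_m` column.")
  r <- df$distance_m
  if (length(r) < 10) abort("At least 10 retained sightings are required.")
  if (is.null(w)) w <- max(r)
  if (any(r > w)) abort("Distances exceed the truncation distance `w`.")

  Z <- NULL
  z_center <- z_scale <- NULL
  if (!is.null(covariates)) {
    missing_cov <- setdiff(covariates, names(df))
    if (length(missing_cov)) {
      abort(sprintf("Covariate column(s) missing: %s.",
                    paste(missing_cov, collapse = ", ")))
    }
    Z <- as.matrix(df[, covariates, drop = FALSE])
    z_center <- colMeans(Z)
    z_scale <- apply(Z, 2, sd)
    z_scale[z_scale == 0] <- 1
    Z <- sweep(sweep(Z, 2, z_center), 2, z_scale, "/")
  }
  n_cov <- if (is.null(Z)) 0L else ncol(Z)
  has_shape <- key == "hazard-rate"

  gl <- gauss_legendre(61, 0, w)
  grid_check <- seq(0, w, length.out = 101)

  unpack <- function(par) {
    log_s0 <- par[1]
    beta <- if (n_cov) par[1 + seq_len(n_cov)] else numeric(0)
    pos <- 1 + n_cov
    shape <- if (has_shape) 1 + exp(par[pos + 1]) else NULL
    adj <- if (n_adj) par[(pos + has_shape + 1):(pos + has_shape + n_adj)]
           else numeric(0)
    sigma_i <- exp(log_s0 + if (n_cov) drop(Z %*% beta) else 0)
    list(sigma0 = exp(log_s0), beta = beta, shape = shape, adj = adj,
         sigma_i = sigma_i)
  }

  negll <- function(par) {
    p <- unpack(par)
    if (any(!is.finite(p$sigma_i)) || any(p$sigma_i <= 0)) return(1e10)
    # positivity of g across the range (checked at the reference scale and
    # the extremes of the fitted scales)
    for (s in unique(range(p$sigma_i))) {
      gg <- detection_g(grid_check, w, key, s, p$shape, expansion, p$adj)
      if (any(!is.finite(gg)) || any(gg < 0)) return(1e10)
    }
    g_r <- detection_g(r, w, key, p$sigma_i, p$shape, expansion, p$adj)
    if (any(g_r <= 0)) return(1e10)
    # normalizer per observation: int_0^w u g(u; sigma_i) du
    G <- if (n_cov) {
      normalizer_by_sigma(gl, w, key, p$sigma_i, p$shape, expansion, p$adj)
    } else {
      normalizer_by_sigma(gl, w, key, p$sigma_i[1], p$shape, expansion,
                          p$adj)
    }
    if (any(G <= 0) || any(!is.finite(G))) return(1e10)
    -sum(log(r) + log(g_r) - log(G))
  }

  start <- c(log(quantile(r, 0.6)),
             rep(0, n_cov),
             if (has_shape) log(1.5),
             rep(0, n_adj))
  if (length(start) == 1L) {
    opt <- optim(start, negll, method = "Brent",
                 lower = log(min(r[r > 0]) / 4), upper = log(20 * w))
  } else {
    opt <- optim(start, negll, method = "Nelder-Mead",
                 control = list(maxit = 3000, reltol = 1e-10))
    opt <- optim(opt$par, negll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
  }
  if (opt$value >= 1e9) {
    abort(sprintf(
      "Detection fit did not converge (key %s, expansion %s): %s",
      key, expansion, paste(deparse(round(opt$par, 3)), collapse = "")))
  }
  p <- unpack(opt$par)
  if (has_shape && p$shape < 1.001) {
    warn("Hazard-rate shape at its lower boundary (b near 1).")
  }
  k_free <- length(start)
  logL <- -opt$value
  fit <- structure(
    list(key = key, expansion = expansion, n_adj = n_adj,
         sigma = p$sigma0, shape = p$shape, adj = p$adj,
         beta = setNames(p$beta, covariates),
         covariates = covariates, z_center = z_center, z_scale = z_scale,
         sigma_i = p$sigma_i,
         logLik = logL, k = k_free, AIC = -2 * logL + 2 * k_free,
         w = w, data = df, converged = opt$convergence == 0),
    class = "detection_fit")
  gof <- detection_gof(fit, n_bins = n_bins)
  fit$gof_stat <- gof$stat
  fit$gof_df <- gof$df
  fit$gof_p <- gof$p
  fit
}

# Chi-square goodness of fit on equal-count distance bins.
detection_gof <- function(fit, n_bins = 6) {
  r <- fit$data$distance_m
  n <- length(r)
  n_bins <- max(2, min(n_bins, floor(n / 5)))
  breaks <- unique(quantile(r, probs = seq(0, 1, length.out = n_bins + 1)))
  breaks[1] <- 0
  breaks[length(breaks)] <- fit$w
  observed <- as.vector(table(cut(r, breaks, include.lowest = TRUE)))
  sig <- fit$sigma_i %||% rep(fit$sigma, n)
  den <- normalizer_by_sigma(gauss_legendre(61, 0, fit$w), fit$w, fit$key,
                             sig, fit$shape, fit$expansion, fit$adj)
  probs <- vapply(seq_len(length(breaks) - 1), function(b) {
    gl <- gauss_legendre(31, breaks[b], breaks[b + 1])
    num <- normalizer_by_sigma(gl, fit$w, fit$key, sig, fit$shape,
                               fit$expansion, fit$adj)
    mean(num / den)
  }, numeric(1))
  expected <- n * probs / sum(probs)
  stat <- sum((observed - expected)^2 / expected)
  df <- max(1, length(observed) - 1 - fit$k)
  list(stat = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("<detection_fit> %s%s, n = %d, w = %.1f m\n",
              x$key,
              if (x$n_adj) sprintf(" + %d %s term(s)", x$n_adj, x$expansion)
              else "",
              nrow(x$data), x$w))
  cat(sprintf("  sigma = %.2f m%s%s\n", x$sigma,
              if (!is.null(x$shape)) sprintf(", shape b = %.2f", x$shape)
              else "",
              if (length(x$beta))
                paste0(", ", paste(sprintf("%s = %.3f", names(x$beta),
                                           x$beta), collapse = ", "))
              else ""))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, GoF chi^2 p = %.3f\n",
              x$logLik, x$AIC, x$gof_p))
  invisible(x)
}

#' @describeIn fit_detection Parameter estimates in tidy form.
#' @param x,object A `detection_fit`.
#' @param ... Unused.
#' @export
tidy.detection_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma", if (!is.null(x$shape)) "shape", names(x$beta),
             if (x$n_adj) paste0("adj", seq_len(x$n_adj))),
    estimate = c(x$sigma, x$shape, unname(x$beta), x$adj))
}

#' @describeIn fit_detection One-row model summary.
#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(key = x$key, expansion = x$expansion, n_adj = x$n_adj,
                 n = nrow(x$data), logLik = x$logLik, AIC = x$AIC,
                 k = x$k, gof_p = x$gof_p, w = x$w)
}

#' @describeIn fit_detection Histogram of distances with the fitted
#'   point-transect density overlaid.
#' @export
autoplot.detection_fit <- function(object, ...) {
  r <- object$data$distance_m
  grid <- seq(1e-6, object$w, length.out = 200)
  g <- detection_g(grid, object$w, object$key, object$sigma, object$shape,
                   object$expansion, object$adj)
  gl <- gauss_legendre(61, 0, object$w)
  norm <- sum(gl$weights * gl$nodes *
                detection_g(gl$nodes, object$w, object$key, object$sigma,
                            object$shape, object$expansion, object$adj))
  dens <- tibble::tibble(r = grid, f = grid * g / norm)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(r = r),
      ggplot2::aes(x = .data$r, y = ggplot2::after_stat(density)),
      bins = 20, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$r, y = .data$f),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Radial distance (m)", y = "Density") +
    ggplot2::theme_minimal()
}

#' Select a detection function by AIC with a goodness-of-fit guard
#'
#' Among candidate fits, returns the lowest-AIC model whose chi-square
#' goodness-of-fit test is non-significant (p >= 0.05). If no candidate
#' passes the test, the lowest-AIC fit is returned with `gof_failed`
#' set, mirroring the practice of reporting the best available model with
#' a caveat.
#'
#' @param fits A list of `detection_fit` objects.
#' @return The selected `detection_fit` (with `gof_failed` flag).
#' @export
select_detection <- function(fits) {
  if (inherits(fits, "detection_fit")) fits <- list(fits)
  fits <- Filter(function(f) inherits(f, "detection_fit") && f$converged,
                 fits)
  if (!length(fits)) abort("No converged detection fits to select from.")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  ok <- vapply(fits, function(f) f$gof_p >= 0.05, logical(1))
  if (any(ok)) {
    best <- fits[ok][[which.min(aic[ok])]]
    best$gof_failed <- FALSE
  } else {
    best <- fits[[which.min(aic)]]
    best$gof_failed <- TRUE
    warn("No candidate passed the goodness-of-fit test; returning lowest-AIC fit.")
  }
  best
}

#' Fit the standard candidate set of detection functions
#'
#' Fits both keys with no adjustments and with 1-2 terms of each series
#' expansion, optionally with scale covariates, then selects by
#' [select_detection()]. Candidates that fail to converge are dropped.
#'
#' @inheritParams fit_detection
#' @param max_adj Maximum adjustment terms per series (default 2).
#' @return A list with `selected` (the chosen `detection_fit`) and
#'   `candidates` (a tibble of per-candidate AIC and GoF results).
#' @export
fit_detection_set <- function(sightings, covariates = NULL, w = NULL,
                              max_adj = 2) {
  grid <- dplyr::bind_rows(
    tidyr::expand_grid(key = c("half-normal", "hazard-rate"),
                       expansion = "none", n_adj = 0L),
    tidyr::expand_grid(key = c("half-normal", "hazard-rate"),
                       expansion = c("cosine", "poly", "hermite"),
                       n_adj = seq_len(max_adj)))
  fits <- purrr::pmap(grid, function(key, expansion, n_adj) {
    tryCatch(
      suppressWarnings(
        fit_detection(sightings, key = key, expansion = expansion,
                      n_adj = n_adj, covariates = covariates, w = w)),
      error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  fits <- fits[keep]
  grid <- grid[keep, ]
  candidates <- dplyr::mutate(
    grid,
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    gof_p = vapply(fits, `[[`, numeric(1), "gof_p"))
  list(selected = suppressWarnings(select_detection(fits)),
       candidates = dplyr::arrange(candidates, .data$AIC))
}

#' Effective detection radius of a fitted detection function
#'
#' The effective detection radius rho is the distance at which as many
#' animals are expected to be missed within rho as are detected beyond
#' it: rho = sqrt(2 * integral_0^w r g(r) dr). For a half-normal key with
#' w much larger than sigma this approaches sigma * sqrt(2); for perfect
#' detection (g = 1) it equals w. The confidence interval is a
#' nonparametric percentile bootstrap over sightings, refitting the same
#' model on each resample.
#'
#' @param fit A `detection_fit`.
#' @param n_boot Bootstrap resamples (default 999; 0 skips the CI).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `effective_radius`: `rho` (m), `ci`
#'   (lower/upper, `NA` when `n_boot = 0`), `n_boot`, and the bootstrap
#'   replicates.
#' @examples
#' sim <- simulate_terrapin_distances(
#'   terrapin_sim_spec("half-normal", sigma = 20, w = 60), 60, seed = 2)
#' fit <- fit_detection(sim$distance_m, key = "half-normal", w = 60)
#' effective_radius(fit, n_boot = 0)
#' @export
effective_radius <- function(fit, n_boot = 999, conf = 0.95, seed = 1L) {
  if (!inherits(fit, "detection_fit")) abort("`fit` must be a detection_fit.")
  rho <- edr_value(fit$w, fit$key, fit$sigma, fit$shape, fit$expansion,
                   fit$adj)
  if (!is.finite(rho)) abort("Effective-radius integral is not finite.")
  boots <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(fit$data), replace = TRUE)
        bf <- tryCatch(
          suppressWarnings(
            fit_detection(fit$data[idx, ], key = fit$key,
                          expansion = fit$expansion, n_adj = fit$n_adj,
                          covariates = fit$covariates, w = fit$w)),
          error = function(e) NULL)
        if (is.null(bf)) return(NA_real_)
        edr_value(bf$w, bf$key, bf$sigma, bf$shape, bf$expansion, bf$adj)
      }, numeric(1))
    })
    boots <- boots[is.finite(boots)]
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
  }
  structure(list(rho = rho, ci = ci, conf = conf, n_boot = n_boot,
                 boots = boots, fit = fit),
            class = "effective_radius")
}

# rho = sqrt(2 int_0^w r g(r) dr) by 201-node Gauss-Legendre quadrature.
edr_value <- function(w, key, sigma, shape = NULL, expansion = "none",
                      adj = numeric(0)) {
  gl <- gauss_legendre(201, 0, w)
  integral <- sum(gl$weights * gl$nodes *
                    detection_g(gl$nodes, w, key, sigma, shape, expansion,
                                adj))
  sqrt(2 * integral)
}

#' @export
print.effective_radius <- function(x, ...) {
  cat(sprintf("<effective_radius> rho = %.1f m", x$rho))
  if (x$n_boot > 0) {
    cat(sprintf(" (%.0f%% CI: [%.1f m - %.1f m], %d bootstrap resamples)",
                100 * x$conf, x$ci[1], x$ci[2], length(x$boots)))
  }
  cat("\n")
  invisible(x)
}
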