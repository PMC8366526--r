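# Pareto-smoothed importance-sampling leave-one-out cross-validation.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 profile
# posterior, with the weak shape prior used by standard PSIS practice).
gpd_fit <- function(x, prior_bs = 3, prior_k = 10) {
  x <- sort.int(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[floor(n / 4 + 0.5)]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  k_j <- vapply(theta, function(th) mean(log1p(-th * x)), numeric(1))
  l_j <- n * (log(-theta / k_j) - k_j - 1)
  w_j <- 1 / vapply(jj, function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w_j)
  k_hat <- mean(log1p(-theta_hat * x))
  sigma <- -k_hat / theta_hat
  # weakly informative shape prior stabilizes small tails
  k_hat <- (n * k_hat + prior_k * 0.5) / (n + prior_k)
  list(k = k_hat, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Smooth one vector of log importance ratios; returns smoothed log weights
# and the Pareto shape diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- NA_real_
  if (tail_len >= 5) {
    ord <- order(lw)
    tail_ids <- ord[(S - tail_len + 1):S]
    cut <- exp(lw[ord[S - tail_len]])
    exceed <- exp(lw[tail_ids]) - cut
    if (all(is.finite(exceed)) && length(unique(exceed)) >= 2) {
      fit <- gpd_fit(exceed)
      k <- fit$k
      if (is.finite(k)) {
        p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / tail_len
        smoothed <- cut + vapply(p, qgpd, numeric(1), k = fit$k,
                                 sigma = fit$sigma)
        smoothed <- pmin(smoothed, max(exp(lw)))
        lw[tail_ids] <- log(smoothed)
      }
    }
  }
  list(lw = lw - log_sum_exp(lw), k = k)
}

#' PSIS leave-one-out cross-validation from pointwise log-likelihoods
#'
#' Computes the expected log pointwise predictive density under
#' leave-one-out cross-validation by Pareto-smoothed importance sampling:
#' per observation, the raw importance ratios 1/p(y_i | theta_s) are
#' tail-smoothed with a generalized Pareto fit before reweighting the
#' posterior draws. LOOIC is -2 * elpd_loo, so lower values indicate
#' better out-of-sample prediction.
#'
#' @param x An `age_model_fit`, or a draws-by-observations matrix of
#'   pointwise log-likelihood values.
#' @return A list of class `psis_loo`: `elpd_loo`, `se_elpd`, `looic`,
#'   `p_loo` (effective parameter count), `pointwise` (tibble with
#'   per-observation `elpd` and Pareto `k`), and `pareto_k`.
#'   Observations with Pareto shape > 0.7 trigger a warning (the
#'   importance weights are then too heavy-tailed to trust).
#' @examples
#' d <- tibble::tibble(age = reference_ages(),
#'                     net_score = rnorm(13, -0.3, 0.5))
#' fit <- fit_age_model(d, chains = 2, iter = 2000, warmup = 500, seed = 1)
#' psis_loo(fit)$looic
#' @export
psis_loo <- function(x) {
  ll <- if (inherits(x, "age_model_fit")) x$loglik else as.matrix(x)
  if (!is.matrix(ll) || !is.numeric(ll)) {
    abort("`x` must be an age_model_fit or a numeric log-likelihood matrix.")
  }
  n <- ncol(ll)
  res <- purrr::map_dfr(seq_len(n), function(i) {
    sm <- psis_smooth(-ll[, i])
    tibble::tibble(
      observation = i,
      elpd = log_sum_exp(sm$lw + ll[, i]),
      lpd = log_sum_exp(ll[, i]) - log(nrow(ll)),
      k = sm$k)
  })
  high <- which(res$k > 0.7)
  if (length(high)) {
    warn(sprintf("Pareto shape diagnostic > 0.7 for observation(s) %s.",
                 paste(high, collapse = ", ")))
  }
  elpd <- sum(res$elpd)
  out <- list(elpd_loo = elpd,
              se_elpd = sqrt(n * var(res$elpd)),
              looic = -2 * elpd,
              p_loo = sum(res$lpd) - elpd,
              pointwise = res,
              pareto_k = res$k)
  class(out) <- "psis_loo"
  out
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("<psis_loo> elpd_loo %.2f (SE %.2f), looic %.2f, p_loo %.2f\n",
              x$elpd_loo, x$se_elpd, x$looic, x$p_loo))
  if (any(x$pareto_k > 0.7, na.rm = TRUE)) {
    cat(sprintf("  %d observation(s) with Pareto k > 0.7\n",
                sum(x$pareto_k > 0.7, na.rm = TRUE)))
  }
  invisible(x)
}

#' Compare two fitted models by LOOIC
#'
#' @param model_a,model_b `age_model_fit` objects (or `psis_loo` results)
#'   fitted to the same observations.
#' @return A tibble with one row per model (`model`, `looic`, `elpd_loo`,
#'   `se_elpd`) plus attributes `delta_looic` (looic_a - looic_b) and
#'   `se_delta` (SE of the pointwise elpd difference).
#' @examples
#' d <- tibble::tibble(age = reference_ages(),
#'                     net_score = rnorm(13, -0.3, 0.5))
#' a <- fit_age_model(d, chains = 2, iter = 2000, warmup = 500, seed = 1)
#' b <- fit_null_model(d, chains = 2, iter = 2000, warmup = 500, seed = 1)
#' compare_loo(a, b)
#' @export
compare_loo <- function(model_a, model_b) {
  as_loo <- function(m) if (inherits(m, "psis_loo")) m else psis_loo(m)
  name_of <- function(m, default) {
    if (inherits(m, "age_model_fit")) m$model else default
  }
  la <- as_loo(model_a)
  lb <- as_loo(model_b)
  if (nrow(la$pointwise) != nrow(lb$pointwise)) {
    abort("Models were fitted to different numbers of observations.")
  }
  diff <- la$pointwise$elpd - lb$pointwise$elpd
  out <- tibble::tibble(
    model = c(name_of(model_a, "model_a"), name_of(model_b, "model_b")),
    looic = c(la$looic, lb$looic),
    elpd_loo = c(la$elpd_loo, lb$elpd_loo),
    se_elpd = c(la$se_elpd, lb$se_elpd))
  attr(out, "delta_looic") <- la$looic - lb$looic
  attr(out, "se_delta") <- sqrt(length(diff) * var(diff)) * 2
  out
}

#' Exact leave-one-out cross-validation by refitting
#'
#' Refits the model once per observation with that observation held out
#' and evaluates the posterior-averaged predictive density of the held-out
#' point. With a handful of pairs this is cheap and serves as the exact
#' benchmark against which [psis_loo()] can be validated.
#'
#' @param fit An `age_model_fit` (its data and model are reused).
#' @param chains,iter,warmup MCMC settings for each refit (defaults
#'   shrink the original settings since 13 small refits need fewer draws).
#' @param seed Integer seed.
#' @return A list with `elpd_loo`, `looic` and `pointwise` elpd values.
#' @export
loo_exact_refit <- function(fit, chains = 2L, iter = 6000L, warmup = 1000L,
                            seed = 1L) {
  if (!inherits(fit, "age_model_fit")) abort("`fit` must be an age_model_fit.")
  data <- fit$data
  fitter <- if (fit$model == "log_age") fit_age_model else fit_null_model
  elpd <- vapply(seq_len(nrow(data)), function(i) {
    refit <- fitter(data[-i, ], chains = chains, iter = iter,
                    warmup = warmup, iter_includes_warmup = TRUE,
                    seed = sub_seed(seed, paste0("loo", i)))
    b1 <- if (fit$model == "log_age") refit$draws$beta1 else 0
    mu <- refit$draws$beta0 + b1 * log(data$age[i])
    ll <- dnorm(data$net_score[i], mu, refit$draws$sigma, log = TRUE)
    log_sum_exp(ll) - log(length(ll))
  }, numeric(1))
  list(elpd_loo = sum(elpd), looic = -2 * sum(elpd), pointwise = elpd)
}
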