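# Internal numerical and plumbing helpers.

# Deterministic 32-bit sub-seed from a master seed and a character label, so
# each metric (or chain) gets its own reproducible stream and adding one
# metric never perturbs the draws of another.
sub_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647L
  as.integer((as.double(seed) * 69069 + h) %% 2147483647L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  invisible(x)
}

# Gauss-Legendre nodes/weights on [a, b]; smooth integrands only.
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  list(nodes = (b - a) / 2 * x[ord] + (a + b) / 2,
       weights = (b - a) / 2 * w[ord])
}

# Split-chain potential scale reduction factor (Rhat) for a iterations x
# chains matrix of draws.
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  mu <- colMeans(sub)
  B <- nn * var(mu)
  W <- mean(apply(sub, 2, var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Effective sample size from combined-chain autocorrelations (Geyer initial
# positive sequence, pairwise sums).
ess_basic <- function(draws) {
  n <- nrow(draws)
  m <- ncol(draws)
  max_lag <- min(n - 1, 500L)
  rho <- sapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[-1]
    a
  })
  rho <- rowMeans(matrix(rho, nrow = max_lag))
  # accumulate while paired sums stay positive
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
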