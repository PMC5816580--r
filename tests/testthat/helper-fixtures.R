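# Shared fixtures and independent oracles used across the suite.

# Fitted change-point parameters of the reference survey; also the defaults
# of synthetic_spec().
ref_params <- list(alpha = 0.675, beta1 = 0.024, beta2 = 0.002, gamma = 24.3)

# Write a small estuary CSV and return its path.
write_estuary_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# A tiny valid estuary table built in code.
tiny_estuary_df <- function(n = 6, seed = 101) {
  set.seed(seed)
  data.frame(
    name = paste0("est", seq_len(n)),
    mativ = runif(n),
    ce_ratio = exp(rnorm(n, 3, 0.5)),
    tf = exp(rnorm(n, 0.3, 0.3)),
    pop_prop_1 = runif(n),
    pct_modified = runif(n, 0, 100),
    pct_urbanized = runif(n, 0, 30),
    pct_fertilized = runif(n, 1, 99),
    areal_din_load = exp(rnorm(n, 1.5, 0.8))
  )
}

# Exact model-averaged posterior inclusion probabilities by enumerating all
# 2^k models with closed-form Gaussian marginal likelihoods (no intercept,
# known residual SD). Independent of the Gibbs sampler.
enum_pr_inc <- function(y, Z, p0 = 0.5, slab_sd = 1, sigma = 1) {
  k <- ncol(Z)
  n <- length(y)
  logml <- numeric(2^k)
  prior <- numeric(2^k)
  inc <- matrix(0L, 2^k, k)
  for (s in seq_len(2^k) - 1L) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    inc[s + 1L, idx] <- 1L
    Sg <- diag(sigma^2, n)
    if (length(idx)) {
      Zs <- Z[, idx, drop = FALSE]
      Sg <- Sg + slab_sd^2 * tcrossprod(Zs)
    }
    ch <- chol(Sg)
    logml[s + 1L] <- -0.5 * n * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * sum(backsolve(ch, y, transpose = TRUE)^2)
    prior[s + 1L] <- length(idx) * log(p0) + (k - length(idx)) * log(1 - p0)
  }
  w <- exp(logml + prior - max(logml + prior))
  w <- w / sum(w)
  colSums(inc * w)
}

# Brute-force hierarchical partitioning: average j's incremental R-squared
# over every predictor ordering. Independent of the Shapley-weight formula.
perm_hierpart_I <- function(y, Z) {
  k <- ncol(Z)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  I <- numeric(k)
  all_orders <- perms(seq_len(k))
  for (ord in all_orders) {
    sofar <- integer(0)
    r2_prev <- 0
    for (j in ord) {
      r2_now <- ols_r2(y, Z[, c(sofar, j), drop = FALSE])
      I[j] <- I[j] + (r2_now - r2_prev)
      sofar <- c(sofar, j)
      r2_prev <- r2_now
    }
  }
  I / length(all_orders)
}
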