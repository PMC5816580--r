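test_that("the piecewise mean evaluates its indicator formula literally", {
  expect_equal(piecewise_mean(0, ref_params), 0)
  expect_equal(piecewise_mean(10, ref_params), 0.24)
  expect_equal(piecewise_mean(50, ref_params), 0.675 + 0.002 * 50)
  # at F == gamma both indicators are 1, so both slope terms contribute
  p <- list(alpha = 0.5, beta1 = 0.02, beta2 = 0.01, gamma = 30)
  expect_equal(piecewise_mean(30, p), 0.5 + (0.02 + 0.01) * 30)
  # vectorized
  expect_equal(piecewise_mean(c(0, 10, 50), ref_params),
               c(0, 0.24, 0.775))
})

test_that("Gelman-Rubin follows the between/within variance formula", {
  n <- 10000
  x <- rnorm(n)
  expect_lt(gelman_rubin(cbind(x, x)), 1.001)
  expect_equal(gelman_rubin(cbind(x, x)), sqrt((n - 1) / n),
               tolerance = 1e-12)

  set.seed(60)
  div <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(div), 1.1)

  # hand-computed two-chain example, straight from the definition
  c1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  c2 <- c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9)
  W <- (var(c1) + var(c2)) / 2
  B <- 10 * var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(cbind(c1, c2)),
               sqrt(((10 - 1) / 10 * W + B / 10) / W), tolerance = 1e-12)

  expect_error(gelman_rubin(cbind(c1)), "2 chains")
  expect_error(gelman_rubin(list(c1, c2[1:5])), "equal length")
  expect_error(gelman_rubin(cbind(c1[1:4], c2[1:4])), "short")
})

test_that("plug-in R-squared has its fixed points", {
  y <- c(0.1, 0.4, 0.8, 0.3)
  expect_equal(model_r2(y, y), 1)
  expect_equal(model_r2(y, rep(mean(y), 4)), 0)
  expect_warning(r <- model_r2(rep(0.5, 4), y), "zero variance")
  expect_true(is.na(r))
  expect_error(model_r2(y, y[1:2]), "lengths differ")
})

test_that("the sampler recovers generative parameters with converged chains", {
  d <- generate_dataset(synthetic_spec(n_estuaries = 200, sigma_noise = 0.05,
                                       seed = 61))
  fit <- fit_changepoint(d$mativ, d$pct_fertilized, n_iter = 4000,
                         burn_in = 1500, n_chains = 3, seed = 62)
  s <- fit$summary
  truth <- c(ref_params, sigma = 0.05)
  for (p in names(truth)) {
    row <- s[s$parameter == p, ]
    expect_lt(abs(row$mean - truth[[p]]), 2 * row$sd + 1e-12)
  }
  expect_true(all(s$rhat <= 1.05))
  expect_gt(fit$r2, 0.9)
  # draw bookkeeping: chains x (iterations - burn-in)
  expect_equal(sum(vapply(fit$draws, nrow, integer(1))), 3 * 2500)
})

test_that("a constant response degenerates to a flat upper segment", {
  # y = c is fitted exactly by pushing gamma below the data range with
  # alpha = c and beta2 = 0; beta1 is then unidentified (no points below the
  # change-point) and reverts to its prior, while sigma collapses
  y <- rep(0.4, 20)
  F <- seq(2, 98, length.out = 20)
  suppressWarnings(
    fit <- fit_changepoint(y, F, n_iter = 3000, burn_in = 1000,
                           n_chains = 2, seed = 63)
  )
  s <- fit$summary
  get <- function(p, col) s[s$parameter == p, col]
  expect_lt(abs(get("beta2", "mean")), 0.005)
  expect_lt(get("gamma", "mean"), min(F))
  expect_equal(get("alpha", "mean"), 0.4, tolerance = 0.05)
  expect_lt(get("sigma", "mean"), 0.05)
  # unidentified slope below the change-point keeps its prior scale
  expect_gt(get("beta1", "sd"), 0.5)
})

test_that("with the likelihood disabled the sampler reproduces its priors", {
  fit <- fit_changepoint(rep(0.5, 10), seq(5, 95, length.out = 10),
                         n_iter = 12000, burn_in = 2000, n_chains = 2,
                         seed = 64, prior_only = TRUE)
  g <- do.call(rbind, fit$draws)[, "gamma"]
  # thin the correlated Metropolis draws before the distributional test
  g_thin <- g[seq(1, length(g), by = 20)]
  ks <- suppressWarnings(ks.test(g_thin, "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
  a <- do.call(rbind, fit$draws)[, "alpha"]
  expect_equal(mean(a), 0, tolerance = 0.1)
  expect_equal(sd(a), 2, tolerance = 0.1)
})

test_that("posterior means are stable across seeds within Monte-Carlo error", {
  d <- generate_dataset(synthetic_spec(seed = 65))
  means <- sds <- numeric(5)
  for (i in 1:5) {
    fit <- fit_changepoint(d$mativ, d$pct_fertilized, n_iter = 3000,
                           burn_in = 1000, n_chains = 2, seed = 70 + i)
    s <- fit$summary
    means[i] <- s$mean[s$parameter == "gamma"]
    # batch-means MC standard error from the pooled gamma draws
    g <- do.call(rbind, fit$draws)[, "gamma"]
    nb <- 40
    bm <- tapply(g, rep(seq_len(nb), each = length(g) / nb), mean)
    sds[i] <- sd(bm) / sqrt(nb)
  }
  expect_true(all(abs(means - mean(means)) <= 3 * (sds + mean(sds))))
})

test_that("credible intervals for the change-point cover the truth", {
  hits <- logical(50)
  for (r in seq_len(50)) {
    d <- generate_dataset(synthetic_spec(n_estuaries = 50,
                                         sigma_noise = 0.05,
                                         seed = 8000 + r))
    fit <- fit_changepoint(d$mativ, d$pct_fertilized, n_iter = 2500,
                           burn_in = 1000, n_chains = 2, seed = 900 + r)
    s <- fit$summary
    gi <- s[s$parameter == "gamma", ]
    hits[r] <- gi$q2.5 <= ref_params$gamma && ref_params$gamma <= gi$q97.5
  }
  expect_gte(mean(hits), 0.85)
})

test_that("input and configuration errors are raised before sampling", {
  y <- runif(10)
  F <- runif(10, 0, 100)
  expect_error(fit_changepoint(y, F[1:5]), "lengths differ")
  expect_error(fit_changepoint(c(y[-1], NA), F), "non-finite")
  expect_error(fit_changepoint(y, F, n_iter = 100, burn_in = 100),
               "n_iter")
  expect_error(fit_changepoint(y, F, n_chains = 1), "2 chains")
  expect_error(fit_changepoint(y[1:4], F[1:4]), "at least 5")
})
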