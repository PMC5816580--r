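test_that("posterior odds ratio follows its closed form and boundary contract", {
  expect_identical(posterior_odds_ratio(0.75, 0.5), 3)
  expect_identical(posterior_odds_ratio(0.5, 0.5), 1)
  expect_equal(posterior_odds_ratio(0.9, 0.5), 9)
  expect_equal(posterior_odds_ratio(0.75, 0.25), 9)

  p1 <- posterior_odds_ratio(1, 0.5)
  expect_true(is.infinite(p1) && attr(p1, "boundary"))
  p0 <- posterior_odds_ratio(0, 0.5)
  expect_true(p0 == 0 && attr(p0, "boundary"))
  expect_error(posterior_odds_ratio(0.5, 1), "p0")
})

test_that("importance flag, odds-ratio cut-off and Pr(Inc) >= 0.75 agree", {
  for (p in c(0.1, 0.5, 0.7499, 0.75, 0.76, 0.99)) {
    por <- posterior_odds_ratio(p, 0.5)
    expect_identical(p >= 0.75, por >= 3)
  }
})

test_that("interaction design expands three mains into seven standardized terms", {
  set.seed(30)
  Z <- standardize(matrix(rnorm(60), 20, 3,
                          dimnames = list(NULL, c("ce_ratio", "tf",
                                                  "pct_fertilized"))))
  Zi <- build_interaction_design(Z)
  expect_equal(ncol(Zi), 7)
  expect_true(all(abs(colMeans(Zi)) < 1e-10))
  expect_true(all(abs(apply(Zi, 2, sd) - 1) < 1e-10))
  # product columns equal elementwise products up to re-standardization
  prod_raw <- Z[, "ce_ratio"] * Z[, "tf"]
  expect_equal(unname(Zi[, "ce_ratio:tf"]),
               unname((prod_raw - mean(prod_raw)) / sd(prod_raw)))
  triple <- Z[, 1] * Z[, 2] * Z[, 3]
  expect_gt(abs(cor(Zi[, "ce_ratio:tf:pct_fertilized"], triple)), 0.999999)

  expect_error(build_interaction_design(Z, c("ce_ratio", "tf", "absent")),
               "missing column")
  # a constant column cannot be re-standardized; the failure is explicit
  Zz <- cbind(Z[, 1:2], pct_fertilized = rep(0, 20))
  expect_error(build_interaction_design(Zz), "constant column")
})

test_that("a strong coefficient is recovered and null predictors stay out", {
  set.seed(31)
  Z <- standardize(matrix(rnorm(200 * 6), 200, 6))
  y <- 0.3 * Z[, 1] + rnorm(200, 0, 0.1)
  fit <- fit_ssvs(y, Z, n_iter = 3000, burn_in = 1000, n_chains = 2,
                  seed = 32)
  expect_gte(fit$table$pr_inc[1], 0.9)
  expect_true(all(fit$table$pr_inc[-1] <= 0.2))
  expect_equal(fit$table$beta[1], 0.3, tolerance = 0.05)
  expect_true(fit$table$important[1])
  expect_false(any(fit$table$important[-1]))
})

test_that("pure-noise responses flag no term as important across seeds", {
  for (s in 1:10) {
    set.seed(300 + s)
    Z <- standardize(matrix(rnorm(200 * 4), 200, 4))
    y <- rnorm(200)
    fit <- fit_ssvs(y, Z, n_iter = 1500, burn_in = 500, n_chains = 2,
                    seed = 400 + s)
    expect_true(all(fit$table$pr_inc < 0.75))
  }
})

test_that("chains given the same seed produce identical draws", {
  set.seed(33)
  Z <- standardize(matrix(rnorm(30 * 3), 30, 3))
  y <- rnorm(30)
  f1 <- fit_ssvs(y, Z, n_iter = 500, burn_in = 100, n_chains = 2, seed = 34)
  f2 <- fit_ssvs(y, Z, n_iter = 500, burn_in = 100, n_chains = 2, seed = 34)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$table, f2$table)
  # chain c uses seed + c - 1: chain 2 of a seed-s run equals chain 1 of s+1
  f3 <- fit_ssvs(y, Z, n_iter = 500, burn_in = 100, n_chains = 2, seed = 35)
  expect_identical(f1$draws[[2]], f3$draws[[1]])
})

test_that("Gibbs inclusion probabilities match exact model enumeration", {
  # conjugate settings (no intercept, known sigma) admit an exact
  # model-averaged posterior over all 2^k models
  set.seed(36)
  for (k in 2:3) {
    Z <- standardize(matrix(rnorm(15 * k), 15, k))
    y <- 0.8 * Z[, 1] + rnorm(15, 0, 0.5)
    exact <- enum_pr_inc(y, Z, p0 = 0.5, slab_sd = 1, sigma = 0.5)
    fit <- fit_ssvs(y, Z, slab_sd = 1, sigma = 0.5, intercept = FALSE,
                    n_iter = 55000, burn_in = 5000, n_chains = 2,
                    seed = 37 + k)
    expect_equal(fit$table$pr_inc, unname(exact), tolerance = 0.03)
  }
})

test_that("prior dominance and weak-data limits hold", {
  set.seed(38)
  Z <- standardize(matrix(rnorm(40 * 3), 40, 3))
  y <- Z[, 1] + rnorm(40, 0, 0.3)
  # slab_sd -> 0 forces all model-averaged coefficients to zero
  fit0 <- fit_ssvs(y, Z, slab_sd = 1e-6, n_iter = 1200, burn_in = 200,
                   n_chains = 2, seed = 39)
  expect_true(all(abs(fit0$table$beta) < 1e-4))

  # with a nearly flat likelihood (large fixed sigma), Pr(Inc) returns to
  # the prior inclusion probability
  set.seed(40)
  Z5 <- standardize(matrix(rnorm(5 * 2), 5, 2))
  y5 <- rnorm(5)
  fitw <- fit_ssvs(y5, Z5, sigma = 25, intercept = FALSE, n_iter = 55000,
                   burn_in = 5000, n_chains = 1, seed = 41)
  expect_equal(fitw$table$pr_inc, c(0.5, 0.5), tolerance = 0.1)
})

test_that("configuration and shape errors are caught", {
  Z <- standardize(matrix(rnorm(30), 10, 3))
  y <- rnorm(10)
  expect_error(fit_ssvs(y, Z, n_iter = 100, burn_in = 100),
               "configuration error")
  expect_error(fit_ssvs(rnorm(9), Z), "rows")
  expect_error(fit_ssvs(rnorm(4), Z[1:4, ]), "observations")
  Zr <- cbind(Z, Z[, 1])
  expect_warning(fit_ssvs(y, Zr, n_iter = 200, burn_in = 50, n_chains = 2),
                 "rank-deficient")
})
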