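test_that("pairwise correlations match closed-form Pearson values", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 4)
  r <- pairwise_correlations(cbind(a = x, b = y))
  expect_equal(r["a", "b"], 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(round(r["a", "b"], 3), 0.982)

  dup <- cbind(a = x, b = x, c = -x)
  rd <- pairwise_correlations(dup)
  expect_equal(rd["a", "b"], 1)
  expect_equal(rd["a", "c"], -1)
  expect_equal(rd, t(rd))
  expect_equal(unname(diag(rd)), rep(1, 3))

  expect_error(pairwise_correlations(cbind(a = x, b = c(2, 2, 2))),
               "constant column 'b'")
  expect_error(pairwise_correlations(cbind(a = x[1:2], b = y[1:2])),
               "at least 3 rows")
})

test_that("collinearity screening keeps the member with the lowest external correlation sum", {
  # no pair above the threshold: everything retained
  set.seed(20)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, letters[1:4]))
  scr <- screen_collinearity(pairwise_correlations(X))
  expect_length(scr$dropped, 0)

  # hand-built 3-member inter-correlated component with known external sums
  cm <- diag(4)
  nm <- c("p1", "p2", "p3", "ext")
  dimnames(cm) <- list(nm, nm)
  cm["p1", "p2"] <- cm["p2", "p1"] <- 0.9
  cm["p2", "p3"] <- cm["p3", "p2"] <- 0.8
  cm["p1", "p3"] <- cm["p3", "p1"] <- 0.75
  cm["p1", "ext"] <- cm["ext", "p1"] <- 0.5
  cm["p2", "ext"] <- cm["ext", "p2"] <- 0.3
  cm["p3", "ext"] <- cm["ext", "p3"] <- 0.6
  scr <- screen_collinearity(cm, threshold = 0.7)
  expect_setequal(scr$retained, c("p2", "ext"))
  expect_setequal(scr$dropped, c("p1", "p3"))
  expect_true(any(grepl("retained 'p2'", scr$log)))
})

test_that("a fertilization-DIN pair is resolved in favour of fertilization", {
  # DIN concentration also tracks % modified, so its external correlation
  # sum exceeds fertilization's and it is the member screened out
  d <- generate_dataset(synthetic_spec(n_estuaries = 60, seed = 21))
  pred <- d[, setdiff(names(d), c("name", "mativ", "chlorophyll"))]
  cm <- pairwise_correlations(pred)
  expect_gt(cm["pct_fertilized", "din_concentration"], 0.7)
  scr <- screen_collinearity(cm)
  expect_true("din_concentration" %in% scr$dropped)
  expect_true("pct_fertilized" %in% scr$retained)

  # the retention rule itself: whichever member has the lower external
  # absolute-correlation sum is kept
  comp <- c("pct_fertilized", "din_concentration")
  outside <- setdiff(colnames(cm), comp)
  ext <- vapply(comp, function(j) sum(abs(cm[j, outside])), numeric(1))
  expect_identical(intersect(scr$retained, comp),
                   names(which.min(ext)))
})

test_that("screening output never contains a collinear pair and is order-invariant", {
  set.seed(22)
  for (rep in 1:20) {
    n <- 30
    k <- 6
    base <- matrix(rnorm(n * k), n, k)
    # random contamination to create collinear clusters
    for (j in sample(k, 2)) {
      i <- sample(k, 1)
      base[, j] <- base[, i] + rnorm(n, 0, runif(1, 0.1, 1))
    }
    colnames(base) <- paste0("v", seq_len(k))
    cm <- pairwise_correlations(base)
    scr <- screen_collinearity(cm)
    sub <- cm[scr$retained, scr$retained, drop = FALSE]
    off <- abs(sub[upper.tri(sub)])
    expect_true(all(off <= 0.7))
    # permuting the columns retains the same set
    perm <- sample(k)
    scr2 <- screen_collinearity(cm[perm, perm])
    expect_setequal(scr2$retained, scr$retained)
  }
})

test_that("log transform honours explicit lists, auto skewness and positivity", {
  d <- tiny_estuary_df(n = 20, seed = 23)
  X <- as.matrix(d[, c("ce_ratio", "tf", "pct_urbanized", "pct_fertilized",
                       "areal_din_load")])
  Xt <- log_transform_skewed(X)
  flags <- attr(Xt, "log_transformed")
  expect_true(all(flags[c("ce_ratio", "pct_urbanized", "pct_fertilized",
                          "areal_din_load")]))
  expect_false(flags[["tf"]])
  expect_equal(Xt[, "ce_ratio"], log(X[, "ce_ratio"]))
  expect_equal(Xt[, "tf"], X[, "tf"])

  ones <- cbind(u = rep(1, 5))
  expect_equal(unname(log_transform_skewed(ones, columns = "u")[, 1]),
               rep(0, 5))

  # auto mode flags a log-normal sample but not a normal one
  set.seed(24)
  A <- cbind(ln = exp(rnorm(500)), norm = rnorm(500))
  At <- log_transform_skewed(A, auto = TRUE)
  expect_true(attr(At, "log_transformed")[["ln"]])
  expect_false(attr(At, "log_transformed")[["norm"]])

  Xz <- cbind(v = c(0, 1, 2))
  expect_error(log_transform_skewed(Xz, columns = "v"),
               "non-positive value.*'v'.*row 1")
  expect_equal(unname(log_transform_skewed(Xz, columns = "v",
                                           offset = TRUE)[, 1]),
               log(c(1, 2, 3)))
})

test_that("standardization gives exact zero mean / unit SD and is idempotent", {
  expect_equal(unname(standardize(cbind(x = c(1, 2, 3)))[, 1]),
               c(-1, 0, 1))

  set.seed(25)
  X <- matrix(rexp(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- standardize(X)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  Z2 <- standardize(Z)
  expect_true(all(abs(Z2 - Z) < 1e-10))
  expect_equal(attr(Z, "center"), colMeans(X))

  expect_error(standardize(cbind(a = rep(2, 5))), "constant column 'a'")
})
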