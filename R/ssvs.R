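# Bayesian variable selection by stochastic search over binary inclusion
# indicators (Kuo-Mallick spike-and-slab): each standardized predictor enters
# the linear model as g_j * theta_j with g_j ~ Bernoulli(prior inclusion) and
# theta_j ~ Normal(0, slab_sd^2). The posterior mean of g_j is the posterior
# inclusion probability Pr(Inc); reported coefficients are model-averaged
# (zeros included), so unimportant terms shrink towards zero.

#' Posterior odds ratio of inclusion
#'
#' `[p/(1-p)] / [p0/(1-p0)]`: the posterior inclusion odds divided by the
#' prior inclusion odds. With the uninformative prior `p0 = 0.5`, a posterior
#' inclusion probability of 0.75 gives a ratio of exactly 3, the conventional
#' importance cut-off.
#'
#' @param p Posterior inclusion probability.
#' @param p0 Prior inclusion probability (default 0.5).
#' @return The odds ratio; `Inf` (p = 1) or 0 (p = 0) carry attribute
#'   `boundary = TRUE` instead of raising an error.
#' @export
posterior_odds_ratio <- function(p, p0 = 0.5) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0,1)", call. = FALSE)
  if (p < 0 || p > 1) stop("p must be in [0,1]", call. = FALSE)
  prior_odds <- p0 / (1 - p0)
  if (p == 0 || p == 1) {
    out <- if (p == 1) Inf else 0
    attr(out, "boundary") <- TRUE
    return(out)
  }
  (p / (1 - p)) / prior_odds
}

#' Expand three predictors into a full-interaction design
#'
#' Builds the seven-term design of a full three-way interaction model: the
#' three main effects, the three pairwise products and the triple product.
#' Products are formed on the transformed+standardized scale of the input
#' columns and the whole design is then re-standardized, so all seven columns
#' are again mean 0 / SD 1.
#'
#' @param Z Standardized design matrix containing the three named columns.
#' @param terms Character vector of the three main-effect columns (default
#'   C:E ratio, flushing time, percent fertilized).
#' @return A standardized `design_matrix` with 7 columns; interaction columns
#'   are named `a:b` and `a:b:c`.
#' @export
build_interaction_design <- function(Z, terms = c("ce_ratio", "tf",
                                                  "pct_fertilized")) {
  Z <- as.matrix(Z)
  if (length(terms) != 3) stop("exactly three main-effect terms required",
                               call. = FALSE)
  miss <- setdiff(terms, colnames(Z))
  if (length(miss)) stop("missing column '", miss[1], "'", call. = FALSE)
  a <- Z[, terms[1]]; b <- Z[, terms[2]]; c <- Z[, terms[3]]
  X <- cbind(a, b, c, a * b, a * c, b * c, a * b * c)
  colnames(X) <- c(terms,
                   paste(terms[1], terms[2], sep = ":"),
                   paste(terms[1], terms[3], sep = ":"),
                   paste(terms[2], terms[3], sep = ":"),
                   paste(terms, collapse = ":"))
  standardize(X)
}

# Effective sample size by truncated autocorrelation sum (initial positive
# sequence); conservative but adequate for reporting.
.ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

# One Gibbs chain. sigma == NULL -> residual SD sampled (random-walk
# Metropolis on log sigma, Half-Normal(0, sigma_prior_sd) prior); a fixed
# numeric sigma makes the sampler fully conjugate (used for exact
# cross-checks against model enumeration).
.ssvs_chain <- function(y, Z, prior_inclusion, slab_sd, n_iter, burn_in,
                        seed, intercept, sigma, sigma_prior_sd,
                        intercept_prior_sd) {
  set.seed(seed)
  n <- length(y); k <- ncol(Z)
  zz <- colSums(Z^2)
  fixed_sigma <- !is.null(sigma)
  sig <- if (fixed_sigma) sigma else max(stats::sd(y), 1e-3)
  g <- stats::rbinom(k, 1, prior_inclusion)
  theta <- stats::rnorm(k, 0, slab_sd)
  b0 <- 0
  resid <- y - b0 - drop(Z %*% (g * theta))
  keep <- n_iter - burn_in
  out_g <- matrix(NA_real_, keep, k)
  out_beta <- matrix(NA_real_, keep, k)
  out_extra <- matrix(NA_real_, keep, 2,
                      dimnames = list(NULL, c("intercept", "sigma")))
  log_prior_odds <- log(prior_inclusion / (1 - prior_inclusion))
  step_s <- 0.3; acc_s <- 0L; win <- 50L

  for (it in seq_len(n_iter)) {
    for (j in seq_len(k)) {
      zj <- Z[, j]
      rj <- resid + (g[j] * theta[j]) * zj
      # theta_j | g_j, rest
      if (g[j] == 1L) {
        v <- 1 / (zz[j] / sig^2 + 1 / slab_sd^2)
        m <- v * sum(zj * rj) / sig^2
        theta[j] <- stats::rnorm(1, m, sqrt(v))
      } else {
        theta[j] <- stats::rnorm(1, 0, slab_sd)
      }
      # g_j | theta_j, rest
      ssr0 <- sum(rj^2)
      ssr1 <- sum((rj - theta[j] * zj)^2)
      logodds <- log_prior_odds - (ssr1 - ssr0) / (2 * sig^2)
      g[j] <- as.integer(stats::runif(1) < stats::plogis(logodds))
      resid <- rj - (g[j] * theta[j]) * zj
    }
    if (intercept) {
      r0 <- resid + b0
      v <- 1 / (n / sig^2 + 1 / intercept_prior_sd^2)
      m <- v * sum(r0) / sig^2
      b0 <- stats::rnorm(1, m, sqrt(v))
      resid <- r0 - b0
    }
    if (!fixed_sigma) {
      ssr <- sum(resid^2)
      ls_prop <- log(sig) + stats::rnorm(1, 0, step_s)
      sig_prop <- exp(ls_prop)
      # half-normal prior + log-scale Jacobian
      lpost <- function(s) -n * log(s) - ssr / (2 * s^2) -
        s^2 / (2 * sigma_prior_sd^2) + log(s)
      if (log(stats::runif(1)) < lpost(sig_prop) - lpost(sig)) {
        sig <- sig_prop; acc_s <- acc_s + 1L
      }
      if (it <= burn_in && it %% win == 0L) {
        rate <- acc_s / win
        if (rate < 0.3) step_s <- step_s * 0.8
        if (rate > 0.5) step_s <- step_s * 1.25
        acc_s <- 0L
      }
    }
    if (it > burn_in) {
      i <- it - burn_in
      out_g[i, ] <- g
      out_beta[i, ] <- g * theta
      out_extra[i, ] <- c(b0, sig)
    }
  }
  list(g = out_g, beta = out_beta, extra = out_extra)
}

#' Fit spike-and-slab stochastic-search variable selection
#'
#' Gibbs sampling for the linear model
#' `y_i ~ Normal(b0 + sum_j g_j theta_j z_ij, sigma)` with
#' `g_j ~ Bernoulli(prior_inclusion)` and `theta_j ~ Normal(0, slab_sd^2)`.
#' Slab coefficients are also refreshed from their prior while excluded,
#' which keeps the indicator chain mixing. Per term the fit reports the
#' posterior inclusion probability, the model-averaged coefficient mean and
#' SD (zeros from excluded draws included), the posterior odds ratio against
#' the prior odds, and the importance flag (`Pr(Inc) >= 0.75`, equivalently
#' posterior odds ratio >= 3 under the default prior).
#'
#' @param y Response vector.
#' @param Z Standardized design matrix (see [standardize()]).
#' @param prior_inclusion Prior inclusion probability per term (default 0.5).
#' @param slab_sd Prior SD of an included coefficient on the standardized
#'   scale (default 1).
#' @param n_iter,burn_in Iterations and burn-in per chain (defaults 12000 /
#'   5000).
#' @param n_chains Number of chains (default 3).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`, so chains given
#'   the same seed produce identical draws.
#' @param intercept Include an intercept with Normal(0, `intercept_prior_sd`)
#'   prior (default `TRUE`).
#' @param sigma Fixed residual SD; `NULL` (default) samples it under a
#'   Half-Normal(0, `sigma_prior_sd`) prior.
#' @param sigma_prior_sd,intercept_prior_sd Prior scales (defaults 1 and 10).
#' @return Object of class `ssvs_fit` with `table` (term, `pr_inc`, `beta`,
#'   `sd_beta`, `post_odds_ratio`, `important`), `diagnostics` (R-hat and
#'   effective sample size per tracked quantity), per-chain `draws`, and a
#'   `settings` snapshot.
#' @export
fit_ssvs <- function(y, Z, prior_inclusion = 0.5, slab_sd = 1,
                     n_iter = 12000, burn_in = 5000, n_chains = 3, seed = 1,
                     intercept = TRUE, sigma = NULL, sigma_prior_sd = 1,
                     intercept_prior_sd = 10) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(y)) stop("rows(Z) must equal length(y)",
                                 call. = FALSE)
  if (length(y) < ncol(Z) + 2) {
    stop("need at least #predictors + 2 observations", call. = FALSE)
  }
  if (n_iter <= burn_in) {
    stop("configuration error: n_iter must exceed burn_in", call. = FALSE)
  }
  if (prior_inclusion <= 0 || prior_inclusion >= 1) {
    stop("prior_inclusion must be in (0,1)", call. = FALSE)
  }
  if (qr(Z)$rank < ncol(Z)) {
    warning("design matrix is rank-deficient; the Bayesian model remains proper but coefficients are not separately identified")
  }
  chains <- lapply(seq_len(n_chains), function(cc) {
    .ssvs_chain(y, Z, prior_inclusion, slab_sd, n_iter, burn_in,
                seed + cc - 1L, intercept, sigma, sigma_prior_sd,
                intercept_prior_sd)
  })
  g_all <- do.call(rbind, lapply(chains, `[[`, "g"))
  beta_all <- do.call(rbind, lapply(chains, `[[`, "beta"))
  terms <- colnames(Z)
  if (is.null(terms)) terms <- paste0("x", seq_len(ncol(Z)))
  pr_inc <- colMeans(g_all)
  beta_mean <- colMeans(beta_all)
  beta_sd <- apply(beta_all, 2, stats::sd)
  por <- vapply(pr_inc, function(p) {
    as.numeric(posterior_odds_ratio(p, prior_inclusion))
  }, numeric(1))
  tab <- data.frame(term = terms, pr_inc = pr_inc, beta = beta_mean,
                    sd_beta = beta_sd, post_odds_ratio = por,
                    important = pr_inc >= 0.75, row.names = NULL)
  diag_df <- if (n_chains >= 2) {
    q <- c(stats::setNames(seq_len(ncol(Z)), paste0("beta_", terms)),
           intercept = -1L, sigma = -2L)
    data.frame(
      quantity = names(q),
      rhat = vapply(q, function(j) {
        mat <- vapply(chains, function(ch) {
          if (j > 0) ch$beta[, j]
          else ch$extra[, if (j == -1L) "intercept" else "sigma"]
        }, numeric(nrow(chains[[1]]$beta)))
        gelman_rubin(mat)
      }, numeric(1)),
      ess = vapply(q, function(j) {
        x <- if (j > 0) beta_all[, j] else {
          do.call(rbind, lapply(chains, `[[`, "extra"))[
            , if (j == -1L) "intercept" else "sigma"]
        }
        .ess(x)
      }, numeric(1)),
      row.names = NULL
    )
  } else NULL
  structure(list(
    table = tab, diagnostics = diag_df, draws = chains,
    settings = list(prior_inclusion = prior_inclusion, slab_sd = slab_sd,
                    n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                    seed = seed, intercept = intercept, sigma = sigma,
                    sigma_prior_sd = sigma_prior_sd,
                    intercept_prior_sd = intercept_prior_sd)
  ), class = "ssvs_fit")
}

#' @export
print.ssvs_fit <- function(x, digits = 3, ...) {
  cat("Stochastic-search variable selection (spike-and-slab)\n")
  cat(sprintf("%d chains x %d iterations (%d burn-in), prior inclusion %.2f\n",
              x$settings$n_chains, x$settings$n_iter, x$settings$burn_in,
              x$settings$prior_inclusion))
  tab <- x$table
  tab[, 2:5] <- round(tab[, 2:5], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
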