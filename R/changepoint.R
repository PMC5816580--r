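# Bayesian piecewise change-point regression of MA:TV on percent catchment
# fertilization F. The mean function switches at a change-point gamma:
# below it MA:TV rises linearly from zero with slope beta1; at and above it
# the line jumps to an intercept alpha with slope beta2. Indicator delta(u)
# is 1 for u >= 0, so at F == gamma both branches contribute.

#' Piecewise mean of the change-point model
#'
#' Evaluates
#' `mu = alpha * d(F - gamma) + beta1 * d(gamma - F) * F + beta2 * d(F - gamma) * F`
#' where `d(u) = 1` if `u >= 0`, else 0. Note that at `F == gamma` exactly,
#' both indicators equal 1 and the two slope terms are summed; this literal
#' evaluation is intentional.
#'
#' @param F Percent catchment fertilization, in \[0, 100\] (vectorized).
#' @param params Named list or vector with `alpha`, `beta1`, `beta2`, `gamma`.
#' @return Numeric vector of means (MA:TV units).
#' @export
piecewise_mean <- function(F, params) {
  p <- as.list(params)
  above <- as.numeric(F - p$gamma >= 0)
  below <- as.numeric(p$gamma - F >= 0)
  p$alpha * above + p$beta1 * below * F + p$beta2 * above * F
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `sqrt(((n - 1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B` the between-chain variance of the chain
#' means (times n). Values near 1 indicate that independent chains have
#' converged to the same distribution.
#'
#' @param draws Matrix of posterior draws, iterations x chains (at least two
#'   chains of equal length >= 10), or a list of equal-length numeric vectors.
#' @return The R-hat statistic (scalar).
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) {
    len <- lengths(draws)
    if (length(unique(len)) != 1) stop("chains must have equal length",
                                       call. = FALSE)
    draws <- do.call(cbind, draws)
  }
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
  if (n < 10) stop("chains too short for R-hat (need >= 10)", call. = FALSE)
  means <- colMeans(draws)
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Plug-in coefficient of determination
#'
#' `1 - SS_res / SS_tot` for observed `y` against fitted means `mu`.
#'
#' @param y Observed response vector.
#' @param mu Fitted values (same length).
#' @return R-squared; `NA` with a warning if `y` has zero variance.
#' @export
model_r2 <- function(y, mu) {
  if (length(y) != length(mu)) stop("lengths differ", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("response has zero variance; R-squared undefined")
    return(NA_real_)
  }
  1 - sum((y - mu)^2) / ss_tot
}

#' Default priors for the change-point model
#'
#' Coefficients alpha, beta1, beta2 have Normal(0, sd = 2) priors, the
#' change-point gamma a Uniform(0, 100) prior on the raw percent scale, and
#' the residual SD sigma a Half-Normal(0, 1) prior.
#'
#' @param coef_sd SD of the Normal prior on alpha, beta1, beta2.
#' @param gamma_lower,gamma_upper Support of the Uniform prior on gamma.
#' @param sigma_sd Scale of the Half-Normal prior on sigma.
#' @return Named list of prior settings.
#' @export
changepoint_priors <- function(coef_sd = 2, gamma_lower = 0,
                               gamma_upper = 100, sigma_sd = 1) {
  stopifnot(coef_sd > 0, sigma_sd > 0, gamma_upper > gamma_lower)
  list(coef_sd = coef_sd, gamma_lower = gamma_lower,
       gamma_upper = gamma_upper, sigma_sd = sigma_sd)
}

# Design matrix of the piecewise model at a given change-point.
.cp_design <- function(F, gamma) {
  above <- as.numeric(F - gamma >= 0)
  below <- as.numeric(gamma - F >= 0)
  cbind(above, below * F, above * F)
}

.cp_loglik <- function(y, F, b, gamma, sigma) {
  mu <- .cp_design(F, gamma) %*% b
  sum(stats::dnorm(y, mu, sigma, log = TRUE))
}

# One chain of the Metropolis-within-Gibbs sampler. Coefficients are updated
# by their conjugate multivariate-normal conditional; gamma and log(sigma) by
# random-walk Metropolis with step sizes adapted during burn-in (target
# acceptance 0.3-0.5) and frozen afterwards.
.cp_chain <- function(y, F, priors, n_iter, burn_in, gamma_init, seed,
                      prior_only = FALSE) {
  set.seed(seed)
  n <- length(y)
  b <- c(0, 0, 0)
  gamma <- gamma_init
  sigma <- max(stats::sd(y), 0.05)
  if (prior_only) sigma <- 1
  step_g <- (priors$gamma_upper - priors$gamma_lower) / 10
  step_s <- 0.3
  acc_g <- acc_s <- 0L
  win <- 50L
  keep <- n_iter - burn_in
  out <- matrix(NA_real_, keep, 5,
                dimnames = list(NULL, c("alpha", "beta1", "beta2", "gamma",
                                        "sigma")))
  prior_prec <- diag(3) / priors$coef_sd^2
  ll_cur <- if (prior_only) 0 else .cp_loglik(y, F, b, gamma, sigma)

  for (it in seq_len(n_iter)) {
    # coefficients | gamma, sigma (conjugate)
    if (prior_only) {
      b <- stats::rnorm(3, 0, priors$coef_sd)
    } else {
      X <- .cp_design(F, gamma)
      prec <- crossprod(X) / sigma^2 + prior_prec
      ch <- chol(prec)
      mn <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y) / sigma^2))
      b <- drop(mn + backsolve(ch, stats::rnorm(3)))
      ll_cur <- .cp_loglik(y, F, b, gamma, sigma)
    }

    # gamma | rest (random-walk Metropolis, uniform prior)
    gamma_prop <- gamma + stats::rnorm(1, 0, step_g)
    if (gamma_prop > priors$gamma_lower && gamma_prop < priors$gamma_upper) {
      ll_prop <- if (prior_only) 0 else
        .cp_loglik(y, F, b, gamma_prop, sigma)
      if (log(stats::runif(1)) < ll_prop - ll_cur) {
        gamma <- gamma_prop; ll_cur <- ll_prop; acc_g <- acc_g + 1L
      }
    }

    # sigma | rest (random-walk Metropolis on log sigma, half-normal prior;
    # the log-scale move carries a Jacobian term log(sigma_prop/sigma))
    ls_prop <- log(sigma) + stats::rnorm(1, 0, step_s)
    sigma_prop <- exp(ls_prop)
    lp <- function(s) -s^2 / (2 * priors$sigma_sd^2) + log(s)
    ll_prop <- if (prior_only) 0 else .cp_loglik(y, F, b, gamma, sigma_prop)
    if (log(stats::runif(1)) < ll_prop - ll_cur + lp(sigma_prop) - lp(sigma)) {
      sigma <- sigma_prop; ll_cur <- ll_prop; acc_s <- acc_s + 1L
    }

    # step-size adaptation during burn-in
    if (it <= burn_in && it %% win == 0L) {
      rate_g <- acc_g / win; rate_s <- acc_s / win
      if (rate_g < 0.3) step_g <- step_g * 0.8
      if (rate_g > 0.5) step_g <- step_g * 1.25
      if (rate_s < 0.3) step_s <- step_s * 0.8
      if (rate_s > 0.5) step_s <- step_s * 1.25
      acc_g <- acc_s <- 0L
    }
    if (it > burn_in) out[it - burn_in, ] <- c(b, gamma, sigma)
  }
  out
}

#' Fit the Bayesian piecewise change-point regression
#'
#' Samples the posterior of `(alpha, beta1, beta2, gamma, sigma)` for the
#' model `y_i ~ Normal(mu_i, sigma)` with [piecewise_mean()] as `mu`, by
#' Metropolis-within-Gibbs: conjugate draws for the three coefficients,
#' adaptive random-walk Metropolis for the change-point and the residual SD.
#' Chains start from dispersed change-point values (prior quartiles).
#' Fertilization enters on the raw percent (0-100) scale.
#'
#' @param y MA:TV response vector (values in \[0, 1\]).
#' @param F Percent catchment fertilization vector, same length.
#' @param priors Prior settings from [changepoint_priors()].
#' @param n_iter Total iterations per chain (default 12000).
#' @param burn_in Discarded initial iterations per chain (default 5000).
#' @param n_chains Number of independent chains (default 3; at least 2 so the
#'   Gelman-Rubin diagnostic is defined).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param prior_only If `TRUE`, the likelihood is disabled and the sampler
#'   targets the prior (used to validate the MCMC machinery).
#' @return Object of class `changepoint_fit`: `draws` (list of per-chain
#'   matrices), `summary` (data frame of posterior mean, SD, 2.5%/97.5%
#'   quantiles and R-hat per parameter), `r2` (plug-in R-squared at the
#'   posterior-mean parameters), and a `settings` snapshot.
#' @export
fit_changepoint <- function(y, F, priors = changepoint_priors(),
                            n_iter = 12000, burn_in = 5000, n_chains = 3,
                            seed = 1, prior_only = FALSE) {
  if (length(y) != length(F)) stop("y and F lengths differ", call. = FALSE)
  if (!prior_only && length(y) < 5) stop("need at least 5 observations",
                                         call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(F))) {
    stop("non-finite values in y or F", call. = FALSE)
  }
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in", call. = FALSE)
  if (n_chains < 2) {
    stop("configuration error: at least 2 chains are required for the Gelman-Rubin diagnostic",
         call. = FALSE)
  }
  rng <- priors$gamma_upper - priors$gamma_lower
  inits <- priors$gamma_lower + rng *
    (seq_len(n_chains) / (n_chains + 1))
  interior <- F > priors$gamma_lower & F < priors$gamma_upper
  if (!prior_only && length(unique(F[interior])) < 2) {
    warning("little variation of F inside the change-point prior support")
  }
  chains <- lapply(seq_len(n_chains), function(cc) {
    .cp_chain(y, F, priors, n_iter, burn_in, inits[cc], seed + cc - 1L,
              prior_only = prior_only)
  })
  pooled <- do.call(rbind, chains)
  pars <- colnames(pooled)
  summ <- data.frame(
    parameter = pars,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, stats::quantile, 0.025),
    q97.5 = apply(pooled, 2, stats::quantile, 0.975),
    rhat = vapply(pars, function(p) {
      gelman_rubin(vapply(chains, function(ch) ch[, p],
                          numeric(nrow(chains[[1]]))))
    }, numeric(1)),
    row.names = NULL
  )
  pm <- stats::setNames(summ$mean, summ$parameter)
  r2 <- if (prior_only) NA_real_ else
    model_r2(y, piecewise_mean(F, as.list(pm)))
  structure(list(
    draws = chains, summary = summ, r2 = r2,
    settings = list(n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                    seed = seed, priors = priors, prior_only = prior_only)
  ), class = "changepoint_fit")
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat("Bayesian piecewise change-point regression\n")
  cat(sprintf("%d chains x %d iterations (%d burn-in)\n",
              x$settings$n_chains, x$settings$n_iter, x$settings$burn_in))
  s <- x$summary
  s[, -1] <- round(s[, -1], 4)
  print(s, row.names = FALSE)
  if (!is.na(x$r2)) cat(sprintf("Plug-in R-squared: %.3f\n", x$r2))
  invisible(x)
}
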