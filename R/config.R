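# Analysis configuration: one object collecting every tunable constant, so a
# full run is reproducible from the config plus a seed.

#' Build an analysis configuration
#'
#' Defaults encode the canonical analysis settings: collinearity screening at
#' `|r| > 0.7`, natural-log transform of the right-skewed predictors,
#' standardization to mean 0 / SD 1, 12000 MCMC iterations with 5000 burn-in
#' over 3 chains, an uninformative 0.5 prior inclusion probability,
#' Normal(0, sd 2) coefficient priors and a Uniform(0, 100) change-point
#' prior, and quartile (0.25) export groups.
#'
#' @param screening_threshold Absolute pairwise correlation above which
#'   predictors are considered collinear.
#' @param skew_threshold Sample-skewness cut-off for auto log-transform mode.
#' @param log_columns Columns log-transformed in the default explicit mode.
#' @param log_offset Use `log1p` for zero-containing columns.
#' @param n_iter,burn_in,n_chains,seed MCMC settings shared by the variable
#'   selection and change-point samplers.
#' @param prior_inclusion Prior inclusion probability per SSVS term.
#' @param slab_sd SSVS slab SD on the standardized scale.
#' @param coef_sd Change-point coefficient prior SD.
#' @param gamma_lower,gamma_upper Change-point prior support (% fertilized).
#' @param sigma_sd Half-Normal scale of the residual-SD prior.
#' @param quartile_fraction Export-group fraction.
#' @param rhat Compute Gelman-Rubin diagnostics (requires >= 2 chains).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(screening_threshold = 0.7, skew_threshold = 1,
                            log_columns = DEFAULT_LOG_COLUMNS,
                            log_offset = FALSE,
                            n_iter = 12000, burn_in = 5000, n_chains = 3,
                            seed = 1, prior_inclusion = 0.5, slab_sd = 1,
                            coef_sd = 2, gamma_lower = 0, gamma_upper = 100,
                            sigma_sd = 1, quartile_fraction = 0.25,
                            rhat = TRUE) {
  if (screening_threshold <= 0 || screening_threshold >= 1) {
    stop("configuration error: screening_threshold must be in (0,1)",
         call. = FALSE)
  }
  if (!(n_iter > burn_in && burn_in >= 0)) {
    stop("configuration error: need n_iter > burn_in >= 0", call. = FALSE)
  }
  if (rhat && n_chains < 2) {
    stop("configuration error: Gelman-Rubin diagnostics require >= 2 chains",
         call. = FALSE)
  }
  if (quartile_fraction <= 0 || quartile_fraction > 0.5) {
    stop("configuration error: quartile_fraction must be in (0, 0.5]",
         call. = FALSE)
  }
  structure(list(
    screening_threshold = screening_threshold,
    skew_threshold = skew_threshold, log_columns = log_columns,
    log_offset = log_offset,
    mcmc = list(n_iter = n_iter, burn_in = burn_in, n_chains = n_chains,
                seed = as.integer(seed)),
    priors = list(prior_inclusion = prior_inclusion, slab_sd = slab_sd,
                  coef_sd = coef_sd, gamma_lower = gamma_lower,
                  gamma_upper = gamma_upper, sigma_sd = sigma_sd),
    quartile_fraction = quartile_fraction, rhat = rhat
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys mirror the arguments of [analysis_config()]; absent keys keep their
#' defaults. A `synthetic:` block (keys of [synthetic_spec()]) is passed
#' through unchanged for use by the simulation entry point.
#'
#' @param path YAML file path.
#' @return An `analysis_config`, with any `synthetic` block attached as an
#'   attribute.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  synth <- raw$synthetic
  raw$synthetic <- NULL
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("configuration error: unknown key '", unknown[1], "'",
         call. = FALSE)
  }
  cfg <- do.call(analysis_config, raw)
  attr(cfg, "synthetic") <- synth
  cfg
}
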