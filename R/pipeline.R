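# End-to-end orchestration: screening -> transformation -> variable selection
# -> hierarchical partitioning -> interaction model -> change-point
# regression, from one configuration and one seed. Per-stage seeds are fixed
# offsets of the global seed so stages are reproducible independently.

.stage_seed <- function(seed, stage) {
  seed + c(ssvs = 11L, interaction = 23L, changepoint = 37L)[[stage]]
}

#' Run the full land-use / benthic-vegetation analysis
#'
#' Executes the analysis stages in order on a per-estuary table:
#' collinearity screening and transformation of the candidate predictors,
#' spike-and-slab variable selection, hierarchical partitioning, the
#' three-way interaction model (C:E ratio x flushing time x % fertilized,
#' run whenever those columns survive screening), and the piecewise
#' change-point regression of MA:TV on the raw percent-fertilized scale.
#' Convergence failures (any R-hat above `rhat_limit`) are flagged in the
#' report rather than truncating it.
#'
#' @param df An `estuary_table` (from [read_estuary_table()] or
#'   [generate_dataset()]).
#' @param config An [analysis_config()].
#' @param input_path Optional path of the source CSV, recorded (with an MD5
#'   hash) for provenance.
#' @param rhat_limit Convergence flag threshold (default 1.05).
#' @return Object of class `mativ_report` with elements `provenance`,
#'   `screening`, `ssvs`, `hierpart`, `interaction` (or `NULL`),
#'   `changepoint`, `convergence` (flags), and `settings`.
#' @export
run_full_analysis <- function(df, config = analysis_config(),
                              input_path = NULL, rhat_limit = 1.05) {
  stopifnot(inherits(config, "analysis_config"))
  validate_estuary_table(df)
  seed <- config$mcmc$seed
  stage <- "preprocess"
  report <- list()
  report$provenance <- list(
    rows = nrow(df),
    input_path = input_path,
    input_md5 = if (!is.null(input_path)) unname(tools::md5sum(input_path))
                else NA_character_,
    seed = seed
  )
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  prep <- run("preprocess", preprocess_estuary_table(
    df, threshold = config$screening_threshold,
    log_columns = config$log_columns, offset = config$log_offset))
  report$screening <- prep$screening

  report$ssvs <- run("ssvs", fit_ssvs(
    prep$y, prep$Z, prior_inclusion = config$priors$prior_inclusion,
    slab_sd = config$priors$slab_sd, n_iter = config$mcmc$n_iter,
    burn_in = config$mcmc$burn_in, n_chains = config$mcmc$n_chains,
    seed = .stage_seed(seed, "ssvs")))

  report$hierpart <- run("hierpart", hier_part(prep$y, prep$Z))

  inter_terms <- c("ce_ratio", "tf", "pct_fertilized")
  report$interaction <- if (all(inter_terms %in% colnames(prep$Z))) {
    run("interaction", {
      Zi <- build_interaction_design(prep$Z, inter_terms)
      list(ssvs = fit_ssvs(
             prep$y, Zi, prior_inclusion = config$priors$prior_inclusion,
             slab_sd = config$priors$slab_sd, n_iter = config$mcmc$n_iter,
             burn_in = config$mcmc$burn_in, n_chains = config$mcmc$n_chains,
             seed = .stage_seed(seed, "interaction")),
           hierpart = hier_part(prep$y, Zi))
    })
  } else NULL

  report$changepoint <- run("changepoint", fit_changepoint(
    df$mativ, df$pct_fertilized,
    priors = changepoint_priors(
      coef_sd = config$priors$coef_sd,
      gamma_lower = config$priors$gamma_lower,
      gamma_upper = config$priors$gamma_upper,
      sigma_sd = config$priors$sigma_sd),
    n_iter = config$mcmc$n_iter, burn_in = config$mcmc$burn_in,
    n_chains = config$mcmc$n_chains,
    seed = .stage_seed(seed, "changepoint")))

  rhats <- c(
    stats::setNames(report$ssvs$diagnostics$rhat,
                    paste0("ssvs_", report$ssvs$diagnostics$quantity)),
    stats::setNames(report$changepoint$summary$rhat,
                    paste0("cp_", report$changepoint$summary$parameter))
  )
  report$convergence <- list(rhat_limit = rhat_limit, rhat = rhats,
                             converged = all(rhats <= rhat_limit))
  report$settings <- config
  class(report) <- "mativ_report"
  report
}

#' @export
print.mativ_report <- function(x, ...) {
  cat("== Land-use / benthic-vegetation analysis report ==\n")
  cat(sprintf("%d estuaries (seed %d)\n\n", x$provenance$rows,
              x$provenance$seed))
  print(x$screening); cat("\n")
  print(x$ssvs); cat("\n")
  print(x$hierpart); cat("\n")
  if (!is.null(x$interaction)) {
    cat("-- Interaction model --\n")
    print(x$interaction$ssvs)
    print(x$interaction$hierpart); cat("\n")
  }
  print(x$changepoint)
  cat(sprintf("\nConvergence: %s (max R-hat %.3f, limit %.2f)\n",
              if (x$convergence$converged) "ok" else "NOT CONVERGED",
              max(x$convergence$rhat), x$convergence$rhat_limit))
  invisible(x)
}

#' Write a run report to a directory as plain-text artifacts
#'
#' Emits `screening.txt`, `ssvs.csv`, `hierpart.csv`, optional
#' `interaction_ssvs.csv` / `interaction_hierpart.csv`,
#' `changepoint_summary.csv`, `changepoint_fitted.csv` (observed vs fitted
#' points for plotting) and `run_log.txt`. The same report always produces
#' byte-identical files.
#'
#' @param report A `mativ_report`.
#' @param dir Output directory (created if needed).
#' @param df The estuary table the report was computed from (used for the
#'   fitted-vs-observed export); optional.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, df = NULL) {
  stopifnot(inherits(report, "mativ_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  writeLines(c("Collinearity screening", report$screening$log),
             file.path(dir, "screening.txt"))
  wcsv(report$ssvs$table, "ssvs.csv")
  wcsv(report$hierpart$table, "hierpart.csv")
  if (!is.null(report$interaction)) {
    wcsv(report$interaction$ssvs$table, "interaction_ssvs.csv")
    wcsv(report$interaction$hierpart$table, "interaction_hierpart.csv")
  }
  wcsv(report$changepoint$summary, "changepoint_summary.csv")
  if (!is.null(df)) {
    pm <- stats::setNames(report$changepoint$summary$mean,
                          report$changepoint$summary$parameter)
    wcsv(data.frame(name = df$name, pct_fertilized = df$pct_fertilized,
                    mativ = df$mativ,
                    fitted = piecewise_mean(df$pct_fertilized, as.list(pm))),
         "changepoint_fitted.csv")
  }
  log <- c(
    sprintf("rows: %d", report$provenance$rows),
    sprintf("input: %s (md5 %s)",
            if (is.null(report$provenance$input_path)) "<in-memory>"
            else report$provenance$input_path,
            report$provenance$input_md5),
    sprintf("seed: %d", report$provenance$seed),
    sprintf("mcmc: %d iterations, %d burn-in, %d chains",
            report$settings$mcmc$n_iter, report$settings$mcmc$burn_in,
            report$settings$mcmc$n_chains),
    sprintf("screening threshold: %g", report$settings$screening_threshold),
    sprintf("changepoint R2: %.4f", report$changepoint$r2),
    sprintf("converged: %s (max R-hat %.4f)", report$convergence$converged,
            max(report$convergence$rhat))
  )
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
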