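# Predictor screening and transformation: collinearity elimination at
# |r| > 0.7, natural-log transform of right-skewed predictors, and
# standardization to mean 0 / SD 1 (the scale on which variable selection is
# run).

.as_predictor_matrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (!is.numeric(X)) stop("predictor matrix must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

#' Pairwise Pearson correlations among predictors
#'
#' @param X Numeric matrix or data frame (rows = estuaries, columns =
#'   predictors), at least 3 rows, no constant column.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(X) {
  X <- .as_predictor_matrix(X)
  if (nrow(X) < 3) stop("need at least 3 rows", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate input: constant column '",
         colnames(X)[which(sds == 0)[1]], "'", call. = FALSE)
  }
  stats::cor(X)
}

#' Screen predictors for collinearity
#'
#' Finds inter-correlated sets of predictors as connected components of the
#' graph whose edges join pairs with `|r| > threshold`. Within each such set a
#' single predictor is retained: the one with the lowest sum of absolute
#' correlations with the predictors *outside* the set (ties broken by column
#' order). All other members are dropped. An audit log records each decision.
#'
#' @param corr Correlation matrix from [pairwise_correlations()].
#' @param threshold Absolute-correlation threshold above which a pair is
#'   considered collinear (default 0.7).
#' @return A list of class `screening` with elements `retained`, `dropped`
#'   (character vectors of column names), `components` (list of inter-
#'   correlated sets), and `log` (character vector of decisions).
#' @export
screen_collinearity <- function(corr, threshold = 0.7) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || any(abs(diag(corr) - 1) > 1e-8)) {
    stop("'corr' must be a correlation matrix with unit diagonal",
         call. = FALSE)
  }
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0,1)", call. = FALSE)
  }
  p <- ncol(corr)
  nm <- colnames(corr)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  adj <- abs(corr) > threshold
  diag(adj) <- FALSE

  # connected components by repeated flood fill
  comp <- rep(NA_integer_, p)
  cid <- 0L
  for (i in seq_len(p)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }

  retained <- logical(p)
  log <- character(0)
  components <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) == 1L) {
      retained[members] <- TRUE
      next
    }
    components[[length(components) + 1L]] <- nm[members]
    outside <- setdiff(seq_len(p), members)
    ext_sum <- vapply(members, function(j) {
      if (length(outside) == 0) 0 else sum(abs(corr[j, outside]))
    }, numeric(1))
    keep <- members[which.min(ext_sum)]  # which.min takes first on ties
    retained[keep] <- TRUE
    log <- c(log, sprintf(
      "inter-correlated set {%s}: retained '%s' (external |r| sums: %s)",
      paste(nm[members], collapse = ", "), nm[keep],
      paste(sprintf("%s=%.3f", nm[members], ext_sum), collapse = ", ")))
    for (j in setdiff(members, keep)) {
      log <- c(log, sprintf("dropped '%s' (|r|=%.3f with '%s')",
                            nm[j], abs(corr[j, keep]), nm[keep]))
    }
  }
  if (length(components) == 0) {
    log <- c(log, sprintf("no pairwise |r| > %g; all predictors retained",
                          threshold))
  }
  structure(list(retained = nm[retained], dropped = nm[!retained],
                 components = components, threshold = threshold, log = log),
            class = "screening")
}

#' @export
print.screening <- function(x, ...) {
  cat("Collinearity screening (|r| >", x$threshold, ")\n")
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("Dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

# Default set of predictors taken onto the natural-log scale before
# standardization: the strongly right-skewed ones in a typical land-use table.
DEFAULT_LOG_COLUMNS <- c("ce_ratio", "pct_urbanized", "pct_fertilized",
                         "areal_din_load")

#' Natural-log transform of right-skewed predictors
#'
#' Either an explicit column list is transformed (the default mode), or, with
#' `auto = TRUE`, every column whose adjusted Fisher-Pearson sample skewness
#' exceeds `skew_threshold` is transformed. Columns destined for the log must
#' be strictly positive unless `offset = TRUE`, in which case `log(x + 1)` is
#' used (useful for percentage columns containing zeros).
#'
#' @param X Predictor matrix or data frame.
#' @param columns Character vector of columns to transform; defaults to the
#'   intersection of the canonical skewed set (C:E ratio, % urbanized,
#'   % fertilized, areal DIN load) with the columns present.
#' @param auto If `TRUE`, ignore `columns` and select by sample skewness.
#' @param skew_threshold Skewness cut-off for auto mode (default 1).
#' @param offset Use `log1p` instead of `log` (default `FALSE`).
#' @return Matrix with the named columns transformed and a logical attribute
#'   `log_transformed` flagging them.
#' @export
log_transform_skewed <- function(X, columns = NULL, auto = FALSE,
                                 skew_threshold = 1, offset = FALSE) {
  X <- .as_predictor_matrix(X)
  if (auto) {
    skews <- apply(X, 2, e1071::skewness, type = 2)
    columns <- colnames(X)[!is.na(skews) & skews > skew_threshold]
  } else if (is.null(columns)) {
    columns <- intersect(DEFAULT_LOG_COLUMNS, colnames(X))
  } else {
    miss <- setdiff(columns, colnames(X))
    if (length(miss)) stop("unknown column '", miss[1], "'", call. = FALSE)
  }
  flags <- stats::setNames(colnames(X) %in% columns, colnames(X))
  for (cl in columns) {
    x <- X[, cl]
    if (!offset && any(x <= 0)) {
      stop(sprintf(
        "non-positive value in column '%s' (row %d); use offset = TRUE or drop the column from the log list",
        cl, which(x <= 0)[1]), call. = FALSE)
    }
    X[, cl] <- if (offset) log1p(x) else log(x)
  }
  attr(X, "log_transformed") <- flags
  X
}

#' Standardize predictor columns to mean 0, SD 1
#'
#' Column-wise `(x - mean) / sd` with the sample standard deviation (n-1
#' denominator). The means and SDs used are recorded as attributes `center`
#' and `scale` so coefficients can be mapped back to the original scale.
#'
#' @param X Predictor matrix or data frame; no constant columns.
#' @return Standardized matrix of class `design_matrix`, carrying forward any
#'   `log_transformed` flags and setting `standardized = TRUE`.
#' @export
standardize <- function(X) {
  flags <- attr(X, "log_transformed")
  X <- .as_predictor_matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) {
    stop("degenerate input: constant column '",
         colnames(X)[which(scl == 0)[1]], "'", call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (is.null(flags)) {
    flags <- stats::setNames(rep(FALSE, ncol(X)), colnames(X))
  }
  structure(Z, center = ctr, scale = scl, log_transformed = flags,
            standardized = TRUE, class = c("design_matrix", class(Z)))
}

#' Screen, transform and standardize an estuary table in one call
#'
#' Applies the screening-transformation sequence used throughout the package:
#' pairwise correlations on the raw predictors, collinearity screening at
#' `threshold`, natural-log transform of the configured skewed columns among
#' the retained ones, then standardization.
#'
#' @param df An `estuary_table` (see [read_estuary_table()]).
#' @param threshold Collinearity threshold (default 0.7).
#' @param log_columns Columns to log-transform (defaults as in
#'   [log_transform_skewed()]).
#' @param offset Passed to [log_transform_skewed()].
#' @return List with `Z` (the standardized `design_matrix` of retained
#'   predictors), `screening` (the audit object) and `y` (the MA:TV vector).
#' @export
preprocess_estuary_table <- function(df, threshold = 0.7, log_columns = NULL,
                                     offset = FALSE) {
  pred_cols <- intersect(c(PREDICTOR_COLUMNS, OPTIONAL_PREDICTORS), names(df))
  X <- .as_predictor_matrix(df[, pred_cols, drop = FALSE])
  corr <- pairwise_correlations(X)
  scr <- screen_collinearity(corr, threshold)
  Xr <- X[, scr$retained, drop = FALSE]
  if (is.null(log_columns)) {
    log_columns <- intersect(DEFAULT_LOG_COLUMNS, colnames(Xr))
  } else {
    log_columns <- intersect(log_columns, colnames(Xr))
  }
  Xt <- log_transform_skewed(Xr, columns = log_columns, offset = offset)
  list(Z = standardize(Xt), screening = scr, y = df$mativ)
}
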