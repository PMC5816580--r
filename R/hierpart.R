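# Exact hierarchical partitioning of regression goodness-of-fit: the full
# model's R-squared is decomposed into a non-negative "independent"
# contribution I_j per predictor (the Shapley-weighted average of j's
# incremental R-squared over all predictor subsets) and a "joint" part
# J_j = R2({j}) - I_j, which may be negative under suppression.

# Canonical subset key: sorted indices joined by ",", empty set -> "0".
.subset_key <- function(idx) {
  if (length(idx) == 0) "0" else paste(sort(idx), collapse = ",")
}

#' Ordinary least squares R-squared
#'
#' Coefficient of determination of the OLS fit of `y` on the given predictor
#' columns (with intercept). An empty predictor set returns 0 (the null
#' model).
#'
#' @param y Response vector.
#' @param X Predictor matrix (or `NULL`/zero columns for the null model).
#' @return R-squared in \[0, 1\].
#' @export
ols_r2 <- function(y, X = NULL) {
  if (is.null(X) || NCOL(X) == 0 || length(X) == 0) return(0)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("dimension mismatch", call. = FALSE)
  if (length(y) <= ncol(X)) {
    stop("need more observations than predictors", call. = FALSE)
  }
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("singular design", call. = FALSE)
  fit <- qr.fitted(qrD, y)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("response has zero variance", call. = FALSE)
  1 - sum((y - fit)^2) / ss_tot
}

#' Goodness-of-fit over all predictor subsets
#'
#' Computes [ols_r2()] for every subset of the columns of `Z` (2^k fits).
#'
#' @param y Response vector.
#' @param Z Predictor matrix with `k <= max_k` columns.
#' @param max_k Guard on the exponential enumeration (default 13).
#' @return Named numeric vector keyed by canonical sorted-index strings
#'   ("0" for the empty set, "1,3" for columns 1 and 3, ...), with attributes
#'   `k` and `predictors`.
#' @export
all_subsets_gof <- function(y, Z, max_k = 13) {
  Z <- as.matrix(Z)
  k <- ncol(Z)
  if (k > max_k) {
    stop(sprintf(
      "resource error: %d predictors imply %.0f subsets; reduce the predictor set or raise max_k",
      k, 2^k), call. = FALSE)
  }
  n_sub <- 2^k
  out <- numeric(n_sub)
  keys <- character(n_sub)
  for (s in seq_len(n_sub) - 1L) {
    idx <- which(bitwAnd(s, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    keys[s + 1L] <- .subset_key(idx)
    out[s + 1L] <- ols_r2(y, Z[, idx, drop = FALSE])
  }
  names(out) <- keys
  attr(out, "k") <- k
  attr(out, "predictors") <- colnames(Z)
  out
}

#' Hierarchical partitioning from a complete subset goodness-of-fit map
#'
#' For each predictor `j`,
#' `I_j = sum over subsets S not containing j of w(|S|) * (R2(S + j) - R2(S))`
#' with Shapley weights `w(s) = s! (k - s - 1)! / k!`; equivalently, the mean
#' over all k! predictor orderings of j's incremental R-squared. The joint
#' contribution is `J_j = R2({j}) - I_j`. The decomposition conserves the
#' full-model fit: `sum_j (I_j + J_j) = R2(full)`.
#'
#' @param gof Output of [all_subsets_gof()] (a complete 2^k map).
#' @param k Number of predictors; defaults to the map's `k` attribute.
#' @return Object of class `hierpart`: `table` (predictor, `independent`,
#'   `joint`, `pct_indep`) and `r2_full`.
#' @export
hierarchical_partition <- function(gof, k = attr(gof, "k")) {
  if (is.null(k)) stop("k not supplied and not recorded on 'gof'",
                       call. = FALSE)
  idx_all <- seq_len(k)
  expected <- vapply(seq_len(2^k) - 1L, function(s) {
    .subset_key(which(bitwAnd(s, bitwShiftL(1L, idx_all - 1L)) > 0L))
  }, character(1))
  miss <- setdiff(expected, names(gof))
  if (length(miss)) {
    stop("incomplete subset map; missing: ",
         paste(utils::head(miss, 5), collapse = " | "), call. = FALSE)
  }
  w <- factorial(seq_len(k) - 1) * factorial(k - seq_len(k)) / factorial(k)
  # w[s+1] is the weight for |S| = s
  I <- numeric(k)
  for (j in idx_all) {
    others <- setdiff(idx_all, j)
    for (s in seq_len(2^(k - 1)) - 1L) {
      S <- others[bitwAnd(s, bitwShiftL(1L, seq_along(others) - 1L)) > 0L]
      inc <- gof[[.subset_key(c(S, j))]] - gof[[.subset_key(S)]]
      I[j] <- I[j] + w[length(S) + 1L] * inc
    }
  }
  r2_single <- vapply(idx_all, function(j) gof[[.subset_key(j)]], numeric(1))
  J <- r2_single - I
  preds <- attr(gof, "predictors")
  if (is.null(preds)) preds <- paste0("x", idx_all)
  pct <- if (sum(I) > 0) 100 * I / sum(I) else rep(NA_real_, k)
  structure(list(
    table = data.frame(predictor = preds, independent = I, joint = J,
                       pct_indep = pct, row.names = NULL),
    r2_full = unname(gof[[.subset_key(idx_all)]])
  ), class = "hierpart")
}

#' Percent of explained variance independently attributable to each predictor
#'
#' `100 * I_j / sum(I)`, which sums to exactly 100 before any rounding.
#'
#' @param result A `hierpart` object.
#' @return Named numeric vector of percentages.
#' @export
percent_independent <- function(result) {
  stopifnot(inherits(result, "hierpart"))
  I <- result$table$independent
  if (sum(I) <= 0) {
    stop("all independent contributions are zero; percentages undefined",
         call. = FALSE)
  }
  stats::setNames(100 * I / sum(I), result$table$predictor)
}

#' Hierarchical partitioning of a response on a predictor matrix
#'
#' Convenience wrapper running [all_subsets_gof()] then
#' [hierarchical_partition()].
#'
#' @param y Response vector.
#' @param Z Predictor matrix.
#' @param max_k Enumeration guard (default 13).
#' @return A `hierpart` object.
#' @export
hier_part <- function(y, Z, max_k = 13) {
  hierarchical_partition(all_subsets_gof(y, Z, max_k = max_k))
}

#' @export
print.hierpart <- function(x, digits = 3, ...) {
  cat("Hierarchical partitioning of OLS R-squared\n")
  tab <- x$table
  tab[, 2:4] <- round(tab[, 2:4], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Full-model R-squared: %.4f\n", x$r2_full))
  invisible(x)
}
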