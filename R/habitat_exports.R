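# Habitat-side statistics: coverage-weighted habitat areas and the MA:TV
# ratio from gridded habitat classifications, and quartile summaries of
# catchment nutrient-export rates.

HABITAT_CLASSES <- c("seagrass", "macroalgae", "bare", "channel")
VEGETATED_CLASSES <- c("seagrass", "macroalgae")
DENSITY_WEIGHTS <- c(sparse_medium = 0.5, dense = 1.0)

#' Coverage-weighted habitat areas
#'
#' Sums cell areas per habitat class with vegetation-density weighting:
#' sparse/medium coverage counts as 50% vegetation, dense as 100%. For a cell
#' with a single vegetated class, the unvegetated remainder accrues to bare
#' sediment (a 10 m2 medium-seagrass cell contributes 5 m2 seagrass and 5 m2
#' bare). Cells may carry several classes (e.g. seagrass with epiphytic
#' macroalgae); each listed class receives its own weighted area, so class
#' areas of multi-membership cells may overlap and sum to more than the cell
#' area — in that case no bare remainder is added.
#'
#' @param cells Data frame as returned by [read_habitat_table()]: columns
#'   `area_m2`, `classes` (list of class labels per cell) and `densities`
#'   (list of density labels, one per vegetated class, in the same order).
#' @return Named numeric vector of areas (m2) for seagrass, macroalgae, bare
#'   and channel.
#' @export
coverage_weighted_areas <- function(cells) {
  areas <- stats::setNames(numeric(length(HABITAT_CLASSES)), HABITAT_CLASSES)
  for (i in seq_len(nrow(cells))) {
    area <- cells$area_m2[i]
    if (!is.finite(area) || area <= 0) {
      stop("cell ", i, ": area must be > 0", call. = FALSE)
    }
    cls <- cells$classes[[i]]
    dens <- cells$densities[[i]]
    bad <- setdiff(cls, HABITAT_CLASSES)
    if (length(bad)) stop("cell ", i, ": unknown habitat class '", bad[1],
                          "'", call. = FALSE)
    veg <- cls[cls %in% VEGETATED_CLASSES]
    if (length(dens) != length(veg)) {
      stop("cell ", i, ": need one density label per vegetated class",
           call. = FALSE)
    }
    badd <- setdiff(dens, names(DENSITY_WEIGHTS))
    if (length(badd)) stop("cell ", i, ": unknown density label '", badd[1],
                           "'", call. = FALSE)
    vegetated_area <- 0
    di <- 0L
    for (cl in cls) {
      if (cl %in% VEGETATED_CLASSES) {
        di <- di + 1L
        w <- DENSITY_WEIGHTS[[dens[di]]]
        areas[cl] <- areas[cl] + area * w
        vegetated_area <- vegetated_area + area * w
      } else {
        areas[cl] <- areas[cl] + area
      }
    }
    if (length(veg) > 0) {
      areas["bare"] <- areas["bare"] + max(0, area - vegetated_area)
    }
  }
  areas
}

#' Macroalgae-to-total-vegetation ratio
#'
#' `MA:TV = A_macroalgae / (A_macroalgae + A_seagrass)`, the proportion of
#' vegetated area occupied by macroalgae; rises towards 1 as fast-growing
#' macroalgae overgrow seagrass under nutrient enrichment.
#'
#' @param areas Named vector with at least `macroalgae` and `seagrass`
#'   entries (e.g. from [coverage_weighted_areas()]).
#' @return Ratio in \[0, 1\]; `NA` with a warning if both areas are zero.
#' @export
compute_mativ <- function(areas) {
  ma <- areas[["macroalgae"]]
  sg <- areas[["seagrass"]]
  if (ma < 0 || sg < 0) stop("areas must be non-negative", call. = FALSE)
  if (ma + sg == 0) {
    warning("no vegetated area; MA:TV undefined")
    return(NA_real_)
  }
  ma / (ma + sg)
}

#' Quartile summaries of catchment nutrient-export rates
#'
#' Ranks catchments by percent fertilized area and summarises the `k` least-
#' and `k` most-fertilized ones (`k = ceiling(fraction * n)`): mean, minimum
#' and maximum of the TN and NOx export rates per group. Ties in percent
#' fertilized straddling a cut are all included (and the expansion logged in
#' the returned object).
#'
#' @param records An `export_table` (see [read_export_table()]).
#' @param fraction Group fraction (default 0.25, i.e. quartiles).
#' @return List of class `export_summary` with elements `lower` and `upper`,
#'   each holding `systems`, `tn` and `nox` (mean/min/max), plus `k` and
#'   `log`.
#' @export
quartile_export_stats <- function(records, fraction = 0.25) {
  n <- nrow(records)
  if (n < 4) stop("need at least 4 records", call. = FALSE)
  if (fraction <= 0 || fraction > 0.5) {
    stop("fraction must be in (0, 0.5]", call. = FALSE)
  }
  k <- ceiling(fraction * n)
  ord <- order(records$pct_fertilized)
  pf <- records$pct_fertilized
  log <- character(0)

  lower_idx <- ord[seq_len(k)]
  cut_lo <- pf[ord[k]]
  extra <- setdiff(which(pf <= cut_lo), lower_idx)
  if (length(extra)) {
    lower_idx <- c(lower_idx, extra)
    log <- c(log, sprintf("lower group expanded by %d tied record(s) at %g%%",
                          length(extra), cut_lo))
  }
  upper_idx <- ord[seq(n - k + 1, n)]
  cut_hi <- pf[ord[n - k + 1]]
  extra <- setdiff(which(pf >= cut_hi), upper_idx)
  if (length(extra)) {
    upper_idx <- c(upper_idx, extra)
    log <- c(log, sprintf("upper group expanded by %d tied record(s) at %g%%",
                          length(extra), cut_hi))
  }

  summarise <- function(idx, label) {
    list(label = label,
         systems = records$system[idx][order(pf[idx])],
         tn = c(mean = mean(records$tn_export[idx]),
                min = min(records$tn_export[idx]),
                max = max(records$tn_export[idx])),
         nox = c(mean = mean(records$nox_export[idx]),
                 min = min(records$nox_export[idx]),
                 max = max(records$nox_export[idx])))
  }
  structure(list(lower = summarise(lower_idx, "lower"),
                 upper = summarise(upper_idx, "upper"),
                 k = k, fraction = fraction, log = log),
            class = "export_summary")
}

#' @export
print.export_summary <- function(x, ...) {
  show <- function(g) {
    cat(sprintf("%s quartile (%d systems): %s\n", g$label,
                length(g$systems), paste(g$systems, collapse = ", ")))
    cat(sprintf("  TN  mean %.3f (range %.3g-%.3g) kg/ha/yr\n",
                g$tn[["mean"]], g$tn[["min"]], g$tn[["max"]]))
    cat(sprintf("  NOx mean %.3f (range %.3g-%.3g) kg/ha/yr\n",
                g$nox[["mean"]], g$nox[["min"]], g$nox[["max"]]))
  }
  cat("Catchment nutrient-export summary\n")
  show(x$lower); show(x$upper)
  if (length(x$log)) cat(paste0("  note: ", x$log, collapse = "\n"), "\n")
  invisible(x)
}
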