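# Readers, writers and validation for the two tabular inputs: the per-estuary
# survey table (response + candidate predictors) and the per-catchment
# nutrient-export table.

# Canonical predictor columns of an estuary table, in display order.
PREDICTOR_COLUMNS <- c(
  "ce_ratio", "tf", "pop_prop_1", "pct_modified", "pct_urbanized",
  "pct_fertilized", "areal_din_load"
)

# Optional columns that may ride along (e.g. river DIN concentration, kept so
# collinearity screening has something to screen out).
OPTIONAL_PREDICTORS <- c("din_concentration")

#' Human-readable labels for estuary-table columns
#'
#' @return Named character vector mapping canonical column names to the labels
#'   used in reports.
#' @export
predictor_labels <- function() {
  c(
    ce_ratio = "C:E ratio", tf = "Tf", pop_prop_1 = "Pop_Prop_1",
    pct_modified = "% Modified", pct_urbanized = "% Urbanized",
    pct_fertilized = "% Fertilized", areal_din_load = "Areal DIN load",
    din_concentration = "DIN concentration"
  )
}

# Normalize a header: lowercase, strip everything but letters/digits.
.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# Alias table: normalized header -> canonical name.
.estuary_aliases <- function() {
  a <- c(
    name = "name", estuary = "name", system = "name", site = "name",
    mativ = "mativ", matv = "mativ", mativratio = "mativ",
    chlorophyll = "chlorophyll", chl = "chlorophyll", chla = "chlorophyll",
    ceratio = "ce_ratio", ce = "ce_ratio", catchmentestuaryratio = "ce_ratio",
    tf = "tf", flushingtime = "tf", flushingtimedays = "tf",
    popprop1 = "pop_prop_1", popprop = "pop_prop_1",
    modified = "pct_modified", pctmodified = "pct_modified",
    percentmodified = "pct_modified",
    urbanized = "pct_urbanized", pcturbanized = "pct_urbanized",
    percenturbanized = "pct_urbanized",
    fertilized = "pct_fertilized", pctfertilized = "pct_fertilized",
    percentfertilized = "pct_fertilized",
    arealdinload = "areal_din_load", dinload = "areal_din_load",
    dinconcentration = "din_concentration", dinconc = "din_concentration"
  )
  a
}

.read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    strip.white = TRUE),
    error = function(e) {
      stop("format error: cannot parse '", path, "' (",
           conditionMessage(e), ")", call. = FALSE)
    })
  if (nrow(df) == 0L) {
    stop("format error: '", path, "' has no data rows", call. = FALSE)
  }
  df
}

# Coerce a character/numeric column to numeric, rejecting unparseable cells
# (including thousands separators) with row/column context.
.parse_numeric <- function(x, column) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
  if (any(bad)) {
    stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                 x[which(bad)[1]], column, which(bad)[1]), call. = FALSE)
  }
  as.numeric(x)
}

#' Read a per-estuary survey table
#'
#' Reads a CSV with one row per estuary: a name, the MA:TV ratio, optionally a
#' mean chlorophyll-a concentration (ug/L), and the candidate predictors
#' (C:E ratio, flushing time in days, population proportion, % modified,
#' % urbanized, % fertilized, areal DIN load in t km-2 yr-1, optionally the
#' riverine DIN concentration). Header names are matched case-insensitively
#' against common aliases ("% Fertilized", "pct_fertilized", ...).
#'
#' Rows violating the domain invariants (MA:TV outside \[0,1\], percentages
#' outside \[0,100\], non-positive flushing time or C:E ratio, negative DIN
#' load) are rejected with the offending row reported.
#'
#' @param path Path to a CSV file with a header row.
#' @return A validated `data.frame` of class `estuary_table` with canonical
#'   column names.
#' @seealso [write_estuary_table()], [generate_dataset()]
#' @export
read_estuary_table <- function(path) {
  df <- .read_csv_strict(path)
  aliases <- .estuary_aliases()
  norm <- .norm_header(names(df))
  known <- norm %in% names(aliases)
  canon <- ifelse(known, unname(aliases[norm]), names(df))
  if (anyDuplicated(canon[known])) {
    dup <- canon[known][duplicated(canon[known])][1]
    stop("format error: multiple columns map to '", dup, "'", call. = FALSE)
  }
  names(df) <- canon
  if (!"mativ" %in% canon) {
    stop("format error: missing mandatory column 'mativ'", call. = FALSE)
  }
  if (!"name" %in% canon) df$name <- paste0("estuary_", seq_len(nrow(df)))
  num_cols <- intersect(
    c("mativ", "chlorophyll", PREDICTOR_COLUMNS, OPTIONAL_PREDICTORS),
    names(df)
  )
  for (cl in num_cols) df[[cl]] <- .parse_numeric(df[[cl]], cl)
  out <- df[, intersect(c("name", "mativ", "chlorophyll", PREDICTOR_COLUMNS,
                          OPTIONAL_PREDICTORS), names(df)), drop = FALSE]
  validate_estuary_table(out)
  class(out) <- c("estuary_table", "data.frame")
  out
}

#' Validate the invariants of an estuary table
#'
#' @param df Data frame with canonical estuary-table columns.
#' @return The data frame, invisibly, if valid; otherwise an error naming the
#'   first offending row and field.
#' @export
validate_estuary_table <- function(df) {
  check <- function(cond, field) {
    bad <- which(!is.na(cond) & !cond)
    if (length(bad)) {
      stop(sprintf("validation error: row %d violates %s", bad[1], field),
           call. = FALSE)
    }
  }
  if ("mativ" %in% names(df)) {
    check(df$mativ >= 0 & df$mativ <= 1, "mativ in [0,1]")
  }
  for (cl in intersect(c("pct_modified", "pct_urbanized", "pct_fertilized"),
                       names(df))) {
    check(df[[cl]] >= 0 & df[[cl]] <= 100, paste(cl, "in [0,100]"))
  }
  if ("pop_prop_1" %in% names(df)) {
    check(df$pop_prop_1 >= 0 & df$pop_prop_1 <= 1, "pop_prop_1 in [0,1]")
  }
  if ("tf" %in% names(df)) check(df$tf > 0, "tf > 0")
  if ("ce_ratio" %in% names(df)) check(df$ce_ratio > 0, "ce_ratio > 0")
  if ("areal_din_load" %in% names(df)) {
    check(df$areal_din_load >= 0, "areal_din_load >= 0")
  }
  invisible(df)
}

#' Write an estuary table to CSV
#'
#' The written file round-trips through [read_estuary_table()] to identical
#' records (up to floating-point formatting, which uses full precision).
#'
#' @param df An `estuary_table` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estuary_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a catchment nutrient-export table
#'
#' Reads a CSV of per-catchment export rates: river-system name, percent of
#' the catchment fertilized, and annual NOx and total-nitrogen export rates in
#' kg ha-1 yr-1. The fixture shipped with the package
#' (`system.file("extdata", "catchment_exports.csv", package = "mativ")`) covers
#' 15 river systems in south-eastern Australia.
#'
#' @param path Path to a CSV file with columns system, pct_fertilized, nox and
#'   tn (aliases accepted).
#' @return A `data.frame` of class `export_table` with columns `system`,
#'   `pct_fertilized`, `nox_export`, `tn_export`, in file order.
#' @seealso [quartile_export_stats()]
#' @export
read_export_table <- function(path) {
  df <- .read_csv_strict(path)
  aliases <- c(
    system = "system", river = "system", name = "system",
    pctfertilized = "pct_fertilized", fertilized = "pct_fertilized",
    percentfertilized = "pct_fertilized",
    nox = "nox_export", noxexport = "nox_export", din = "nox_export",
    tn = "tn_export", tnexport = "tn_export", totalnitrogen = "tn_export"
  )
  norm <- .norm_header(names(df))
  known <- norm %in% names(aliases)
  names(df)[known] <- unname(aliases[norm[known]])
  need <- c("system", "pct_fertilized", "nox_export", "tn_export")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing mandatory column '", miss[1], "'",
         call. = FALSE)
  }
  for (cl in need[-1]) df[[cl]] <- .parse_numeric(df[[cl]], cl)
  if (any(df$pct_fertilized < 0 | df$pct_fertilized > 100)) {
    stop("validation error: pct_fertilized outside [0,100]", call. = FALSE)
  }
  if (any(df$nox_export < 0) || any(df$tn_export < 0)) {
    stop("validation error: negative export rate", call. = FALSE)
  }
  out <- df[, need]
  class(out) <- c("export_table", "data.frame")
  out
}

#' Path to the packaged catchment-export fixture
#'
#' @return Path of the installed `catchment_exports.csv` fixture (15 Victorian
#'   river systems with % fertilized catchment area and NOx/TN export rates).
#' @export
export_fixture_path <- function() {
  system.file("extdata", "catchment_exports.csv", package = "mativ",
              mustWork = TRUE)
}

#' Read a gridded habitat-classification table
#'
#' Each row is one map cell with its area and one or more habitat classes
#' (`seagrass`, `macroalgae`, `bare`, `channel`); vegetated classes carry a
#' density label (`sparse_medium` or `dense`). Multiple classes/densities are
#' given as semicolon-separated lists in a single cell.
#'
#' @param path CSV with columns `cell_id`, `area_m2`, `classes`, `densities`.
#' @return A data frame with list-columns `classes` and `densities`.
#' @seealso [coverage_weighted_areas()]
#' @export
read_habitat_table <- function(path) {
  df <- .read_csv_strict(path)
  need <- c("cell_id", "area_m2", "classes", "densities")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error: missing mandatory column '", miss[1], "'",
         call. = FALSE)
  }
  df$area_m2 <- .parse_numeric(df$area_m2, "area_m2")
  split_list <- function(x) {
    lapply(strsplit(as.character(x), ";", fixed = TRUE),
           function(v) trimws(v[nzchar(trimws(v))]))
  }
  out <- data.frame(cell_id = df$cell_id, area_m2 = df$area_m2)
  out$classes <- split_list(df$classes)
  out$densities <- split_list(df$densities)
  out
}
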