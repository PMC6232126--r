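# Case-table / gridded-field data model and I/O.
#
# Cases live in a plain data.frame (class "case_table") with a "period"
# attribute, the way surveillance line lists are usually handled; gridded
# daily fields live in a light S3 container (class "gridded_series") holding
# a time x lat x lon array with explicit axes and units.

CASE_REQUIRED_COLS <- c("case_id", "onset_date", "lat", "lon")
CASE_OPTIONAL_COLS <- c("age", "sex", "esr", "anc", "crp", "ggt_elevated",
                        "illness_day", "burst_id")

#' Define a study period
#'
#' @param start,end calendar dates (`Date` or `"YYYY-MM-DD"` strings),
#'   inclusive on both ends.
#' @return an object of class `study_period` with elements `start` and `end`.
#' @examples
#' study_period("2002-01-01", "2017-04-15")
#' @export
study_period <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end))
    stop_kd("study period bounds must be valid dates", class = "validation_error")
  if (start > end)
    stop_kd("study period start (%s) is after end (%s)", start, end,
            class = "validation_error")
  structure(list(start = start, end = end), class = "study_period")
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("<study_period> %s .. %s (%d days)\n",
              x$start, x$end, n_days(x)))
  invisible(x)
}

#' Number of days in a study period
#' @param period a `study_period`.
#' @return integer day count (inclusive of both bounds).
#' @export
n_days <- function(period) {
  as.integer(period$end - period$start) + 1L
}

#' Daily date axis of a study period
#' @param period a `study_period`.
#' @return `Date` vector from start to end.
#' @export
period_dates <- function(period) {
  seq(period$start, period$end, by = "day")
}

#' Construct a validated case table
#'
#' Validates coordinates, dates and covariates, sorts by onset date and
#' attaches the study period. This is the universal input of every analysis
#' stage: one row per disease onset ("first day of fever").
#'
#' @param df a data.frame with columns `case_id`, `onset_date`, `lat`, `lon`
#'   and optionally `age`, `sex`, `esr`, `anc`, `crp`, `ggt_elevated`,
#'   `illness_day`, `burst_id`. Empty strings are treated as missing.
#' @param period a [study_period()]; all onsets must fall inside it.
#' @return a `case_table`: a data.frame sorted by `onset_date` with attribute
#'   `period`.
#' @export
case_table <- function(df, period) {
  stopifnot(inherits(period, "study_period"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CASE_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop_kd("case table is missing required column(s): %s",
            paste(missing_cols, collapse = ", "), class = "schema_error")

  df$case_id <- as.character(df$case_id)
  if (anyDuplicated(df$case_id))
    stop_kd("duplicate case_id(s): %s",
            paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "),
            class = "validation_error")

  df$onset_date <- as.Date(df$onset_date)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)

  bad_date <- is.na(df$onset_date)
  bad_coord <- is.na(df$lat) | is.na(df$lon) |
    df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180
  if (any(bad_date | bad_coord))
    stop_kd("invalid onset_date/coordinates for case_id(s): %s",
            paste(df$case_id[bad_date | bad_coord], collapse = ", "),
            class = "validation_error")

  outside <- df$onset_date < period$start | df$onset_date > period$end
  if (any(outside))
    stop_kd("onset outside study period for case_id(s): %s",
            paste(df$case_id[outside], collapse = ", "),
            class = "validation_error")

  for (col in c("age", "esr", "anc", "crp", "illness_day")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
    df[[col]][df[[col]] == ""] <- NA
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(df$age < 0, na.rm = TRUE))
    stop_kd("negative age for case_id(s): %s",
            paste(df$case_id[!is.na(df$age) & df$age < 0], collapse = ", "),
            class = "validation_error")
  if (!"sex" %in% names(df)) df$sex <- rep("unknown", nrow(df))
  df$sex <- as.character(df$sex)
  df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
  if (!all(df$sex %in% c("M", "F", "unknown")))
    stop_kd("sex must be one of M, F, unknown", class = "validation_error")
  if (!"ggt_elevated" %in% names(df)) df$ggt_elevated <- rep(NA, nrow(df))
  if (is.character(df$ggt_elevated)) df$ggt_elevated[df$ggt_elevated == ""] <- NA
  df$ggt_elevated <- suppressWarnings(as.numeric(df$ggt_elevated)) != 0
  if (!"burst_id" %in% names(df)) df$burst_id <- rep(NA_integer_, nrow(df))
  df$burst_id <- as.integer(df$burst_id)

  keep <- c(CASE_REQUIRED_COLS, CASE_OPTIONAL_COLS)
  df <- df[order(df$onset_date, df$case_id), intersect(keep, names(df)),
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, period = period, class = c("case_table", "data.frame"))
}

#' @export
print.case_table <- function(x, ...) {
  p <- attr(x, "period")
  cat(sprintf("<case_table> %d cases, %s .. %s\n", nrow(x), p$start, p$end))
  NextMethod()
}

#' Study period of a case table
#' @param cases a `case_table`.
#' @return the attached [study_period()].
#' @export
case_period <- function(cases) {
  attr(cases, "period", exact = TRUE)
}

#' Read a case table from CSV
#'
#' Expects a comma-separated UTF-8 file with ISO-8601 (`YYYY-MM-DD`) onset
#' dates and the columns documented in [case_table()]; empty string means
#' missing. Rows with unparseable onset dates or coordinates are rejected
#' with a line-numbered report.
#'
#' @param path path to the CSV file.
#' @param period a [study_period()].
#' @return a `case_table`.
#' @export
read_cases <- function(path, period) {
  if (!file.exists(path))
    stop_kd("case file not found: %s", path, class = "io_error")
  df <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  if ("case_id" %in% names(df)) df$case_id <- as.character(df$case_id)
  missing_cols <- setdiff(CASE_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stop_kd("case CSV %s missing required column(s): %s", path,
            paste(missing_cols, collapse = ", "), class = "schema_error")
  onset <- as.Date(as.character(df$onset_date), format = "%Y-%m-%d")
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  bad <- which(is.na(onset) | is.na(lat) | is.na(lon))
  if (length(bad))
    stop_kd("unparseable onset_date/coordinates at data line(s): %s",
            paste(sprintf("%d (case_id=%s)", bad + 1L,
                          as.character(df$case_id)[bad]), collapse = "; "),
            class = "parse_error")
  df$onset_date <- onset
  case_table(df, period)
}

#' Write a case table to CSV
#'
#' Inverse of [read_cases()]: `read_cases(write_cases(x, f), case_period(x))`
#' reproduces `x` field for field.
#'
#' @param cases a `case_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  df <- as.data.frame(cases)
  df$onset_date <- format(df$onset_date, "%Y-%m-%d")
  df$ggt_elevated <- ifelse(is.na(df$ggt_elevated), NA_integer_,
                            as.integer(df$ggt_elevated))
  data.table::fwrite(df, path, na = "")
  invisible(path)
}

#' Daily case-count series
#'
#' Counts onsets per calendar day across the full study period (zeros
#' included); the basis of the moving-window cluster construction.
#'
#' @param cases a `case_table`.
#' @return a `daily_counts` object: list with `period`, `dates`, and integer
#'   `counts` (one per day, `sum(counts) == nrow(cases)`).
#' @export
daily_counts <- function(cases) {
  period <- case_period(cases)
  dates <- period_dates(period)
  idx <- as.integer(cases$onset_date - period$start) + 1L
  counts <- tabulate(idx, nbins = length(dates))
  structure(list(period = period, dates = dates, counts = as.integer(counts)),
            class = "daily_counts")
}

#' Build a daily-count series directly from counts
#'
#' For worked examples and simulation nulls where only the per-day totals
#' matter, not individual case records.
#'
#' @param counts nonnegative integer vector, one entry per day of `period`.
#' @param period a [study_period()] with exactly `length(counts)` days.
#' @return a `daily_counts` object.
#' @export
daily_counts_from_vector <- function(counts, period) {
  stopifnot(inherits(period, "study_period"))
  if (length(counts) != n_days(period))
    stop_kd("counts length %d != period length %d", length(counts),
            n_days(period), class = "validation_error")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_kd("counts must be nonnegative integers", class = "validation_error")
  structure(list(period = period, dates = period_dates(period),
                 counts = as.integer(counts)),
            class = "daily_counts")
}

#' @export
print.daily_counts <- function(x, ...) {
  cat(sprintf("<daily_counts> %d days, %d cases, %s .. %s\n",
              length(x$counts), sum(x$counts), x$period$start, x$period$end))
  invisible(x)
}

# ---- gridded daily fields ---------------------------------------------------

GRID_VARIABLES <- c(tmax = "degC", tmin = "degC", precip = "mm/day",
                    hgt700 = "m", uwnd = "m/s", vwnd = "m/s")

#' Construct a gridded daily series
#'
#' @param variable one of `tmax`, `tmin`, `precip`, `hgt700`, `uwnd`, `vwnd`.
#' @param dates strictly increasing, daily-contiguous `Date` axis.
#' @param lats,lons numeric grid axes (degrees north / east).
#' @param values numeric array `(time, lat, lon)`; `NA` allowed.
#' @param units units string; defaults to the conventional unit for
#'   `variable`.
#' @return a `gridded_series`.
#' @export
gridded_series <- function(variable, dates, lats, lons, values,
                           units = NULL) {
  if (!variable %in% names(GRID_VARIABLES))
    stop_kd("unknown variable '%s' (expected one of %s)", variable,
            paste(names(GRID_VARIABLES), collapse = ", "),
            class = "validation_error")
  dates <- as.Date(dates)
  dd <- diff(as.integer(dates))
  if (length(dates) > 1 && (any(dd <= 0) || any(dd != 1)))
    stop_kd("time axis must be strictly increasing and daily-contiguous",
            class = "format_error")
  if (!identical(dim(values), c(length(dates), length(lats), length(lons))))
    stop_kd("values shape %s inconsistent with axes (%d, %d, %d)",
            paste(dim(values), collapse = "x"),
            length(dates), length(lats), length(lons), class = "format_error")
  structure(list(variable = variable,
                 units = units %||% unname(GRID_VARIABLES[variable]),
                 dates = dates, lats = as.numeric(lats),
                 lons = as.numeric(lons), values = values),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("<gridded_series> %s [%s], %d days x %d lat x %d lon, %s .. %s\n",
              x$variable, x$units, length(x$dates), length(x$lats),
              length(x$lons), min(x$dates), max(x$dates)))
  invisible(x)
}

#' Write a gridded series as a plain-text grid file
#'
#' Serializes as a self-describing text file: `# key: value` attribute lines
#' (variable, units, axes) followed by a CSV matrix, one row per day, one
#' column per grid cell in lat-major order. A plain-text stand-in for CF
#' NetCDF so the file survives text-only pipelines; round-trips bit-exact
#' through [read_gridded()].
#'
#' @param field a `gridded_series`.
#' @param path output path (conventionally `.grid.csv`).
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path) {
  stopifnot(inherits(field, "gridded_series"))
  hdr <- c(
    sprintf("# variable: %s", field$variable),
    sprintf("# units: %s", field$units),
    sprintf("# start_date: %s", format(min(field$dates))),
    sprintf("# lats: %s", paste(format(field$lats, digits = 15), collapse = " ")),
    sprintf("# lons: %s", paste(format(field$lons, digits = 15), collapse = " "))
  )
  nt <- length(field$dates)
  mat <- matrix(field$values, nrow = nt)  # columns vary lat fastest
  # %.17g guarantees a bit-exact double round-trip through the text file
  chr <- array(sprintf("%.17g", mat), dim = dim(mat))
  chr[is.na(mat)] <- "NA"
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(data.table::as.data.table(chr), path, append = TRUE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded daily series from a plain-text grid file
#'
#' Parses the format written by [write_gridded()] and validates the time
#' axis. Files written by this package are daily-contiguous from
#' `start_date`; files carrying an explicit `# dates:` header (e.g. exported
#' from another tool) may have gaps, which are handled like missing scans in
#' reanalysis archives: gaps of at most 2 days are filled with all-missing
#' days, longer gaps or duplicated/non-increasing dates are a format error.
#'
#' @param path path to the grid file.
#' @param variable expected variable name; a mismatch is a format error that
#'   names the variable actually present.
#' @return a `gridded_series` with a contiguous daily axis.
#' @export
read_gridded <- function(path, variable) {
  if (!file.exists(path))
    stop_kd("grid file not found: %s", path, class = "io_error")
  hdr_lines <- readLines(path, n = 20L)
  hdr_lines <- hdr_lines[startsWith(hdr_lines, "# ")]
  kv <- regmatches(hdr_lines, regexec("^# ([a-z_]+): (.*)$", hdr_lines))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  names(vals) <- keys
  for (need in c("variable", "units", "lats", "lons"))
    if (!need %in% keys)
      stop_kd("grid file %s missing header attribute '%s'", path, need,
              class = "format_error")
  if (!any(c("start_date", "dates") %in% keys))
    stop_kd("grid file %s needs a 'start_date' or 'dates' header", path,
            class = "format_error")
  if (!identical(vals[["variable"]], variable))
    stop_kd("grid file %s holds variable '%s', not '%s'", path,
            vals[["variable"]], variable, class = "format_error")
  lats <- as.numeric(strsplit(vals[["lats"]], " +")[[1]])
  lons <- as.numeric(strsplit(vals[["lons"]], " +")[[1]])
  mat <- as.matrix(data.table::fread(path, skip = length(hdr_lines),
                                     header = FALSE))
  if (ncol(mat) != length(lats) * length(lons))
    stop_kd("grid file %s: %d data columns but %d grid cells declared", path,
            ncol(mat), length(lats) * length(lons), class = "format_error")
  if ("dates" %in% keys) {
    raw_dates <- as.Date(strsplit(vals[["dates"]], " +")[[1]])
    if (length(raw_dates) != nrow(mat))
      stop_kd("grid file %s: %d dates but %d data rows", path,
              length(raw_dates), nrow(mat), class = "format_error")
    dd <- diff(as.integer(raw_dates))
    if (any(dd <= 0))
      stop_kd("grid file %s: time axis not strictly increasing", path,
              class = "format_error")
    if (any(dd > 3))
      stop_kd("grid file %s: time-axis gap of %d days exceeds the 2-day limit",
              path, max(dd) - 1L, class = "format_error")
    dates <- seq(min(raw_dates), max(raw_dates), by = "day")
    full <- matrix(NA_real_, nrow = length(dates), ncol = ncol(mat))
    full[match(raw_dates, dates), ] <- mat
    mat <- full
  } else {
    dates <- as.Date(vals[["start_date"]]) + seq_len(nrow(mat)) - 1L
  }
  gridded_series(variable,
                 dates = dates, lats = lats, lons = lons,
                 values = array(mat, dim = c(nrow(mat), length(lats),
                                             length(lons))),
                 units = vals[["units"]])
}
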