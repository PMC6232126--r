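# Day-of-year climatology, daily anomalies, and event-lagged composites.
#
# The climatology is the multi-year mean of a centered running mean (5 days
# for surface variables, 7 days for 700 hPa fields), indexed on a 365-day
# calendar: Feb 29 contributes to the running means of its neighbours but
# has no climatology slot of its own; its anomaly uses the Feb 28 / Mar 1
# average. Anomaly = daily value - climatology for that day-of-year, which
# makes days comparable across seasons. Composites pool anomaly maps over
# event dates shifted by lag-bin offsets (repeats kept) and mark cells where
# the one-sample t statistic of the pooled mean clears a two-sided critical
# value.

DEFAULT_SMOOTH_DAYS <- c(tmax = 5L, tmin = 5L, precip = 5L,
                         hgt700 = 7L, uwnd = 7L, vwnd = 7L)

#' Day-of-year climatology of a gridded daily series
#'
#' Applies a centered `smooth_window_days` running mean along time (window
#' shrunk at the record edges, missing values skipped), then averages by
#' 365-calendar day-of-year across years.
#'
#' @param field a `gridded_series` covering at least 2 full years.
#' @param smooth_window_days odd window length in days; default depends on
#'   the variable (5 for tmax/tmin/precip, 7 for hgt700/uwnd/vwnd).
#' @return a `climatology`: list with `variable`, `units`, `doy` (1..365),
#'   `lats`, `lons`, `values` array (365, lat, lon), `smooth_window_days`.
#' @export
day_of_year_climatology <- function(field,
                                    smooth_window_days =
                                      DEFAULT_SMOOTH_DAYS[[field$variable]]) {
  stopifnot(inherits(field, "gridded_series"))
  assert_scalar_number(smooth_window_days, "smooth_window_days", min = 1)
  if (smooth_window_days %% 2 == 0)
    stop_kd("smooth_window_days must be odd, got %d", smooth_window_days,
            class = "validation_error")
  nt <- length(field$dates)
  if (nt < 730L)
    stop_kd("climatology needs >= 2 full years of data, got %d days", nt,
            class = "validation_error")
  ncell <- length(field$lats) * length(field$lons)
  vals <- matrix(field$values, nrow = nt, ncol = ncell)
  sm <- running_mean(vals, smooth_window_days)
  doy <- doy365(field$dates)
  keep <- !is.na(doy)
  clim <- rowsum(sm[keep, , drop = FALSE], group = doy[keep], na.rm = TRUE)
  cnt <- rowsum((!is.na(sm[keep, , drop = FALSE])) + 0, group = doy[keep])
  out <- matrix(NA_real_, nrow = 365L, ncol = ncell)
  got <- as.integer(rownames(clim))
  out[got, ] <- as.matrix(clim) / ifelse(cnt > 0, cnt, NA)
  structure(list(variable = field$variable, units = field$units,
                 doy = 1:365, lats = field$lats, lons = field$lons,
                 values = array(out, dim = c(365L, length(field$lats),
                                             length(field$lons))),
                 smooth_window_days = as.integer(smooth_window_days)),
            class = "climatology")
}

# centered running mean along rows of a (time x cell) matrix; window shrinks
# at the edges; NAs skipped
running_mean <- function(mat, w) {
  if (w == 1L) return(mat)
  half <- (w - 1L) %/% 2L
  x <- mat
  x[is.na(x)] <- 0
  cnt <- (!is.na(mat)) + 0
  nt <- nrow(mat)
  cx <- rbind(0, apply(x, 2L, cumsum))
  cc <- rbind(0, apply(cnt, 2L, cumsum))
  lo <- pmax(1L, seq_len(nt) - half)
  hi <- pmin(nt, seq_len(nt) + half)
  s <- cx[hi + 1L, , drop = FALSE] - cx[lo, , drop = FALSE]
  k <- cc[hi + 1L, , drop = FALSE] - cc[lo, , drop = FALSE]
  out <- s / ifelse(k > 0, k, NA)
  out
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> %s [%s], %d-day smoothing, %d x %d grid\n",
              x$variable, x$units, x$smooth_window_days, length(x$lats),
              length(x$lons)))
  invisible(x)
}

#' Daily anomalies relative to a day-of-year climatology
#'
#' `anomaly = daily value - climatology(day of year)`. Feb 29 uses the mean
#' of the Feb 28 and Mar 1 climatology.
#'
#' @param field a `gridded_series`.
#' @param clim a [day_of_year_climatology()] on the same grid and variable.
#' @return an `anomaly_series` (a `gridded_series` subclass).
#' @export
anomalies <- function(field, clim) {
  stopifnot(inherits(field, "gridded_series"), inherits(clim, "climatology"))
  if (!identical(field$variable, clim$variable))
    stop_kd("variable mismatch: field %s vs climatology %s", field$variable,
            clim$variable, class = "validation_error")
  if (!isTRUE(all.equal(field$lats, clim$lats)) ||
      !isTRUE(all.equal(field$lons, clim$lons)))
    stop_kd("grid mismatch between field and climatology",
            class = "validation_error")
  ncell <- length(field$lats) * length(field$lons)
  cmat <- matrix(clim$values, nrow = 365L, ncol = ncell)
  doy <- doy365(field$dates)
  ref <- matrix(NA_real_, nrow = length(field$dates), ncol = ncell)
  ok <- !is.na(doy)
  ref[ok, ] <- cmat[doy[ok], , drop = FALSE]
  if (any(!ok))  # Feb 29: mean of Feb 28 (doy 59) and Mar 1 (doy 60)
    ref[!ok, ] <- rep((cmat[59L, ] + cmat[60L, ]) / 2, each = sum(!ok))
  vals <- matrix(field$values, nrow = length(field$dates)) - ref
  out <- gridded_series(field$variable, field$dates, field$lats, field$lons,
                        array(vals, dim = dim(field$values)),
                        units = field$units)
  class(out) <- c("anomaly_series", class(out))
  out
}

#' Resolve event-day groups for composites
#'
#' Builds the four date groups composited against each other: days without
#' any case (a seeded random sample, season-matched and of the same size as
#' the all-case-day group), days with any case, days with only non-cluster
#' cases, and days with cluster cases. Seasons: `DJFMA` (months 12,1-4, the
#' main season), `MJJA` (months 5-8, the secondary season), or `ALL`.
#'
#' @param cases a `case_table`.
#' @param clusters a `temporal_clusters` from the same cases.
#' @param season `"ALL"`, `"DJFMA"` or `"MJJA"`.
#' @param seed integer seed for the no-case-day sample.
#' @return named list of four `event_group_spec` objects
#'   (`no_case_days`, `all_case_days`, `noncluster_case_days`,
#'   `cluster_case_days`), each a list with `group`, `season`, `dates`, and
#'   an `empty` flag.
#' @export
resolve_event_groups <- function(cases, clusters, season = "ALL", seed = 1L) {
  season <- match.arg(season, c("ALL", "DJFMA", "MJJA"))
  months_in <- switch(season, ALL = 1:12, DJFMA = c(12, 1, 2, 3, 4),
                      MJJA = 5:8)
  assignment <- attr(clusters, "assignment")
  in_cluster <- !is.na(assignment[cases$case_id])

  in_season <- function(d) (as.POSIXlt(d)$mon + 1L) %in% months_in
  all_days <- sort(unique(cases$onset_date[in_season(cases$onset_date)]))
  cl_days <- sort(unique(cases$onset_date[in_cluster &
                                            in_season(cases$onset_date)]))
  nc_days <- setdiff_dates(all_days, cl_days)

  period <- case_period(cases)
  pd <- period_dates(period)
  zero_days <- pd[!(pd %in% cases$onset_date) & in_season(pd)]
  k <- min(length(all_days), length(zero_days))
  no_days <- withr::with_seed(substream_seed(seed, 0L),
                              sort(sample(zero_days, k)))

  mk <- function(group, dates) {
    spec <- list(group = group, season = season, dates = dates,
                 empty = length(dates) == 0L)
    if (spec$empty)
      warning(sprintf("event group '%s' (%s) is empty; composite will be skipped",
                      group, season), call. = FALSE)
    structure(spec, class = "event_group_spec")
  }
  list(no_case_days = mk("no_case_days", no_days),
       all_case_days = mk("all_case_days", all_days),
       noncluster_case_days = mk("noncluster_case_days", nc_days),
       cluster_case_days = mk("cluster_case_days", cl_days))
}

# setdiff() drops the Date class; keep it
setdiff_dates <- function(a, b) a[!(a %in% b)]

#' Default lag bins around the date of onset
#'
#' Mirrors the composite column layout: pooled (-5,-4), (-3,-2), -1, 0 (DOO),
#' +1, (+2,+3), (+4,+5).
#'
#' @return named list of integer offset vectors.
#' @export
default_lag_bins <- function() {
  list("DOO-5" = c(-5L, -4L), "DOO-3" = c(-3L, -2L), "DOO-1" = -1L,
       "DOO" = 0L, "DOO+1" = 1L, "DOO+2" = c(2L, 3L), "DOO+4" = c(4L, 5L))
}

#' Event-lagged composite anomaly maps with significance masks
#'
#' For each lag bin, pools the anomaly maps at `date + offset` for every
#' event date and offset in the bin (shared lagged days pooled repeatedly —
#' the induced non-independence is a documented property of the method), and
#' computes per cell the pooled mean, the one-sample t statistic
#' `mean / (sd / sqrt(n))`, and a two-sided significance mask at the given
#' confidence. Out-of-coverage lagged days are dropped and counted.
#'
#' @param anoms an [anomalies()] series.
#' @param spec an `event_group_spec` (one element of
#'   [resolve_event_groups()]).
#' @param lag_bins named list of integer offset vectors
#'   (default [default_lag_bins()]).
#' @param confidence two-sided confidence level in (0.5, 1), default 0.95.
#' @return a `composite_result`: list with `variable`, `group`, `season`,
#'   `confidence`, `n_dropped`, and `bins` — per bin a list `mean` (lat x
#'   lon), `n`, `t` (lat x lon), `mask` (logical lat x lon; all `FALSE` when
#'   `n < 2`). `NULL` (with a warning) for an empty spec.
#' @export
composite_anomaly <- function(anoms, spec, lag_bins = default_lag_bins(),
                              confidence = 0.95) {
  stopifnot(inherits(anoms, "anomaly_series"),
            inherits(spec, "event_group_spec"))
  if (confidence <= 0.5 || confidence >= 1)
    stop_kd("confidence must be in (0.5, 1)", class = "validation_error")
  if (isTRUE(spec$empty)) {
    warning("empty event group; composite skipped", call. = FALSE)
    return(NULL)
  }
  nt <- length(anoms$dates)
  nlat <- length(anoms$lats); nlon <- length(anoms$lons)
  vals <- matrix(anoms$values, nrow = nt)
  t0 <- min(anoms$dates)
  ev <- as.integer(spec$dates - t0) + 1L

  bins <- list()
  n_dropped <- 0L
  for (bn in names(lag_bins)) {
    offs <- lag_bins[[bn]]
    idx <- as.vector(outer(ev, as.integer(offs), `+`))
    inside <- idx >= 1L & idx <= nt
    n_dropped <- n_dropped + sum(!inside)
    idx <- idx[inside]
    n <- length(idx)
    if (n == 0L) {
      bins[[bn]] <- list(mean = matrix(NA_real_, nlat, nlon), n = 0L,
                         t = matrix(NA_real_, nlat, nlon),
                         mask = matrix(FALSE, nlat, nlon))
      next
    }
    sub <- vals[idx, , drop = FALSE]
    m <- colMeans(sub, na.rm = TRUE)
    if (n >= 2L) {
      s <- apply(sub, 2L, sd, na.rm = TRUE)
      tstat <- m / (s / sqrt(n))
      crit <- qt(1 - (1 - confidence) / 2, df = n - 1L)
      mask <- is.finite(tstat) & abs(tstat) > crit
    } else {
      tstat <- rep(NA_real_, length(m))
      mask <- rep(FALSE, length(m))
    }
    bins[[bn]] <- list(mean = matrix(m, nlat, nlon), n = n,
                       t = matrix(tstat, nlat, nlon),
                       mask = matrix(mask, nlat, nlon))
  }
  structure(list(variable = anoms$variable, group = spec$group,
                 season = spec$season, confidence = confidence,
                 lag_bins = lag_bins, n_dropped = n_dropped, bins = bins),
            class = "composite_result")
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf("<composite_result> %s, group %s, season %s, %d lag bins (%d lagged days dropped)\n",
              x$variable, x$group, x$season, length(x$bins), x$n_dropped))
  for (bn in names(x$bins))
    cat(sprintf("  %-6s n=%4d mean=%8.3f masked=%d/%d\n", bn, x$bins[[bn]]$n,
                mean(x$bins[[bn]]$mean, na.rm = TRUE),
                sum(x$bins[[bn]]$mask), length(x$bins[[bn]]$mask)))
  invisible(x)
}
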