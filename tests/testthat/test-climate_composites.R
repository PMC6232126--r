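toy_field <- function(values_fn, start = "2010-01-01", end = "2013-12-31",
                      lats = c(32.5, 32.7, 32.9),
                      lons = c(-117.3, -117.1), variable = "tmax") {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  nt <- length(dates)
  vals <- array(values_fn(nt, length(lats) * length(lons)),
                dim = c(nt, length(lats), length(lons)))
  gridded_series(variable, dates, lats, lons, vals)
}

test_that("climatology of a constant field is that constant", {
  f <- toy_field(function(nt, nc) 3.5)
  cl <- day_of_year_climatology(f, smooth_window_days = 5)
  expect_equal(as.vector(cl$values), rep(3.5, length(cl$values)))
  an <- anomalies(f, cl)
  expect_lt(max(abs(an$values)), 1e-12)
})

test_that("exactly repeated years give zero anomalies to 1e-12", {
  # two identical non-leap years of an integer-valued daily pattern
  one_year <- withr::with_seed(5, matrix(sample.int(9, 365 * 6, TRUE),
                                         nrow = 365))
  f <- toy_field(function(nt, nc) rbind(one_year, one_year),
                 start = "2010-01-01", end = "2011-12-31")
  cl1 <- day_of_year_climatology(f, smooth_window_days = 1)
  expect_lt(max(abs(anomalies(f, cl1)$values)), 1e-12)
  # with smoothing, the climatology equals the circular 5-day running mean
  # of the repeated-year pattern (away from the doys touched by the record
  # edges, where the window shrinks instead of wrapping)
  cl5 <- day_of_year_climatology(f, smooth_window_days = 5)
  circ <- apply(one_year, 2L, function(col) {
    ext <- c(tail(col, 2), col, head(col, 2))
    vapply(1:365, function(d) mean(ext[d:(d + 4)]), numeric(1))
  })
  got <- matrix(cl5$values, nrow = 365)
  expect_equal(got[3:363, ], circ[3:363, ], tolerance = 1e-12)
})

test_that("climatology is invariant to the ordering of years", {
  y1 <- withr::with_seed(1, matrix(rnorm(365 * 6), nrow = 365))
  y2 <- withr::with_seed(2, matrix(rnorm(365 * 6), nrow = 365))
  f12 <- toy_field(function(nt, nc) rbind(y1, y2),
                   start = "2010-01-01", end = "2011-12-31")
  f21 <- toy_field(function(nt, nc) rbind(y2, y1),
                   start = "2010-01-01", end = "2011-12-31")
  c12 <- day_of_year_climatology(f12, smooth_window_days = 1)
  c21 <- day_of_year_climatology(f21, smooth_window_days = 1)
  expect_equal(c12$values, c21$values, tolerance = 1e-12)
})

test_that("white-noise climatology variance matches the averaging formula", {
  n_years <- 8; w <- 5
  f <- toy_field(function(nt, nc) withr::with_seed(7, rnorm(nt * nc)),
                 start = "2008-01-01", end = "2015-12-31",
                 lats = seq(32, 33.5, 0.25), lons = seq(-118, -116.5, 0.25))
  cl <- day_of_year_climatology(f, smooth_window_days = w)
  v <- var(as.vector(cl$values))
  # independent noise averaged over ~n_years * w draws
  expect_equal(v, 1 / (n_years * w), tolerance = 0.15)
})

test_that("anomalies validates grids and applies the Feb 29 convention", {
  f <- toy_field(function(nt, nc) 1)
  cl <- day_of_year_climatology(f)
  f_bad <- toy_field(function(nt, nc) 1, lats = c(32.5, 32.7))
  expect_error(anomalies(f_bad, cl), class = "validation_error")
  f_var <- toy_field(function(nt, nc) 1, variable = "tmin")
  expect_error(anomalies(f_var, cl), class = "validation_error")

  # field = climatology + 1 -> anomalies of 1, including on Feb 29 (2012)
  doy <- doy365(f$dates)
  expect_true(any(is.na(doy)))  # 2012-02-29 present
  an <- anomalies(toy_field(function(nt, nc) 2), cl)
  expect_equal(as.vector(an$values), rep(1, length(an$values)))
})

test_that("resolve_event_groups partitions case days and samples no-case days", {
  cases <- table1_cases()
  cl <- find_temporal_clusters(cases)
  g <- resolve_event_groups(cases, cl, "ALL", seed = 5)
  expect_equal(g$noncluster_case_days$dates, as.Date("2010-01-09"))
  expect_equal(g$cluster_case_days$dates,
               sort(unique(cases$onset_date[cases$case_id != "T05"])))
  expect_equal(length(g$all_case_days$dates),
               length(unique(cases$onset_date)))
  # no-case days: same size as all-case days (when available), zero onsets
  expect_equal(length(g$no_case_days$dates), length(g$all_case_days$dates))
  expect_false(any(g$no_case_days$dates %in% cases$onset_date))
  # determinism of the seeded sample
  g2 <- resolve_event_groups(cases, cl, "ALL", seed = 5)
  expect_identical(g2$no_case_days$dates, g$no_case_days$dates)

  # no cases in MJJA -> empty groups, one warning per empty group
  w <- testthat::capture_warnings(
    gm <- resolve_event_groups(cases, cl, "MJJA", seed = 1))
  expect_true(all(grepl("empty", w)))
  expect_true(gm$all_case_days$empty)
  expect_null(suppressWarnings(
    composite_anomaly(structure(list(variable = "tmax"),
                                class = c("anomaly_series", "gridded_series")),
                      gm$all_case_days)))
})

test_that("composite_anomaly: forced injection, pooling, and linearity", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2011-12-31"), by = "day")
  nt <- length(dates)
  ev <- as.Date(c("2010-04-10", "2010-09-03", "2011-02-20"))
  base <- array(0, dim = c(nt, 2, 2))
  base[match(ev, dates), , ] <- 2  # +2 exactly on event days
  f <- gridded_series("tmax", dates, c(32.5, 32.7), c(-117.2, -117.0), base)
  an <- f; class(an) <- c("anomaly_series", class(f))  # already anomalies

  spec <- structure(list(group = "all_case_days", season = "ALL",
                         dates = ev, empty = FALSE),
                    class = "event_group_spec")
  comp <- composite_anomaly(an, spec)
  expect_equal(comp$bins[["DOO"]]$mean, matrix(2, 2, 2))
  expect_equal(comp$bins[["DOO"]]$n, 3L)
  for (bn in setdiff(names(comp$bins), "DOO"))
    expect_equal(comp$bins[[bn]]$mean, matrix(0, 2, 2))
  # zero-variance nonzero bins cannot be masked (t undefined -> FALSE)
  expect_false(any(comp$bins[["DOO-1"]]$mask))

  # all-zero anomalies -> zero composite, empty mask
  z <- gridded_series("tmax", dates, c(32.5, 32.7), c(-117.2, -117.0),
                      array(0, dim = c(nt, 2, 2)))
  class(z) <- c("anomaly_series", class(z))
  cz <- composite_anomaly(z, spec)
  expect_equal(cz$bins[["DOO"]]$mean, matrix(0, 2, 2))
  expect_false(any(vapply(cz$bins, function(b) any(b$mask), logical(1))))

  # linearity: composite of a union = n-weighted average of the parts
  rnd <- gridded_series("tmax", dates, c(32.5, 32.7), c(-117.2, -117.0),
                        array(withr::with_seed(3, rnorm(nt * 4)),
                              dim = c(nt, 2, 2)))
  class(rnd) <- c("anomaly_series", class(rnd))
  s1 <- structure(list(group = "a", season = "ALL", dates = ev[1:2],
                       empty = FALSE), class = "event_group_spec")
  s2 <- structure(list(group = "b", season = "ALL", dates = ev[3],
                       empty = FALSE), class = "event_group_spec")
  su <- structure(list(group = "u", season = "ALL", dates = ev,
                       empty = FALSE), class = "event_group_spec")
  bins <- list(DOO = 0L)
  c1 <- composite_anomaly(rnd, s1, bins); c2 <- composite_anomaly(rnd, s2, bins)
  cu <- composite_anomaly(rnd, su, bins)
  n1 <- c1$bins$DOO$n; n2 <- c2$bins$DOO$n
  expect_equal(cu$bins$DOO$mean,
               (n1 * c1$bins$DOO$mean + n2 * c2$bins$DOO$mean) / (n1 + n2),
               tolerance = 1e-12)

  # out-of-coverage offsets are dropped and counted
  s_edge <- structure(list(group = "e", season = "ALL", dates = dates[1],
                           empty = FALSE), class = "event_group_spec")
  ce <- composite_anomaly(rnd, s_edge)
  expect_equal(ce$n_dropped, 5L)  # offsets -5..-1 fall before the record

  expect_error(composite_anomaly(rnd, su, confidence = 1.2),
               class = "validation_error")
})
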