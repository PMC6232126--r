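short_period <- function() study_period("2010-01-01", "2012-12-31")

test_that("simulate_cases respects degenerate configs and determinism", {
  cfg0 <- case_sim_config(period = short_period(), n_expected = 0,
                          burst_rate = 0, seed = 3)
  expect_equal(nrow(simulate_cases(cfg0)), 0L)

  cfg <- case_sim_config(period = short_period(), n_expected = 150,
                         burst_rate = 3, burst_size_min = 2, seed = 9)
  a <- simulate_cases(cfg)
  b <- simulate_cases(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_s3_class(a, "case_table")
  expect_true(all(a$onset_date >= short_period()$start &
                    a$onset_date <= short_period()$end))
  expect_true(all(c("age", "esr", "anc", "ggt_elevated", "burst_id") %in%
                    names(a)))
  expect_true(any(!is.na(a$burst_id)))
  expect_true(all(a$age > 0))

  expect_error(case_sim_config(period = short_period(),
                               monthly_rate_profile = rep(0, 12)),
               class = "validation_error")
})

test_that("burst-free totals are calibrated to n_expected", {
  cfg <- case_sim_config(period = short_period(), n_expected = 80,
                         burst_rate = 0, seed = 1)
  totals <- vapply(1:200, function(s) {
    cfg$seed <- s
    nrow(simulate_cases(cfg))
  }, integer(1))
  # Poisson(80) totals: mean within 3 standard errors
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 80), 3 * se)
})

test_that("seasonality shapes where cases land", {
  cfg <- case_sim_config(period = short_period(), n_expected = 600,
                         burst_rate = 0,
                         monthly_rate_profile = c(5, rep(0.1, 11)), seed = 4)
  cs <- simulate_cases(cfg)
  m <- as.POSIXlt(cs$onset_date)$mon + 1L
  expect_gt(mean(m == 1L), 0.5)
})

test_that("ground-truth burst cases fall inside detected temporal clusters", {
  hits <- vapply(1:6, function(s) {
    cfg <- case_sim_config(period = short_period(), n_expected = 150,
                           burst_rate = 4, burst_duration_days = 5,
                           burst_size_mean = 6, burst_size_min = 4, seed = s)
    cs <- simulate_cases(cfg)
    cl <- find_temporal_clusters(cs)
    assignment <- attr(cl, "assignment")
    truth <- !is.na(cs$burst_id)
    mean(!is.na(assignment[cs$case_id[truth]]))
  }, numeric(1))
  expect_gt(mean(hits), 0.8)
})

test_that("seasonal_profile_from_counts does the per-month arithmetic", {
  # uniform 1 case/day -> all weights 1
  p <- study_period("2010-01-01", "2011-12-31")
  u <- daily_counts_from_vector(rep(1L, n_days(p)), p)
  prof_u <- seasonal_profile_from_counts(u)
  expect_equal(prof_u$weights, rep(1, 12))
  expect_equal(prof_u$sd_across_years, rep(0, 12))

  # cases only in January
  v <- rep(0L, n_days(p))
  v[as.POSIXlt(period_dates(p))$mon == 0L] <- 2L
  prof_j <- seasonal_profile_from_counts(daily_counts_from_vector(v, p))
  expect_equal(prof_j$weights, c(2, rep(0, 11)))

  # 2-year toy with hand-computed weights: 62 cases spread over the two
  # Januaries (one/day) and 10 cases on 2010-06-15
  w <- rep(0L, n_days(p))
  w[as.POSIXlt(period_dates(p))$mon == 0L] <- 1L
  w[period_dates(p) == as.Date("2010-06-15")] <- 10L
  prof <- seasonal_profile_from_counts(daily_counts_from_vector(w, p))
  expect_equal(prof$weights[1], 1)
  expect_equal(prof$weights[6], 10 / 60)  # 10 cases over two 30-day Junes
  expect_equal(sum(prof$weights[-c(1, 6)]), 0)

  expect_error(
    seasonal_profile_from_counts(
      daily_counts_from_vector(rep(1L, 100),
                               study_period("2010-01-01", "2010-04-10"))),
    class = "validation_error")
})

test_that("GGT hotspot: p decreases with contrast; strong contrast is detected", {
  pv <- function(p_in, s) {
    cfg <- case_sim_config(period = short_period(), n_expected = 230,
                           burst_rate = 0,
                           ggt_hotspot = list(lat = 32.80, lon = -117.05,
                                              radius_km = 8,
                                              p_inside = p_in,
                                              p_outside = 0.1),
                           seed = s)
    cs <- simulate_cases(cfg)
    spatial_label_permutation_test(cs, n_reps = 199, seed = s + 50)$p_value
  }
  m <- sapply(c(0.1, 0.35, 0.6),
              function(p_in) vapply(1:15, function(s) pv(p_in, s + 60),
                                    numeric(1)))
  # average p falls monotonically as the inside/outside contrast grows
  expect_true(all(diff(colMeans(m)) < 0))
  # 0.6-vs-0.1 contrast detected at alpha = 0.05 in >= 80% of seeds
  expect_gte(mean(m[, 3] <= 0.05), 0.8)
})

test_that("without burst shifts the trait slope sits in its null band", {
  sl <- vapply(1:12, function(s) {
    cfg <- case_sim_config(period = short_period(), n_expected = 230,
                           burst_rate = 0, seed = s + 70)
    pts <- conditional_window_medians(simulate_cases(cfg), "age", 10)
    r <- trait_slope_regression(pts, "points")
    c(slope = r$slope, reject = r$p_slope < 0.05)
  }, numeric(2))
  expect_lt(abs(mean(sl["slope", ])),
            3 * sd(sl["slope", ]) / sqrt(ncol(sl)))
  expect_lte(mean(sl["reject", ]), 0.25)  # ~nominal rate at 12 seeds
})

test_that("simulate_climate is exact without noise and deterministic with it", {
  # two identical non-leap years: the cycle repeats exactly, so anomalies
  # after climatology are zero to numerical precision
  cfg0 <- climate_sim_config(lats = c(32.5, 32.7), lons = c(-117.2, -117.0),
                             start = "2010-01-01", end = "2011-12-31",
                             variables = "tmax",
                             noise_sd = c(tmax = 0),
                             coupling_amplitude = c(tmax = 0), seed = 1)
  f0 <- simulate_climate(cfg0)$tmax
  doy <- as.POSIXlt(f0$dates)$yday + 1
  cyc <- 22 + 6 * cos(2 * pi * (doy - 196) / 365.25)
  expect_equal(f0$values[, 1, 1], cyc, tolerance = 1e-12)
  an <- anomalies(f0, day_of_year_climatology(f0, smooth_window_days = 1))
  expect_lt(max(abs(an$values), na.rm = TRUE), 1e-12)

  cfgn <- climate_sim_config(lats = c(32.5, 32.7), lons = c(-117.2, -117.0),
                             start = "2010-01-01", end = "2010-12-31",
                             variables = c("tmax", "precip"), seed = 12)
  f1 <- simulate_climate(cfgn)
  f2 <- simulate_climate(cfgn)
  expect_identical(f1$tmax$values, f2$tmax$values)
  expect_identical(f1$precip$values, f2$precip$values)
  cfg13 <- cfgn; cfg13$seed <- 13
  expect_false(identical(f1$tmax$values, simulate_climate(cfg13)$tmax$values))

  expect_error(simulate_climate(cfgn, event_days = as.Date("2013-01-01")),
               class = "validation_error")
})

test_that("event coupling adds the configured anomaly on coupled days", {
  ev <- as.Date(c("2010-03-10", "2010-11-02"))
  cfg <- climate_sim_config(lats = 32.6, lons = -117.1,
                            start = "2010-01-01", end = "2010-12-31",
                            variables = "tmax", noise_sd = c(tmax = 0),
                            coupling_amplitude = c(tmax = 2), seed = 1)
  f <- simulate_climate(cfg, ev)$tmax
  cfg0 <- cfg; cfg0$coupling_amplitude <- c(tmax = 0)
  f0 <- simulate_climate(cfg0)$tmax
  diffv <- f$values[, 1, 1] - f0$values[, 1, 1]
  coupled <- rep(FALSE, length(f$dates))
  for (d in ev) coupled[abs(as.numeric(f$dates) - d) <= 5] <- TRUE
  expect_equal(diffv[coupled], rep(2, sum(coupled)))
  expect_equal(diffv[!coupled], rep(0, sum(!coupled)))
})
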