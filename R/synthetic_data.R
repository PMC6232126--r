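# Ground-truth synthetic data: seasonal inhomogeneous case process with
# injected space-time bursts and trait structure, plus AR(1) gridded climate
# fields with event-coupled anomalies. The generator's defaults describe a
# San Diego-like surveillance setting: a winter-spring incidence peak with a
# June secondary peak and an early-fall nadir, episodic bursts of about a
# week confined to a few km, cases spread over a ~100 km metropolitan
# region, burst-shared trait shifts inducing 10-day autocorrelation, and a
# spatial hotspot of elevated GGT.

# Relative mean cases/day per month, Jan..Dec: Jan-Mar high, June secondary
# peak, Sep-Oct nadir.
DEFAULT_MONTHLY_PROFILE <- c(1.5, 1.5, 1.4, 1.0, 0.9, 1.1,
                             0.8, 0.7, 0.5, 0.5, 0.8, 1.2)

DEFAULT_TRAIT_MODELS <- list(
  # age in years: log-normal, median ~2.7 y, typical KD age distribution
  age = list(dist = "lnorm", meanlog = 1.0, sdlog = 0.65, burst_shift_sd = 0),
  # ESR mm/hr in acute KD: gamma, mean ~56
  esr = list(dist = "gamma", shape = 8, scale = 7, burst_shift_sd = 0),
  # ANC cells/mm^3: gamma, mean ~8400
  anc = list(dist = "gamma", shape = 6, scale = 1400, burst_shift_sd = 0),
  # CRP mg/dL: gamma, mean ~8
  crp = list(dist = "gamma", shape = 2, scale = 4, burst_shift_sd = 0))

#' Configuration of the synthetic case generator
#'
#' Defaults describe the emulated surveillance setting; see the methods
#' vignette for the rationale of each value.
#'
#' @param period a [study_period()].
#' @param n_expected expected number of background (non-burst) cases over
#'   the whole period.
#' @param monthly_rate_profile 12 nonnegative relative weights (mean
#'   cases/day per month, Jan..Dec).
#' @param burst_rate expected bursts per year (0 disables bursts).
#' @param burst_duration_days burst length in days.
#' @param burst_size_mean mean extra cases per burst (Poisson).
#' @param burst_size_min lower bound applied to each burst's size draw.
#' @param burst_spatial_sd_km spatial spread (km) of burst cases around the
#'   burst center.
#' @param background_centers data.frame with columns `lat`, `lon`, `weight`,
#'   `sd_km`: Gaussian population mixture the background (and burst centers)
#'   are drawn from. Default: one dense urban core plus two suburban lobes
#'   spanning roughly 100 km.
#' @param trait_models named list (age, esr, anc, crp) of baseline
#'   distributions (`dist` = `"lnorm"` or `"gamma"` with its parameters) and
#'   `burst_shift_sd`, the sd of the burst-shared additive shift on the
#'   trait's natural scale (0 = no induced autocorrelation).
#' @param ggt_hotspot list `(lat, lon, radius_km, p_inside, p_outside)`:
#'   probability of elevated GGT inside vs outside a circular hotspot.
#' @param seed integer seed; all randomness derives from it.
#' @return a `case_sim_config`.
#' @export
case_sim_config <- function(period = study_period("2002-01-01", "2017-04-15"),
                            n_expected = 1000,
                            monthly_rate_profile = DEFAULT_MONTHLY_PROFILE,
                            burst_rate = 2,
                            burst_duration_days = 7L,
                            burst_size_mean = 5,
                            burst_size_min = 0L,
                            burst_spatial_sd_km = 5,
                            background_centers = data.frame(
                              lat = c(32.75, 33.05, 32.60),
                              lon = c(-117.10, -117.25, -116.90),
                              weight = c(0.6, 0.25, 0.15),
                              sd_km = c(12, 10, 15)),
                            trait_models = DEFAULT_TRAIT_MODELS,
                            ggt_hotspot = list(lat = 32.80, lon = -117.05,
                                               radius_km = 8,
                                               p_inside = 0.15,
                                               p_outside = 0.15),
                            seed = 1L) {
  stopifnot(inherits(period, "study_period"))
  assert_scalar_number(n_expected, "n_expected", min = 0)
  assert_scalar_number(burst_rate, "burst_rate", min = 0)
  assert_scalar_number(burst_duration_days, "burst_duration_days", min = 1)
  assert_scalar_number(burst_size_mean, "burst_size_mean", min = 0)
  assert_scalar_number(burst_spatial_sd_km, "burst_spatial_sd_km", min = 0)
  if (length(monthly_rate_profile) != 12L || any(monthly_rate_profile < 0) ||
      !any(monthly_rate_profile > 0))
    stop_kd("monthly_rate_profile must be 12 nonnegative weights, not all zero",
            class = "validation_error")
  for (p in c("p_inside", "p_outside"))
    if (ggt_hotspot[[p]] < 0 || ggt_hotspot[[p]] > 1)
      stop_kd("ggt_hotspot$%s must be in [0, 1]", p, class = "validation_error")
  structure(list(period = period, n_expected = n_expected,
                 monthly_rate_profile = monthly_rate_profile,
                 burst_rate = burst_rate,
                 burst_duration_days = as.integer(burst_duration_days),
                 burst_size_mean = burst_size_mean,
                 burst_size_min = as.integer(burst_size_min),
                 burst_spatial_sd_km = burst_spatial_sd_km,
                 background_centers = background_centers,
                 trait_models = trait_models, ggt_hotspot = ggt_hotspot,
                 seed = seed),
            class = "case_sim_config")
}

KM_PER_DEG_LAT <- 111.195  # 2 * pi * 6371 / 360

# draw n positions from the Gaussian mixture in `centers`
draw_positions <- function(n, centers) {
  if (n == 0L)
    return(data.frame(lat = numeric(), lon = numeric()))
  comp <- sample.int(nrow(centers), n, replace = TRUE,
                     prob = centers$weight)
  sd_deg <- centers$sd_km[comp] / KM_PER_DEG_LAT
  lat <- rnorm(n, centers$lat[comp], sd_deg)
  lon <- rnorm(n, centers$lon[comp],
               sd_deg / cos(centers$lat[comp] * pi / 180))
  data.frame(lat = lat, lon = lon)
}

draw_baseline_trait <- function(n, model) {
  switch(model$dist,
         lnorm = rlnorm(n, model$meanlog, model$sdlog),
         gamma = rgamma(n, shape = model$shape, scale = model$scale),
         stop_kd("unknown trait distribution '%s'", model$dist,
                 class = "validation_error"))
}

#' Simulate a synthetic case table
#'
#' Background onsets: a Poisson(`n_expected`) total allocated over days by a
#' multinomial draw with day probability proportional to the monthly
#' seasonal profile — the same process as the analysis null, so burst-free
#' output is exactly null-distributed. Bursts: a homogeneous Poisson number
#' of bursts, each with a uniform start day, a size draw
#' `max(burst_size_min, Poisson(burst_size_mean))`, onset times uniform
#' within the burst window (clipped to the period), and positions scattered
#' `burst_spatial_sd_km` around a center drawn from the background mixture.
#' Traits are baseline draws plus, for burst cases, a burst-shared additive
#' shift (sd `burst_shift_sd`, natural scale, truncated at a small positive
#' floor). Elevated GGT is Bernoulli with the hotspot inside/outside
#' probability. The same seed reproduces the table exactly.
#'
#' @param config a [case_sim_config()].
#' @return a `case_table` with ground-truth column `burst_id` (`NA` for
#'   background cases).
#' @export
simulate_cases <- function(config) {
  stopifnot(inherits(config, "case_sim_config"))
  period <- config$period
  dates <- period_dates(period)
  nd <- length(dates)
  years <- nd / 365.25

  df <- withr::with_seed(substream_seed(config$seed, 1L), {
    # background
    p_day <- day_probabilities(dates, config$monthly_rate_profile)
    n_bg <- rpois(1L, config$n_expected)
    bg_day <- if (n_bg > 0)
      rep(seq_len(nd), as.integer(stats::rmultinom(1L, n_bg, p_day)))
    else integer()
    bg_pos <- draw_positions(n_bg, config$background_centers)

    # bursts
    n_bursts <- if (config$burst_rate > 0) rpois(1L, config$burst_rate * years)
                else 0L
    burst_day <- integer(); burst_id <- integer()
    burst_pos <- data.frame(lat = numeric(), lon = numeric())
    burst_shift <- list()
    if (n_bursts > 0L) {
      starts <- sample.int(nd, n_bursts, replace = TRUE)
      sizes <- pmax(config$burst_size_min, rpois(n_bursts, config$burst_size_mean))
      centers <- draw_positions(n_bursts, config$background_centers)
      for (b in seq_len(n_bursts)) {
        nb <- sizes[b]
        if (nb == 0L) next
        d <- starts[b] + sample.int(config$burst_duration_days, nb,
                                    replace = TRUE) - 1L
        d <- pmin(d, nd)
        sd_deg <- config$burst_spatial_sd_km / KM_PER_DEG_LAT
        lat <- rnorm(nb, centers$lat[b], sd_deg)
        lon <- rnorm(nb, centers$lon[b],
                     sd_deg / cos(centers$lat[b] * pi / 180))
        burst_day <- c(burst_day, d)
        burst_id <- c(burst_id, rep.int(b, nb))
        burst_pos <- rbind(burst_pos, data.frame(lat = lat, lon = lon))
      }
      # burst-shared trait shifts, one per burst and trait
      burst_shift <- lapply(config$trait_models, function(m)
        rnorm(n_bursts, 0, m$burst_shift_sd %||% 0))
    }

    day <- c(bg_day, burst_day)
    n <- length(day)
    if (n == 0L) {
      data.frame(case_id = character(), onset_date = as.Date(character()),
                 lat = numeric(), lon = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      df <- data.frame(
        case_id = sprintf("case%05d", seq_len(n)),
        onset_date = dates[day],
        lat = c(bg_pos$lat, burst_pos$lat),
        lon = c(bg_pos$lon, burst_pos$lon),
        burst_id = c(rep(NA_integer_, n_bg), burst_id),
        stringsAsFactors = FALSE)
      for (trait in names(config$trait_models)) {
        m <- config$trait_models[[trait]]
        v <- draw_baseline_trait(n, m)
        shift <- ifelse(is.na(df$burst_id), 0,
                        burst_shift[[trait]][df$burst_id])
        df[[trait]] <- pmax(v + shift, 0.01)
      }
      df$sex <- ifelse(runif(n) < 0.6, "M", "F")  # male predominance ~1.5:1
      df$illness_day <- sample.int(10L, n, replace = TRUE)
      hs <- config$ggt_hotspot
      inside <- great_circle_km(df$lat, df$lon, hs$lat, hs$lon) <= hs$radius_km
      df$ggt_elevated <- runif(n) < ifelse(inside, hs$p_inside, hs$p_outside)
      df
    }
  })
  case_table(df, period)
}

#' Seasonal profile from a daily-count series
#'
#' `weight[m]` = total cases in month m across years / total days in month m
#' across years, i.e. the mean cases/day for each calendar month — the
#' observed-seasonality input of the Monte Carlo nulls. Also returns the
#' across-year sd of each month's cases/day.
#'
#' @param counts a `daily_counts` covering at least one full year.
#' @return a `seasonal_profile`: list with `weights` (12), `sd_across_years`
#'   (12), and `n_years_by_month`.
#' @export
seasonal_profile_from_counts <- function(counts) {
  stopifnot(inherits(counts, "daily_counts"))
  if (length(counts$counts) < 365L)
    stop_kd("seasonal profile needs >= 1 full year of counts",
            class = "validation_error")
  lt <- as.POSIXlt(counts$dates)
  m <- lt$mon + 1L
  y <- lt$year
  tot <- tapply(counts$counts, m, sum)
  days <- tapply(counts$counts, m, length)
  weights <- rep(0, 12)
  weights[as.integer(names(tot))] <- tot / days
  # per (year, month) cases/day, then sd across years
  ym_rate <- tapply(counts$counts, list(y, m), mean)
  sdv <- rep(NA_real_, 12)
  sdv[as.integer(colnames(ym_rate))] <- apply(ym_rate, 2L, sd, na.rm = TRUE)
  structure(list(weights = as.numeric(weights), sd_across_years = sdv,
                 n_years_by_month = apply(!is.na(ym_rate), 2L, sum)),
            class = "seasonal_profile")
}

# ---- synthetic climate ------------------------------------------------------

#' Configuration of the synthetic climate generator
#'
#' Each variable is seasonal cycle + per-cell AR(1) weather noise + an
#' additive anomaly on days within `coupling_lag_days` of a supplied event
#' day. Defaults emulate a small coastal-Southern-California surface grid and
#' a coarse mid-troposphere grid.
#'
#' @param lats,lons grid axes (decimal degrees).
#' @param start,end date range of the daily axis.
#' @param variables character vector of variables to emit.
#' @param mean_level,seasonal_cycle_amplitude named numeric per variable
#'   (units of the variable); the cycle peaks in mid-July (doy 196) for
#'   temperatures and heights, mid-January for precipitation.
#' @param ar1_coefficient,noise_sd named per variable: weather-noise AR(1)
#'   coefficient (|a| < 1) and innovation sd.
#' @param coupling_amplitude named per variable: additive anomaly applied on
#'   event days +/- `coupling_lag_days` (0 = uncoupled).
#' @param coupling_lag_days half-width of the coupled window (default 5,
#'   matching the composite lag range).
#' @param seed integer seed.
#' @return a `climate_sim_config`.
#' @export
climate_sim_config <- function(lats = seq(32.2, 33.6, by = 0.2),
                               lons = seq(-117.6, -116.2, by = 0.2),
                               start = "2002-01-01", end = "2016-12-31",
                               variables = c("tmax", "tmin", "precip"),
                               mean_level = c(tmax = 22, tmin = 12,
                                              precip = 0.8, hgt700 = 3000,
                                              uwnd = 5, vwnd = 0),
                               seasonal_cycle_amplitude = c(tmax = 6, tmin = 5,
                                                            precip = 0.7,
                                                            hgt700 = 60,
                                                            uwnd = 3, vwnd = 1),
                               ar1_coefficient = c(tmax = 0.7, tmin = 0.7,
                                                   precip = 0.3, hgt700 = 0.8,
                                                   uwnd = 0.6, vwnd = 0.6),
                               noise_sd = c(tmax = 1.5, tmin = 1.2,
                                            precip = 1.0, hgt700 = 25,
                                            uwnd = 2, vwnd = 2),
                               coupling_amplitude = c(tmax = 0, tmin = 0,
                                                      precip = 0, hgt700 = 0,
                                                      uwnd = 0, vwnd = 0),
                               coupling_lag_days = 5L,
                               seed = 1L) {
  bad <- variables[!variables %in% names(GRID_VARIABLES)]
  if (length(bad))
    stop_kd("unknown climate variable(s): %s", paste(bad, collapse = ", "),
            class = "validation_error")
  if (any(abs(ar1_coefficient[variables]) >= 1))
    stop_kd("|ar1_coefficient| must be < 1", class = "validation_error")
  if (any(noise_sd[variables] < 0))
    stop_kd("noise_sd must be >= 0", class = "validation_error")
  structure(list(lats = lats, lons = lons,
                 start = as.Date(start), end = as.Date(end),
                 variables = variables, mean_level = mean_level,
                 seasonal_cycle_amplitude = seasonal_cycle_amplitude,
                 ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
                 coupling_amplitude = coupling_amplitude,
                 coupling_lag_days = as.integer(coupling_lag_days),
                 seed = seed),
            class = "climate_sim_config")
}

#' Simulate gridded daily climate fields
#'
#' `value(t, x) = seasonal_cycle(t) + AR(1) noise(t, x) +
#' coupling_amplitude * 1[t within +/- coupling_lag_days of an event day]`.
#' Noise is independent across cells; the same seed gives bit-identical
#' arrays.
#'
#' @param config a [climate_sim_config()].
#' @param event_days optional `Date` vector of event days (e.g. cluster case
#'   onsets) the coupled anomaly attaches to; must lie within the time axis.
#' @return named list of `gridded_series`, one per configured variable.
#' @export
simulate_climate <- function(config, event_days = as.Date(character())) {
  stopifnot(inherits(config, "climate_sim_config"))
  dates <- seq(config$start, config$end, by = "day")
  event_days <- as.Date(event_days)
  if (length(event_days) &&
      (min(event_days) < config$start || max(event_days) > config$end))
    stop_kd("event_days outside the simulated time axis",
            class = "validation_error")
  nt <- length(dates)
  ncell <- length(config$lats) * length(config$lons)
  doy <- as.POSIXlt(dates)$yday + 1  # real day-of-year for the cycle

  coupled <- rep(FALSE, nt)
  if (length(event_days)) {
    ev <- as.integer(event_days - config$start) + 1L
    for (o in -config$coupling_lag_days:config$coupling_lag_days) {
      io <- ev + o
      coupled[io[io >= 1L & io <= nt]] <- TRUE
    }
  }

  out <- list()
  for (k in seq_along(config$variables)) {
    v <- config$variables[k]
    peak_doy <- if (v == "precip") 15 else 196  # wet winter, warm summer
    cyc <- config$mean_level[[v]] + config$seasonal_cycle_amplitude[[v]] *
      cos(2 * pi * (doy - peak_doy) / 365.25)
    a <- config$ar1_coefficient[[v]]
    sdv <- config$noise_sd[[v]]
    noise <- withr::with_seed(substream_seed(config$seed, k), {
      eps <- matrix(rnorm(nt * ncell, 0, sdv), nrow = nt)
      if (a != 0 && nt > 1) {
        for (t in 2:nt) eps[t, ] <- a * eps[t - 1L, ] + eps[t, ]
      }
      eps
    })
    vals <- cyc + noise + config$coupling_amplitude[[v]] * coupled
    out[[v]] <- gridded_series(v, dates, config$lats, config$lons,
                               array(vals, dim = c(nt, length(config$lats),
                                                   length(config$lons))))
  }
  out
}
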