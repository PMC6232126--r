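# Two-stage temporal cluster construction and its seasonal Monte Carlo null.
#
# Stage 1 flags "cluster days": every day lying inside some full
# window_days-long window (no wraparound, windows wholly inside the period)
# whose total onset count reaches min_cases. Stage 2 takes maximal unbroken
# runs of flagged days as temporal clusters and assigns member cases by
# onset date. The null model redistributes the observed number of cases over
# the period with day probabilities proportional to the observed monthly
# seasonality, and repeats the construction.

#' Cluster construction parameters
#'
#' Defaults encode the primary construction: at least 4 onsets within 7
#' consecutive days. Alternative time scales (e.g. 3- or 30-day windows) are
#' expressed through these parameters rather than separate code paths.
#'
#' @param window_days moving-window length in days (>= 1).
#' @param min_cases minimum onset count within a window for its days to be
#'   flagged (>= 1).
#' @return a `cluster_params` object.
#' @export
cluster_params <- function(window_days = 7L, min_cases = 4L) {
  assert_scalar_number(window_days, "window_days", min = 1)
  assert_scalar_number(min_cases, "min_cases", min = 1)
  structure(list(window_days = as.integer(window_days),
                 min_cases = as.integer(min_cases)),
            class = "cluster_params")
}

#' Flag cluster days with a moving window
#'
#' A day is flagged iff at least one full `window_days`-long window that
#' contains it (and lies wholly inside the study period — no wraparound, so
#' days near the period edges belong to fewer windows) has a total of
#' `min_cases` or more onsets. Periods shorter than the window have no full
#' windows and hence no flagged days.
#'
#' @param counts a `daily_counts` object.
#' @param params a [cluster_params()].
#' @return logical vector, one flag per day of the period.
#' @export
flag_cluster_days <- function(counts, params = cluster_params()) {
  stopifnot(inherits(counts, "daily_counts"), inherits(params, "cluster_params"))
  n <- length(counts$counts)
  w <- params$window_days
  if (n < w) return(rep(FALSE, n))
  # wsum[s] = onsets in window [s, s + w - 1], s = 1 .. n - w + 1
  cs <- c(0L, cumsum(counts$counts))
  starts <- seq_len(n - w + 1L)
  wsum <- cs[starts + w] - cs[starts]
  hot <- wsum >= params$min_cases
  # day d is flagged iff any hot window start in [d - w + 1, d]
  ch <- c(0L, cumsum(hot))
  d <- seq_len(n)
  lo <- pmax(1L, d - w + 1L)
  hi <- pmin(d, n - w + 1L)
  (ch[hi + 1L] - ch[lo]) > 0L
}

#' Extract temporal clusters from flagged days
#'
#' Clusters are maximal unbroken runs of flagged days; member cases are those
#' with onset inside the run. A cluster is extended until a break (an
#' unflagged day) occurs, so its final length can exceed the window and its
#' size can exceed the window minimum. Runs whose member count falls below
#' `min_cases` (possible only in pathological overlaps) are discarded. Every
#' case belongs to at most one cluster; the rest are non-cluster cases.
#'
#' @param counts the `daily_counts` the flags were computed from.
#' @param flags logical per-day flags from [flag_cluster_days()].
#' @param cases the `case_table` behind `counts`, or `NULL` when only counts
#'   exist (member ids are then omitted but sizes/durations are still exact).
#' @param params the [cluster_params()] used for flagging.
#' @return a `temporal_clusters` object: a data.frame with one row per
#'   cluster (`start_day`, `end_day`, `size`, `duration_days`, `case_ids` as
#'   a comma-joined string) plus attributes `assignment` (per-case cluster
#'   index, `NA` = non-cluster; named by case_id when `cases` given) and
#'   `params`.
#' @export
extract_clusters <- function(counts, flags, cases = NULL,
                             params = cluster_params()) {
  stopifnot(inherits(counts, "daily_counts"))
  if (length(flags) != length(counts$counts))
    stop_kd("flags length %d != counts length %d", length(flags),
            length(counts$counts), class = "validation_error")
  r <- rle(as.logical(flags))
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep_runs <- which(r$values)

  dates <- counts$dates
  if (!is.null(cases)) {
    case_day <- as.integer(cases$onset_date - counts$period$start) + 1L
    ids <- cases$case_id
  } else {
    # expand counts into synthetic per-case day indices
    case_day <- rep(seq_along(counts$counts), counts$counts)
    ids <- as.character(seq_along(case_day))
  }
  assignment <- rep(NA_integer_, length(case_day))

  rows <- list()
  k <- 0L
  for (ri in keep_runs) {
    s <- run_start[ri]; e <- run_end[ri]
    member <- which(case_day >= s & case_day <= e)
    if (length(member) < params$min_cases) next
    k <- k + 1L
    assignment[member] <- k
    rows[[k]] <- data.frame(
      cluster = k,
      start_day = dates[s], end_day = dates[e],
      size = length(member),
      duration_days = e - s + 1L,
      case_ids = paste(ids[member], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (k > 0L) do.call(rbind, rows) else
    data.frame(cluster = integer(), start_day = as.Date(character()),
               end_day = as.Date(character()), size = integer(),
               duration_days = integer(), case_ids = character(),
               stringsAsFactors = FALSE)
  names(assignment) <- ids
  structure(out, assignment = assignment, params = params,
            class = c("temporal_clusters", "data.frame"))
}

#' One-call cluster construction
#'
#' Convenience wrapper: [daily_counts()] then [flag_cluster_days()] then
#' [extract_clusters()].
#'
#' @param cases a `case_table`.
#' @param params a [cluster_params()].
#' @return a `temporal_clusters` object (see [extract_clusters()]).
#' @export
find_temporal_clusters <- function(cases, params = cluster_params()) {
  counts <- daily_counts(cases)
  flags <- flag_cluster_days(counts, params)
  extract_clusters(counts, flags, cases, params)
}

#' Cluster-size exceedance curve
#'
#' `n_exceeding[S]` counts clusters with strictly more than S member cases —
#' the curve used to compare observed clustering against the seasonal null
#' envelope.
#'
#' @param clusters a `temporal_clusters` object (or anything with a `size`
#'   column).
#' @param s_max largest S to tabulate (>= 1).
#' @return a `cluster_size_curve` data.frame with columns `s` (1..s_max) and
#'   `n_exceeding` (non-increasing).
#' @export
cluster_size_curve <- function(clusters, s_max = 20L) {
  assert_scalar_number(s_max, "s_max", min = 1)
  s <- seq_len(s_max)
  sizes <- clusters$size
  n_exceeding <- vapply(s, function(S) sum(sizes > S), integer(1))
  structure(data.frame(s = s, n_exceeding = n_exceeding),
            class = c("cluster_size_curve", "data.frame"))
}

#' Seasonal Monte Carlo null ensemble for the cluster construction
#'
#' Each replicate redistributes exactly `n_cases` onsets over the days of the
#' period by a multinomial draw with day probability proportional to the
#' monthly seasonal weight of the day's month (same number of cases, observed
#' seasonality, no further temporal structure), then reruns the full cluster
#' construction.
#'
#' @param n_cases number of onsets per replicate (the observed total).
#' @param profile 12 nonnegative monthly weights (Jan..Dec), e.g. from
#'   [seasonal_profile_from_counts()]; not all zero.
#' @param period a [study_period()].
#' @param params a [cluster_params()].
#' @param n_reps number of replicates (default 500).
#' @param seed integer seed; per-rep substreams are derived deterministically.
#' @param s_max largest cluster size tabulated in the per-rep curves.
#' @return a `seasonal_null_ensemble`: list with per-rep cluster counts
#'   (`n_clusters`), a reps x s_max matrix `curves` of exceedance counts,
#'   per-S `mean`/`sd`, and the generation settings.
#' @export
seasonal_null_ensemble <- function(n_cases, profile, period,
                                   params = cluster_params(),
                                   n_reps = 500L, seed = 1L, s_max = 20L) {
  assert_scalar_number(n_cases, "n_cases", min = 0)
  assert_scalar_number(n_reps, "n_reps", min = 1)
  if (length(profile) != 12L || any(profile < 0) || !any(profile > 0))
    stop_kd("profile must be 12 nonnegative monthly weights, not all zero",
            class = "validation_error")
  dates <- period_dates(period)
  p_day <- day_probabilities(dates, profile)
  n <- length(dates)

  n_clusters <- integer(n_reps)
  curves <- matrix(0L, nrow = n_reps, ncol = s_max)
  for (r in seq_len(n_reps)) {
    counts_r <- withr::with_seed(substream_seed(seed, r), {
      as.integer(stats::rmultinom(1L, size = n_cases, prob = p_day))
    })
    dc <- structure(list(period = period, dates = dates, counts = counts_r),
                    class = "daily_counts")
    cl <- extract_clusters(dc, flag_cluster_days(dc, params), NULL, params)
    n_clusters[r] <- nrow(cl)
    curves[r, ] <- cluster_size_curve(cl, s_max)$n_exceeding
  }
  structure(list(n_reps = as.integer(n_reps), s_values = seq_len(s_max),
                 n_clusters = n_clusters, curves = curves,
                 mean = colMeans(curves), sd = apply(curves, 2L, sd),
                 mean_n_clusters = mean(n_clusters),
                 sd_n_clusters = sd(n_clusters),
                 params = params, seed = seed),
            class = "seasonal_null_ensemble")
}

# day selection probabilities proportional to the month weight of each day
day_probabilities <- function(dates, profile) {
  m <- as.POSIXlt(dates)$mon + 1L
  p <- profile[m]
  p / sum(p)
}

#' @export
print.seasonal_null_ensemble <- function(x, ...) {
  cat(sprintf("<seasonal_null_ensemble> %d reps, mean clusters %.2f (sd %.2f)\n",
              x$n_reps, x$mean_n_clusters, x$sd_n_clusters))
  invisible(x)
}

#' Test observed clustering against the seasonal null
#'
#' Compares the observed cluster count (and exceedance curve) with the
#' Monte Carlo distribution two ways: (i) the t-statistic of the observed
#' value against the simulated mean and sd, with one- and two-sided p-values
#' (the simulated distribution's sidedness is not fixed by convention, so
#' both are reported); (ii) the empirical rank p-value
#' `(1 + #\{reps >= observed\}) / (n_reps + 1)`, overall and per S.
#'
#' @param observed a `temporal_clusters` object, or a list with elements
#'   `n_clusters` and optionally `curve` (a [cluster_size_curve()]).
#' @param ensemble a [seasonal_null_ensemble()].
#' @return a `cluster_excess_test` list: `observed_n_clusters`, `t_statistic`,
#'   `p_t_two_sided`, `p_t_upper`, `p_empirical`, `degenerate` flag, and a
#'   per-S data.frame `per_s` (`s`, `observed`, `null_mean`, `null_sd`,
#'   `p_empirical`).
#' @export
cluster_excess_test <- function(observed, ensemble) {
  stopifnot(inherits(ensemble, "seasonal_null_ensemble"))
  if (inherits(observed, "temporal_clusters")) {
    obs_n <- nrow(observed)
    obs_curve <- cluster_size_curve(observed, max(ensemble$s_values))
  } else {
    obs_n <- observed$n_clusters
    obs_curve <- observed$curve %||% NULL
  }
  mu <- ensemble$mean_n_clusters
  sg <- ensemble$sd_n_clusters
  degenerate <- !is.finite(sg) || sg == 0
  if (degenerate) {
    t_stat <- if (obs_n == mu) 0 else NA_real_
    p_t2 <- p_t1 <- NA_real_
  } else {
    t_stat <- (obs_n - mu) / sg
    df <- ensemble$n_reps - 1L
    p_t1 <- pt(t_stat, df = df, lower.tail = FALSE)
    p_t2 <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  }
  p_emp <- (1 + sum(ensemble$n_clusters >= obs_n)) / (ensemble$n_reps + 1)

  per_s <- NULL
  if (!is.null(obs_curve)) {
    ge <- colSums(ensemble$curves >=
                    matrix(obs_curve$n_exceeding, nrow = ensemble$n_reps,
                           ncol = length(ensemble$s_values), byrow = TRUE))
    per_s <- data.frame(s = ensemble$s_values,
                        observed = obs_curve$n_exceeding,
                        null_mean = ensemble$mean, null_sd = ensemble$sd,
                        p_empirical = (1 + ge) / (ensemble$n_reps + 1))
  }
  structure(list(observed_n_clusters = obs_n, null_mean = mu, null_sd = sg,
                 t_statistic = t_stat, p_t_two_sided = p_t2, p_t_upper = p_t1,
                 p_empirical = p_emp, degenerate = degenerate, per_s = per_s,
                 n_reps = ensemble$n_reps),
            class = "cluster_excess_test")
}

#' @export
print.cluster_excess_test <- function(x, ...) {
  cat(sprintf(paste0("<cluster_excess_test> observed %d clusters vs null ",
                     "%.2f (sd %.2f): t = %.2f, p[t, upper] = %.4g, ",
                     "p[empirical] = %.4g%s\n"),
              x$observed_n_clusters, x$null_mean, x$null_sd,
              x$t_statistic, x$p_t_upper, x$p_empirical,
              if (x$degenerate) " [degenerate null: empirical p only]" else ""))
  invisible(x)
}
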