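# Fixtures and independent brute-force oracles. Oracles deliberately use
# naive loops and none of the package's vectorized code paths.

table1_period <- function() study_period("2010-01-01", "2010-01-22")

# the 22-day worked example: onsets on days 1,2,2,3,9,15,15,16,17,18
table1_cases <- function() {
  read_cases(system.file("extdata", "table1_cases.csv",
                         package = "kdspacetime"),
             table1_period())
}

table1_counts_expected <- c(1, 2, 1, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0,
                            2, 1, 1, 1, 0, 0, 0, 0)
table1_flags_expected <- as.logical(as.integer(strsplit(
  "1111111000111111111110", "")[[1]]))

# random small case table for property tests
random_case_table <- function(n, seed, span_days = 60, spread_deg = 0.5) {
  withr::with_seed(seed, {
    period <- study_period("2011-01-01", as.Date("2011-01-01") + span_days - 1)
    df <- data.frame(
      case_id = sprintf("r%03d", seq_len(n)),
      onset_date = as.Date("2011-01-01") + sample.int(span_days, n,
                                                      replace = TRUE) - 1L,
      lat = 32.7 + runif(n, -spread_deg, spread_deg),
      lon = -117.1 + runif(n, -spread_deg, spread_deg),
      age = rlnorm(n, 1, 0.6))
    case_table(df, period)
  })
}

# O(n^2) row-by-row Knox pair-count oracle with its own inline haversine
# (does not call any package code beyond the case-table columns)
oracle_close_pair_counts <- function(cases, tau, delta) {
  n <- nrow(cases)
  day <- as.numeric(cases$onset_date)
  phi <- cases$lat * pi / 180
  lam <- cases$lon * pi / 180
  X <- NT <- NS <- 0L
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    dt <- abs(day[i] - day[j])
    h <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    dk <- 2 * 6371 * asin(sqrt(pmin(pmax(h, 0), 1)))
    tc <- dt <= tau
    sc <- dk <= delta
    NT <- NT + sum(tc)
    NS <- NS + sum(sc)
    X <- X + sum(tc & sc)
  }
  list(X = X, n_time = NT, n_space = NS, n_pairs = (n * (n - 1L)) %/% 2L)
}

# per-day loop reimplementation of the two-stage cluster construction:
# returns the number of clusters in an integer counts vector
oracle_n_clusters <- function(counts, window = 7L, min_cases = 4L) {
  n <- length(counts)
  if (n < window) return(0L)
  flagged <- rep(FALSE, n)
  for (d in seq_len(n)) {
    for (s in max(1L, d - window + 1L):min(d, n - window + 1L)) {
      if (sum(counts[s:(s + window - 1L)]) >= min_cases) {
        flagged[d] <- TRUE
        break
      }
    }
  }
  k <- 0L
  d <- 1L
  while (d <= n) {
    if (flagged[d]) {
      e <- d
      while (e < n && flagged[e + 1L]) e <- e + 1L
      if (sum(counts[d:e]) >= min_cases) k <- k + 1L
      d <- e + 1L
    } else d <- d + 1L
  }
  k
}

# brute-force forward-window conditional medians (loop over cases)
oracle_conditional_medians <- function(cases, trait, window_days) {
  v <- cases[[trait]]
  day <- as.numeric(cases$onset_date)
  out <- list()
  for (i in seq_len(nrow(cases))) {
    if (is.na(v[i])) next
    sel <- which(day > day[i] & day <= day[i] + window_days & !is.na(v))
    sel <- setdiff(sel, i)
    if (!length(sel)) next
    out[[length(out) + 1L]] <- c(x = v[i], y = median(v[sel]))
  }
  do.call(rbind, out)
}

# tie-randomized empirical rank p: exactly uniform on {1..R+1}/(R+1) under
# exchangeability of (obs, reps)
randomized_rank_p <- function(obs, reps, u) {
  (1 + sum(reps > obs) + floor(u * (1 + sum(reps == obs)))) /
    (length(reps) + 1)
}
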