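# Excess Knox space-time interaction statistic and its permutation null.
#
# For thresholds (tau, delta), X counts unordered case pairs close in BOTH
# time (|dt| <= tau days) and space (great-circle distance <= delta km).
# Under independence of onset times and locations the expected count is
# E = N_T * N_S / M, and the excess statistic (X - E)/E measures relative
# space-time interaction. Significance comes from shuffling the multiset of
# case locations against the fixed onset dates, which leaves N_T, N_S and M
# unchanged and breaks any space-time dependence.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle (haversine) distance
#'
#' Distance in km on a sphere of radius 6371 km. Vectorized over coordinate
#' vectors (recycled as usual).
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (WGS84, treated
#'   spherically).
#' @return distance(s) in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)  # ~111.195 km, one degree along the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad; phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Knox threshold grids
#'
#' @param time_days strictly increasing positive temporal thresholds (days).
#' @param space_km strictly increasing positive spatial thresholds (km).
#'   Defaults cover the sub-monthly, 1-100 km range over which preferential
#'   scales of case clustering are sought.
#' @return a `knox_thresholds` object.
#' @export
knox_thresholds <- function(time_days = 1:30,
                            space_km = c(1, 2, 5, 10, 20, 50, 100)) {
  for (g in list(time_days, space_km))
    if (length(g) < 1L || any(g <= 0) || is.unsorted(g, strictly = TRUE))
      stop_kd("threshold grids must be positive and strictly increasing",
              class = "validation_error")
  structure(list(time_days = as.numeric(time_days),
                 space_km = as.numeric(space_km)),
            class = "knox_thresholds")
}

# unordered pair index vectors (i < j) for n cases
pair_indices <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L) + rep.int(0L:(n - 2L), (n - 1L):1L)
  list(i = i, j = j)
}

#' Close-pair counts at one threshold pair
#'
#' Over all unordered case pairs, counts pairs close in time
#' (`|onset_i - onset_j| <= tau`, inclusive, so same-day pairs are time-close
#' at any `tau >= 0`), close in space (great-circle `<= delta`), and close in
#' both.
#'
#' @param cases a `case_table` with >= 2 cases.
#' @param tau temporal threshold, days.
#' @param delta spatial threshold, km.
#' @return named list `X` (both-close), `n_time`, `n_space`, `n_pairs`
#'   (`= n(n-1)/2`).
#' @export
close_pair_counts <- function(cases, tau, delta) {
  n <- nrow(cases)
  if (n < 2L)
    stop_kd("close_pair_counts needs at least 2 cases, got %d", n,
            class = "validation_error")
  px <- pair_indices(n)
  dt <- abs(as.numeric(cases$onset_date[px$i] - cases$onset_date[px$j]))
  dk <- great_circle_km(cases$lat[px$i], cases$lon[px$i],
                        cases$lat[px$j], cases$lon[px$j])
  tc <- dt <= tau
  sc <- dk <= delta
  list(X = sum(tc & sc), n_time = sum(tc), n_space = sum(sc),
       n_pairs = length(dt))
}

#' Excess Knox statistic from close-pair counts
#'
#' `E = n_time * n_space / n_pairs` is the expected both-close count under
#' independence of times and locations; the excess is `(X - E)/E` (bounded
#' below by -1). When `E == 0` the statistic is undefined and returned as
#' `NA` with `undefined = TRUE` rather than an error.
#'
#' @param counts a list as returned by [close_pair_counts()].
#' @return list `expected`, `excess`, `undefined`.
#' @export
excess_knox <- function(counts) {
  if (counts$n_pairs < 1L)
    stop_kd("excess_knox needs n_pairs >= 1", class = "validation_error")
  E <- counts$n_time * counts$n_space / counts$n_pairs
  if (E == 0)
    return(list(expected = 0, excess = NA_real_, undefined = TRUE))
  list(expected = E, excess = (counts$X - E) / E, undefined = FALSE)
}

# Bin pair separations against threshold grids and accumulate the X count
# for every grid cell at once: cell (a, b) counts pairs with dt <= tau[a] and
# dk <= delta[b], i.e. a double cumulative sum of the 2-D bin histogram.
knox_grid_counts <- function(dt, dk, tau, delta) {
  bt <- findInterval(dt, tau, left.open = TRUE) + 1L   # first tau >= dt
  bs <- findInterval(dk, delta, left.open = TRUE) + 1L
  nt <- length(tau) + 1L; ns <- length(delta) + 1L
  h <- matrix(tabulate((bs - 1L) * nt + bt, nbins = nt * ns),
              nrow = nt, ncol = ns)
  x <- apply(apply(h, 2L, cumsum), 1L, cumsum)  # result is ns x nt
  t(x)[seq_along(tau), seq_along(delta), drop = FALSE]
}

#' Knox permutation test over a threshold grid
#'
#' Computes the excess Knox statistic at every (tau, delta) cell and its
#' upper-tail permutation p-value. Each replicate permutes the multiset of
#' case locations against the fixed onset dates (fixed points allowed); one
#' shared permutation serves all grid cells within a replicate, and the
#' pair-count invariants `n_time`, `n_space`, `n_pairs` are untouched by
#' construction. `p = (1 + #\{X_rep >= X_obs\}) / (n_reps + 1)`.
#'
#' @param cases a `case_table` with >= 2 cases.
#' @param thresholds a [knox_thresholds()].
#' @param n_reps number of permutation replicates (default 999).
#' @param seed integer seed.
#' @return a `knox_grid`: a long-format data.frame with one row per cell
#'   (`tau`, `delta`, `X`, `n_time`, `n_space`, `n_pairs`, `expected`,
#'   `excess`, `p_value`, `band` in `c("p<0.05", "0.05<p<0.15", "ns")`), with
#'   attributes `n_reps` and `seed`.
#' @export
knox_permutation_test <- function(cases, thresholds = knox_thresholds(),
                                  n_reps = 999L, seed = 1L) {
  stopifnot(inherits(thresholds, "knox_thresholds"))
  assert_scalar_number(n_reps, "n_reps", min = 1)
  n <- nrow(cases)
  if (n < 2L)
    stop_kd("knox_permutation_test needs at least 2 cases",
            class = "validation_error")
  tau <- thresholds$time_days; delta <- thresholds$space_km
  px <- pair_indices(n)
  day <- as.numeric(cases$onset_date - min(cases$onset_date))
  dt <- abs(day[px$i] - day[px$j])
  # full distance matrix: permuted pair distances are lookups into it
  dmat <- outer(seq_len(n), seq_len(n), function(a, b)
    great_circle_km(cases$lat[a], cases$lon[a], cases$lat[b], cases$lon[b]))
  dk_obs <- dmat[cbind(px$i, px$j)]

  x_obs <- knox_grid_counts(dt, dk_obs, tau, delta)
  # time-only and space-only marginals (permutation-invariant)
  n_time <- vapply(tau, function(tv) sum(dt <= tv), numeric(1))
  n_space <- vapply(delta, function(dv) sum(dk_obs <= dv), numeric(1))
  M <- length(dt)

  gt <- eq <- matrix(0L, nrow = length(tau), ncol = length(delta))
  for (r in seq_len(n_reps)) {
    perm <- withr::with_seed(substream_seed(seed, r), sample.int(n))
    dk_r <- dmat[cbind(perm[px$i], perm[px$j])]
    x_r <- knox_grid_counts(dt, dk_r, tau, delta)
    gt <- gt + (x_r > x_obs)
    eq <- eq + (x_r == x_obs)
  }
  p <- (1 + gt + eq) / (n_reps + 1)

  Emat <- outer(n_time, n_space) / M
  excess <- ifelse(Emat > 0, (x_obs - Emat) / Emat, NA_real_)
  grid <- expand.grid(tau = tau, delta = delta, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    tau = grid$tau, delta = grid$delta,
    X = as.vector(x_obs),
    n_time = rep(n_time, times = length(delta)),
    n_space = rep(n_space, each = length(tau)),
    n_pairs = M,
    expected = as.vector(Emat),
    excess = as.vector(excess),
    p_value = as.vector(p),
    # permutation tie structure: p = (1 + n_perm_gt + n_perm_eq)/(n_reps + 1);
    # n_perm_eq quantifies the conservatism of the rank p on a discrete X
    n_perm_gt = as.vector(gt),
    n_perm_eq = as.vector(eq))
  out$band <- ifelse(out$p_value < 0.05, "p<0.05",
                     ifelse(out$p_value < 0.15, "0.05<p<0.15", "ns"))
  structure(out, n_reps = as.integer(n_reps), seed = seed,
            thresholds = thresholds,
            class = c("knox_grid", "data.frame"))
}

#' @export
print.knox_grid <- function(x, ...) {
  cat(sprintf("<knox_grid> %d cells (%d tau x %d delta), %d permutations\n",
              nrow(x), length(unique(x$tau)), length(unique(x$delta)),
              attr(x, "n_reps")))
  best <- x[which.min(x$p_value), , drop = FALSE]
  cat(sprintf("  min p = %.4g at tau = %g d, delta = %g km (excess %.2f)\n",
              best$p_value, best$tau, best$delta, best$excess))
  invisible(x)
}
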