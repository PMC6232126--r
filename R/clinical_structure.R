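# Temporal and spatial structure of clinical traits.
#
# Temporal: for each reference case, the median trait value among cases with
# onset in the 10 days strictly after the reference's onset (half-open
# window (t, t + w]; the reference sits immediately prior to the interval,
# so same-day cases are excluded). Regressing the forward-window median on
# the reference's own trait value tests whether the trait is autocorrelated
# in time. Spatial: a label-permutation Monte Carlo on the mean pairwise
# distance among trait-positive cases.

#' Forward-window conditional medians of a clinical trait
#'
#' For each case i with a non-missing trait, the point
#' `(x = trait_i, y = median trait over cases with onset in
#' (onset_i, onset_i + window_days])` is emitted; the reference itself and
#' same-day cases are excluded, as is any case whose forward window holds no
#' non-missing trait values. Set `include_reference_day = TRUE` for the
#' closed-window variant `[onset_i, onset_i + window_days]` (other same-day
#' cases included, reference still excluded).
#'
#' @param cases a `case_table`.
#' @param trait one of `"age"`, `"esr"`, `"anc"`, `"crp"`.
#' @param window_days forward window length in days (default 10).
#' @param include_reference_day include other cases sharing the reference's
#'   onset day (default `FALSE`).
#' @return a `conditional_medians` data.frame with columns `case_id`, `x`
#'   (reference trait), `y` (forward-window median), `n_in_window`.
#' @export
conditional_window_medians <- function(cases, trait, window_days = 10L,
                                       include_reference_day = FALSE) {
  if (!trait %in% names(cases))
    stop_kd("trait '%s' is not a column of the case table", trait,
            class = "schema_error")
  assert_scalar_number(window_days, "window_days", min = 1)
  v <- cases[[trait]]
  have <- which(!is.na(v))
  if (length(have) < 2L)
    stop_kd("trait '%s' present for fewer than 2 cases", trait,
            class = "validation_error")
  day <- as.numeric(cases$onset_date)
  lo_open <- !include_reference_day
  rows <- lapply(have, function(i) {
    lower_ok <- if (lo_open) day > day[i] else day >= day[i]
    in_win <- which(lower_ok & day <= day[i] + window_days & !is.na(v))
    in_win <- setdiff(in_win, i)
    if (!length(in_win)) return(NULL)
    data.frame(case_id = cases$case_id[i], x = v[i],
               y = median(v[in_win]), n_in_window = length(in_win),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(case_id = character(), x = numeric(), y = numeric(),
               n_in_window = integer(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  structure(out, trait = trait, window_days = as.integer(window_days),
            class = c("conditional_medians", "data.frame"))
}

#' Bin conditional-median points by reference value
#'
#' Per half-open bin `[e_k, e_{k+1})` of the reference value x, the median of
#' the forward-window medians y; empty bins are omitted.
#'
#' @param points a [conditional_window_medians()] result (or any data.frame
#'   with `x`, `y`).
#' @param bin_edges sorted, strictly increasing edges; `"unit"` gives
#'   unit-width bins spanning the x range (used for age), `"deciles"` gives
#'   decile edges of x (used for ESR/ANC).
#' @return data.frame `bin_lo`, `bin_hi`, `x_mid`, `y_median`, `n`.
#' @export
bin_medians <- function(points, bin_edges = "unit") {
  if (nrow(points) < 1L)
    stop_kd("bin_medians needs at least one point", class = "validation_error")
  x <- points$x
  if (identical(bin_edges, "unit")) {
    bin_edges <- seq(floor(min(x)), ceiling(max(x)) + 1)
  } else if (identical(bin_edges, "deciles")) {
    bin_edges <- unique(stats::quantile(x, probs = seq(0, 1, 0.1),
                                        names = FALSE))
    bin_edges[length(bin_edges)] <- bin_edges[length(bin_edges)] + 1e-9
  }
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop_kd("bin edges must be strictly increasing", class = "validation_error")
  b <- findInterval(x, bin_edges, left.open = FALSE)
  ok <- b >= 1L & b < length(bin_edges)
  rows <- lapply(sort(unique(b[ok])), function(k) {
    sel <- ok & b == k
    data.frame(bin_lo = bin_edges[k], bin_hi = bin_edges[k + 1L],
               x_mid = (bin_edges[k] + bin_edges[k + 1L]) / 2,
               y_median = median(points$y[sel]), n = sum(sel))
  })
  do.call(rbind, rows)
}

#' OLS regression of forward-window medians on reference values
#'
#' Ordinary least squares of y on x with a two-sided test of nonzero slope.
#' The regression can be run on the fine per-case points or on the binned
#' medians (`x_mid`/`y_median`); both are legitimate summaries of the same
#' autocorrelation and give different R-squared, so the mode is explicit.
#'
#' @param data points (from [conditional_window_medians()]) or bins (from
#'   [bin_medians()]).
#' @param mode `"points"` or `"bins"`.
#' @return list `slope`, `intercept`, `r_squared`, `p_slope`, `n`, `mode`.
#' @export
trait_slope_regression <- function(data, mode = c("points", "bins")) {
  mode <- match.arg(mode)
  x <- if (mode == "points") data$x else data$x_mid
  y <- if (mode == "points") data$y else data$y_median
  if (length(x) < 3L)
    stop_kd("trait_slope_regression needs >= 3 %s", mode,
            class = "insufficient_data_error")
  if (length(unique(x)) < 2L || sd(x) == 0)
    stop_kd("zero variance in x: regression is degenerate",
            class = "degenerate_input_error")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = sm$r.squared,
       p_slope = sm$coefficients["x", "Pr(>|t|)"],
       n = length(x), mode = mode)
}

#' Spatial Monte Carlo test of a binary trait's clustering
#'
#' Observed statistic: mean pairwise great-circle distance among
#' label-positive cases. Null: the same statistic after randomly permuting
#' the labels over cases (label counts preserved). Lower tail — spatial
#' clustering of positives means unusually short distances:
#' `p = (1 + #\{rep <= observed\}) / (n_reps + 1)`.
#'
#' @param cases a `case_table`.
#' @param label name of a logical column (default `"ggt_elevated"`); `NA`
#'   labels are dropped.
#' @param n_reps permutation replicates (default 999).
#' @param seed integer seed.
#' @return a `spatial_label_test`: list with `trait`, `statistic_name`,
#'   `observed` (km), `null_reps`, `p_value`, `n_positive`, `n_reps`, `seed`.
#' @export
spatial_label_permutation_test <- function(cases, label = "ggt_elevated",
                                           n_reps = 999L, seed = 1L) {
  if (!label %in% names(cases))
    stop_kd("label '%s' is not a column of the case table", label,
            class = "schema_error")
  assert_scalar_number(n_reps, "n_reps", min = 1)
  keep <- !is.na(cases[[label]])
  lab <- as.logical(cases[[label]][keep])
  lat <- cases$lat[keep]; lon <- cases$lon[keep]
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos < 2L || n_neg < 2L)
    stop_kd("need >= 2 positive and >= 2 negative labels (have %d / %d)",
            n_pos, n_neg, class = "validation_error")
  n <- length(lab)
  dmat <- outer(seq_len(n), seq_len(n), function(a, b)
    great_circle_km(lat[a], lon[a], lat[b], lon[b]))

  mean_pos_dist <- function(pos_idx) {
    sub <- dmat[pos_idx, pos_idx]
    mean(sub[upper.tri(sub)])
  }
  observed <- mean_pos_dist(which(lab))
  null_reps <- vapply(seq_len(n_reps), function(r) {
    pos <- withr::with_seed(substream_seed(seed, r),
                            sample.int(n, n_pos))
    mean_pos_dist(pos)
  }, numeric(1))
  p <- (1 + sum(null_reps <= observed)) / (n_reps + 1)
  structure(list(trait = label,
                 statistic_name = "mean_pairwise_distance_km_positives",
                 observed = observed, null_reps = null_reps, p_value = p,
                 n_positive = n_pos, n_reps = as.integer(n_reps), seed = seed),
            class = "spatial_label_test")
}

#' @export
print.spatial_label_test <- function(x, ...) {
  cat(sprintf("<spatial_label_test> %s: observed %s = %.2f km over %d positives, p = %.4g (%d reps)\n",
              x$trait, x$statistic_name, x$observed, x$n_positive,
              x$p_value, x$n_reps))
  invisible(x)
}
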