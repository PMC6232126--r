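#' @importFrom stats median qt pt sd rnorm rpois rbinom rgamma rlnorm runif
#'   complete.cases lm coef filter
#' @importFrom utils head tail
NULL

# Internal helpers shared across modules. All randomness in the package goes
# through substream_seed() + withr::with_seed(): callers pass one integer seed
# and every component derives its own reproducible substream; the global
# .Random.seed is never left modified.

#' Derive a deterministic substream seed
#'
#' Maps a (seed, stream index) pair to a new 31-bit seed via a multiplicative
#' hash, so independent pipeline stages fed from one master seed do not share
#' a random stream.
#'
#' @param seed integer master seed.
#' @param stream integer stream index (>= 0).
#' @return a single integer in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- (abs(as.numeric(seed)) %% m)
  for (k in seq_len(stream + 1L)) {
    s <- (s * 48271 + 11 + 97 * k) %% m
  }
  as.integer(s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_kd <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "kdspacetime_error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop_kd("`%s` must be a finite number in [%s, %s]", name, min, max,
            class = "validation_error")
  invisible(x)
}

# month lengths ignoring leap years; used for day-of-year-365 indexing
.MONTH_DAYS_NOLEAP <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.CUM_MONTH_NOLEAP <- c(0L, cumsum(.MONTH_DAYS_NOLEAP))[1:12]

#' Day-of-year on a 365-day calendar
#'
#' Maps dates to day-of-year 1..365 with non-leap indexing: Mar 1 is always
#' day 60, and Feb 29 returns `NA` (its climatology is handled separately).
#'
#' @param dates a `Date` vector.
#' @return integer vector, `NA` on Feb 29.
#' @keywords internal
doy365 <- function(dates) {
  lt <- as.POSIXlt(dates)
  m <- lt$mon + 1L
  d <- lt$mday
  out <- .CUM_MONTH_NOLEAP[m] + d
  out[m == 2L & d == 29L] <- NA_integer_
  as.integer(out)
}
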