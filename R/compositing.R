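# Ten-day median compositing and temporal gap filling.

#' Build fixed-interval median composites over a growing season
#'
#' Splits `season` into consecutive periods of `period_days` days anchored at
#' the season start (the last period is truncated at the season end) and, for
#' every pixel and band, takes the median of the unmasked observations whose
#' acquisition date falls in the period. An even number of observations
#' yields the mean of the two central values. Periods with no valid
#' observation for a pixel stay masked until [fill_gaps_linear()].
#'
#' @param stack A [reflectance_stack()].
#' @param season Length-2 `Date` (or coercible) vector: first and last day of
#'   the season to composite.
#' @param period_days Compositing interval in days (default 10).
#' @return A `composite_series`: list with `values` (`[row, col, band,
#'   period]` array), `periods` (tibble: `period`, `start`, `end`,
#'   `midpoint`, `mid_doy`), `fill_flag` (logical array, all `FALSE` here),
#'   `bands`, `geo`.
#' @export
median_composite <- function(stack, season, period_days = 10) {
  season <- as.Date(season)
  stopifnot(length(season) == 2, season[2] >= season[1])
  starts <- seq(season[1], season[2], by = period_days)
  ends <- pmin(starts + period_days - 1, season[2])
  periods <- tibble::tibble(
    period = seq_along(starts), start = starts, end = ends,
    midpoint = starts + (as.numeric(ends - starts)) / 2,
    mid_doy = as.numeric(format(starts + as.numeric(ends - starts) / 2, "%j"))
  )
  in_season <- stack$dates >= season[1] & stack$dates <= season[2]
  if (!any(in_season))
    stop("no stack dates fall within the requested season", call. = FALSE)

  d <- dim(stack$values)
  vals <- array(NA_real_, c(d[1], d[2], d[3], nrow(periods)))
  for (p in seq_len(nrow(periods))) {
    sel <- which(stack$dates >= periods$start[p] &
                   stack$dates <= periods$end[p])
    if (!length(sel)) next
    x <- stack$values[, , , sel, drop = FALSE]
    m <- matrix(x, nrow = d[1] * d[2] * d[3], ncol = length(sel))
    vals[, , , p] <- array(row_median(m), d[1:3])
  }
  structure(
    list(values = vals, periods = periods,
         fill_flag = array(FALSE, dim(vals)),
         bands = stack$bands, geo = stack$geo),
    class = "composite_series"
  )
}

# Vectorised per-row median with NA removal (independent of stats::median so
# the even-count midpoint convention is explicit).
row_median <- function(m) {
  n <- nrow(m)
  if (ncol(m) == 1) return(m[, 1])
  o <- order(row(m), m, na.last = TRUE)
  ms <- matrix(m[o], nrow = n, byrow = TRUE)
  k <- rowSums(!is.na(m))
  lo <- pmax((k + 1L) %/% 2L, 1L)
  hi <- pmax((k + 2L) %/% 2L, 1L)
  res <- (ms[cbind(seq_len(n), lo)] + ms[cbind(seq_len(n), hi)]) / 2
  res[k == 0L] <- NA_real_
  res
}

#' Fill temporal gaps in a composite series by linear interpolation
#'
#' Interior gaps (periods with no valid observation, between two valid
#' periods) are filled by linear interpolation against period midpoints;
#' leading and trailing gaps are filled by extending the nearest valid value.
#' Pixels/bands with no valid period at all stay masked; their count is
#' reported via a message and the `n_unfilled` attribute.
#'
#' @param series A `composite_series` from [median_composite()].
#' @return The series with gaps filled and `fill_flag` set to `TRUE`
#'   wherever a value was produced by interpolation/extension.
#' @export
fill_gaps_linear <- function(series) {
  d <- dim(series$values)
  np <- d[4]
  m <- matrix(series$values, nrow = prod(d[1:3]), ncol = np)
  xs <- as.numeric(series$periods$midpoint - series$periods$start[1])
  k <- rowSums(!is.na(m))
  need <- which(k >= 1L & k < np)
  for (i in need) {
    v <- m[i, ]
    ok <- !is.na(v)
    if (sum(ok) == 1L) {
      m[i, ] <- v[ok]
    } else {
      m[i, ] <- stats::approx(xs[ok], v[ok], xout = xs, rule = 2)$y
    }
  }
  filled <- array(m, d)
  series$fill_flag <- is.na(series$values) & !is.na(filled)
  n_unfilled <- sum(k == 0L)
  if (n_unfilled > 0)
    message(n_unfilled, " pixel-band series had no valid period and remain masked")
  series$values <- filled
  attr(series, "n_unfilled") <- n_unfilled
  series
}

#' @export
print.composite_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<composite_series> ", d[1], "x", d[2], " px, ", d[3], " bands, ",
      d[4], " periods ", as.character(x$periods$start[1]), "..",
      as.character(x$periods$end[d[4]]),
      " (", sum(x$fill_flag), " filled cells)\n", sep = "")
  invisible(x)
}

#' @export
dim.composite_series <- function(x) dim(x$values)
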