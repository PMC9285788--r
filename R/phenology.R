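#' Interpolate an irregular series to a daily time step
#'
#' Linear interpolation of (time, value) observations onto consecutive
#' daily stamps spanning the input range. Duplicate timestamps are averaged
#' with a warning.
#'
#' @param time Date (or coercible) observation times
#' @param value observed values
#' @return data.frame with `time` (Date, daily) and `value`
#' @export
to_daily <- function(time, value) {
  time <- as.Date(time)
  ok <- is.finite(value) & !is.na(time)
  time <- time[ok]; value <- value[ok]
  if (length(unique(time)) < 2L) stop("to_daily: need >= 2 distinct time points")
  if (anyDuplicated(time)) {
    warning("to_daily: duplicate timestamps averaged")
    agg <- tapply(value, time, mean)
    time <- as.Date(names(agg)); value <- as.numeric(agg)
  }
  o <- order(time)
  time <- time[o]; value <- value[o]
  days <- seq(min(time), max(time), by = "day")
  data.frame(
    time = days,
    value = stats::approx(as.numeric(time), value, as.numeric(days))$y
  )
}

#' Smooth a daily series with a Savitzky-Golay filter
#'
#' 15-day window, polynomial order 2, nearest-edge padding. The filter
#' reproduces polynomials up to its order exactly in the interior, so
#' constant and linear series pass through unchanged away from the edges.
#'
#' @param value daily values (length >= window)
#' @param window odd filter window, days
#' @param order polynomial order
#' @return smoothed values, same length
#' @export
smooth_series <- function(value, window = 15, order = 2) {
  n <- length(value)
  if (n < window) {
    stop("smooth_series: series shorter than the filter window (", window, ")")
  }
  h <- (window - 1) / 2
  padded <- c(rep(value[1], h), value, rep(value[n], h))
  out <- signal::sgolayfilt(padded, p = order, n = window)
  out[(h + 1):(h + n)]
}

#' Detect bloom phenology from a smoothed daily series
#'
#' Threshold/cumulative-sum algorithm on one annual window: anomalies are
#' the series minus the threshold (the window median times
#' `threshold_factor`, default 1.05); their cumulative sum is formed and
#' its gradient taken. Bloom initiation is the first day the gradient turns
#' positive and stays positive for more than `persistence_days`;
#' termination is the first later day it turns non-positive and stays so
#' for more than `persistence_days`; duration is the difference. A series
#' with no qualifying initiation returns an explicit no-bloom result.
#' Because the threshold is relative to the median, the result is invariant
#' to rescaling the series by a positive constant.
#'
#' @param time daily Date stamps
#' @param value smoothed daily values
#' @param window_start,window_end annual window (defaults: full series)
#' @param threshold_factor multiplicative threshold on the median
#' @param persistence_days days the gradient sign must persist (exceed)
#' @param community community label carried into the result (1 or 2)
#' @return object of class `phenology_metrics`: list with `bloom`,
#'   `initiation`, `termination`, `duration` (days), `window_start`,
#'   `window_end`, `community`
#' @export
detect_bloom <- function(time, value, window_start = min(time),
                         window_end = max(time), threshold_factor = 1.05,
                         persistence_days = 15, community = NA_integer_) {
  time <- as.Date(time)
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  keep <- time >= window_start & time <= window_end & is.finite(value)
  if (sum(keep) < 2L * persistence_days) {
    stop("detect_bloom: window not covered by the series")
  }
  t <- time[keep]; v <- value[keep]

  anom <- v - threshold_factor * stats::median(v)
  grad <- grad1(cumsum(anom))

  no_bloom <- structure(list(
    bloom = FALSE, initiation = as.Date(NA), termination = as.Date(NA),
    duration = NA_real_, window_start = window_start,
    window_end = window_end, community = community
  ), class = "phenology_metrics")

  # first index from which `sign` persists for more than persistence_days;
  # termination uses non-positive rather than strictly negative gradients so
  # that series with a hard zero floor (a community absent outside its
  # season) still terminate
  first_persistent <- function(sgn, from) {
    runs <- rle(if (sgn > 0) grad > 0 else grad <= 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- which(runs$values & starts >= from &
                   runs$lengths > persistence_days)
    if (length(hit)) starts[hit[1]] else NA_integer_
  }

  i0 <- first_persistent(+1, from = 1L)
  if (is.na(i0)) return(no_bloom)
  i1 <- first_persistent(-1, from = i0)

  structure(list(
    bloom = TRUE,
    initiation = t[i0],
    termination = if (is.na(i1)) as.Date(NA) else t[i1],
    duration = if (is.na(i1)) NA_real_ else as.numeric(t[i1] - t[i0]),
    window_start = window_start, window_end = window_end,
    community = community
  ), class = "phenology_metrics")
}

#' @export
print.phenology_metrics <- function(x, ...) {
  if (!x$bloom) {
    cat("<phenology_metrics> no bloom detected\n")
  } else {
    cat(sprintf(
      "<phenology_metrics> community %s: initiation %s, termination %s, duration %.0f d\n",
      ifelse(is.na(x$community), "?", x$community),
      format(x$initiation), format(x$termination), x$duration
    ))
  }
  invisible(x)
}

#' Column-integrated chlorophyll time series for one community
#'
#' For each fitted profile, reconstructs the requested community's
#' chlorophyll in mg m^-3 from the partition parameters and
#' trapezoid-integrates it down to 6.9 optical depths (`z = 6.9/Kd`,
#' 1.5 times the euphotic depth). A one-community profile contributes zero
#' to the community-2 series.
#'
#' @param fits list of `chl_partition` objects
#' @param times vector of profile times (same length)
#' @param community 1 or 2
#' @param tau_limit integration bound in optical depths
#' @param dz evaluation grid spacing, m
#' @return data.frame with `time` and `value` (mg m^-2)
#' @export
community_series <- function(fits, times, community, tau_limit = 6.9,
                             dz = 0.5) {
  community <- as.character(community)
  stopifnot(community %in% c("1", "2"), length(fits) == length(times))
  value <- vapply(fits, function(f) {
    if (is.null(f)) return(NA_real_)
    z_lim <- tau_limit / f$Kd
    z <- seq(0, z_lim, by = dz)
    if (z[length(z)] < z_lim) z <- c(z, z_lim)
    chl <- reconstruct_chl(z, f, community = community)
    trapz(z, chl)
  }, numeric(1))
  df <- data.frame(time = times, value = value)
  df[order(df$time), ]
}
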