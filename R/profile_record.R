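#' Construct a single-cycle profile record
#'
#' A `profile_record` holds one float cycle: position and time plus the
#' depth-resolved physics (temperature, salinity, pressure), optics (bbp at
#' 700 nm, PAR) and biology (chlorophyll-a) arrays. Missing values are
#' explicit `NA`s, never silent zeros. Depth must be strictly increasing and
#' non-negative, and every depth-resolved array must have the same length.
#'
#' @param cycle_id integer cycle number
#' @param time POSIXct UTC timestamp of the profile
#' @param latitude degrees north
#' @param longitude degrees east
#' @param depth depth grid, m, strictly increasing, >= 0
#' @param pressure sea pressure, dBar (optional; derived from depth if NULL)
#' @param temperature deg C
#' @param salinity PSU
#' @param chl adjusted chlorophyll-a, mg m^-3
#' @param bbp700 adjusted particle backscattering at 700 nm, m^-1
#' @param par instantaneous PAR, umol quanta m^-2 s^-1 (optional)
#' @param oxygen dissolved oxygen, umol kg^-1 (optional)
#' @param truth optional list of generator ground-truth parameters
#' @return object of class `profile_record`
#' @export
profile_record <- function(cycle_id, time, latitude, longitude, depth,
                           pressure = NULL, temperature = NULL,
                           salinity = NULL, chl = NULL, bbp700 = NULL,
                           par = NULL, oxygen = NULL, truth = NULL) {
  n <- length(depth)
  if (n < 2L) stop("profile_record: need at least 2 depth levels")
  if (any(!is.finite(depth)) || any(depth < 0)) {
    stop("profile_record: depth must be finite and >= 0")
  }
  if (any(diff(depth) <= 0)) {
    stop("profile_record: depth must be strictly increasing")
  }
  chk <- function(x, name) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (length(x) != n) {
      stop("profile_record: '", name, "' length ", length(x),
           " != depth length ", n)
    }
    as.numeric(x)
  }
  structure(list(
    cycle_id = as.integer(cycle_id),
    time = as.POSIXct(time, tz = "UTC"),
    latitude = as.numeric(latitude),
    longitude = as.numeric(longitude),
    depth = as.numeric(depth),
    pressure = chk(pressure, "pressure"),
    temperature = chk(temperature, "temperature"),
    salinity = chk(salinity, "salinity"),
    chl = chk(chl, "chl"),
    bbp700 = chk(bbp700, "bbp700"),
    par = chk(par, "par"),
    oxygen = chk(oxygen, "oxygen"),
    truth = truth
  ), class = "profile_record")
}

#' @export
print.profile_record <- function(x, ...) {
  cat(sprintf(
    "<profile_record> cycle %d  %s  (%.3f N, %.3f E)\n  %d levels, %.0f-%.0f m; chl: %d, bbp700: %d, PAR: %d valid\n",
    x$cycle_id, format(x$time, "%Y-%m-%d %H:%M UTC"), x$latitude, x$longitude,
    length(x$depth), min(x$depth), max(x$depth),
    sum(is.finite(x$chl)), sum(is.finite(x$bbp700)), sum(is.finite(x$par))
  ))
  invisible(x)
}
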