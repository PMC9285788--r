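#' EOS-80 seawater routines
#'
#' Classical UNESCO (1983) polynomials for in-situ density, potential
#' temperature and the pressure-to-depth conversion, as used throughout
#' physical oceanography before TEOS-10. Inputs are practical salinity (PSU),
#' in-situ temperature (deg C, IPTS-68) and sea pressure (dBar).
#'
#' @name eos80
#' @keywords internal
NULL

#' Gravity at latitude (surface value, m s^-2)
#' @param latitude degrees north
#' @keywords internal
#' @noRd
sw_gravity <- function(latitude) {
  x <- sin(latitude * pi / 180)^2
  9.780318 * (1 + (5.2788e-3 + 2.36e-5 * x) * x)
}

#' Convert sea pressure to depth
#'
#' Fofonoff & Millard (UNESCO 1983) formula with latitude-dependent gravity.
#' At 0 dBar the depth is exactly 0 m and the mapping is strictly monotone.
#'
#' @param pressure sea pressure, dBar (vector)
#' @param latitude latitude, degrees north (scalar)
#' @return depth in metres, positive downwards
#' @export
#' @examples
#' pressure_to_depth(c(0, 100, 1000), 30)
pressure_to_depth <- function(pressure, latitude) {
  stopifnot(is.numeric(pressure), length(latitude) == 1L, is.finite(latitude))
  if (any(pressure < 0, na.rm = TRUE)) {
    stop("pressure must be non-negative (sea pressure in dBar)")
  }
  p <- pressure
  num <- ((((-1.82e-15 * p + 2.279e-10) * p - 2.2512e-5) * p + 9.72659) * p)
  num / (sw_gravity(latitude) + 1.092e-6 * p)
}

#' Density of seawater at atmospheric pressure (Millero & Poisson 1981)
#' @keywords internal
#' @noRd
sw_dens0 <- function(S, T) {
  # density of standard mean ocean water (pure water)
  smow <- 999.842594 + (6.793952e-2 + (-9.095290e-3 +
    (1.001685e-4 + (-1.120083e-6 + 6.536332e-9 * T) * T) * T) * T) * T
  b <- 8.24493e-1 + (-4.0899e-3 + (7.6438e-5 +
    (-8.2467e-7 + 5.3875e-9 * T) * T) * T) * T
  c <- -5.72466e-3 + (1.0227e-4 - 1.6546e-6 * T) * T
  d <- 4.8314e-4
  smow + b * S + c * S^1.5 + d * S^2
}

#' Secant bulk modulus (UNESCO 1983)
#' @keywords internal
#' @noRd
sw_seck <- function(S, T, p) {
  pb <- p / 10 # dBar -> bar
  # pure water terms
  AW <- 3.239908 + (1.43713e-3 + (1.16092e-4 - 5.77905e-7 * T) * T) * T
  BW <- 8.50935e-5 + (-6.12293e-6 + 5.2787e-8 * T) * T
  KW <- 19652.21 + (148.4206 + (-2.327105 +
    (1.360477e-2 - 5.155288e-5 * T) * T) * T) * T
  # salinity terms
  A <- AW + (2.2838e-3 + (-1.0981e-5 - 1.6078e-6 * T) * T) * S +
    1.91075e-4 * S^1.5
  B <- BW + (-9.9348e-7 + (2.0816e-8 + 9.1697e-10 * T) * T) * S
  K0 <- KW + (54.6746 + (-0.603459 + (1.09987e-2 - 6.1670e-5 * T) * T) * T) * S +
    (7.944e-2 + (1.6483e-2 - 5.3009e-4 * T) * T) * S^1.5
  K0 + (A + B * pb) * pb
}

#' In-situ density of seawater (EOS-80)
#'
#' @param S practical salinity, PSU
#' @param T in-situ temperature, deg C
#' @param p sea pressure, dBar
#' @return density, kg m^-3; values outside the EOS-80 validity range
#'   (S in 0..42, T in -2..40) are masked to NA with a warning
#' @export
#' @examples
#' sw_dens(35, 10, 0) # about 1026.95
sw_dens <- function(S, T, p = 0) {
  n <- max(length(S), length(T), length(p))
  S <- rep_len(S, n); T <- rep_len(T, n); p <- rep_len(p, n)
  bad <- !is.na(S) & !is.na(T) & (S < 0 | S > 42 | T < -2 | T > 40)
  if (any(bad)) {
    warning(sum(bad), " sample(s) outside the EOS-80 S/T validity range; masked")
  }
  rho <- sw_dens0(S, T) / (1 - p / (10 * sw_seck(S, T, p)))
  rho[bad] <- NA_real_
  rho
}

#' Adiabatic temperature gradient (Bryden 1973), deg C / dBar
#' @keywords internal
#' @noRd
sw_adtg <- function(S, T, p) {
  ds <- S - 35
  (3.5803e-5 + (8.5258e-6 + (-6.836e-8 + 6.6228e-10 * T) * T) * T) +
    (1.8932e-6 - 4.2393e-8 * T) * ds +
    ((1.8741e-8 + (-6.7795e-10 + (8.733e-12 - 5.4481e-14 * T) * T) * T) +
      (-1.1351e-10 + 2.7759e-12 * T) * ds) * p +
    (-4.6206e-13 + (1.8676e-14 - 2.1687e-16 * T) * T) * p^2
}

#' Potential temperature (UNESCO 1983, Runge-Kutta integration)
#'
#' @param S salinity, PSU
#' @param T in-situ temperature, deg C
#' @param p sea pressure, dBar
#' @param pr reference pressure, dBar (default 0: surface)
#' @return potential temperature, deg C
#' @export
sw_ptmp <- function(S, T, p, pr = 0) {
  dp <- pr - p
  dth <- dp * sw_adtg(S, T, p)
  th <- T + 0.5 * dth
  q <- dth
  dth <- dp * sw_adtg(S, th, p + 0.5 * dp)
  th <- th + (1 - 1 / sqrt(2)) * (dth - q)
  q <- (2 - sqrt(2)) * dth + (-2 + 3 / sqrt(2)) * q
  dth <- dp * sw_adtg(S, th, p + 0.5 * dp)
  th <- th + (1 + 1 / sqrt(2)) * (dth - q)
  q <- (2 + sqrt(2)) * dth + (-2 - 3 / sqrt(2)) * q
  dth <- dp * sw_adtg(S, th, p + dp)
  th + (dth - 2 * q) / 6
}

#' Potential density referenced to the surface (sigma-theta + 1000)
#' @param S salinity, PSU
#' @param T in-situ temperature, deg C
#' @param p sea pressure, dBar
#' @return potential density, kg m^-3
#' @export
sw_pden <- function(S, T, p) {
  sw_dens(S, sw_ptmp(S, T, p, pr = 0), p = 0)
}
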