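#' Fit the diffuse attenuation coefficient Kd from a PAR profile
#'
#' Fits a Beer-Lambert light profile `PAR(z) = PAR(0) exp(-Kd z)` to the
#' instantaneous PAR samples in the top of the water column by linear least
#' squares on `ln(PAR)` versus depth, which is the closed-form solution for
#' multiplicative noise.
#'
#' @param depth depth, m
#' @param par instantaneous PAR, umol quanta m^-2 s^-1
#' @param max_depth only samples above this depth are used (default 100 m)
#' @return list with `Kd` (m^-1), `par0` (surface PAR from the fit intercept)
#'   and `n` (samples used)
#' @export
fit_kd <- function(depth, par, max_depth = 100) {
  ok <- is.finite(depth) & is.finite(par) & par > 0 & depth <= max_depth
  if (sum(ok) < 4L) {
    stop_skip("fit_kd: fewer than 4 usable PAR samples above ", max_depth,
              " m; use the empirical chlorophyll relation instead")
  }
  fit <- stats::lm(log(par[ok]) ~ depth[ok])
  kd <- -unname(stats::coef(fit)[2])
  if (!is.finite(kd) || kd <= 0) {
    stop_skip("fit_kd: non-positive attenuation (PAR does not decay with depth)")
  }
  list(Kd = kd, par0 = exp(unname(stats::coef(fit)[1])), n = sum(ok))
}

#' Empirical Kd from near-surface chlorophyll
#'
#' Linear relation between the diffuse attenuation coefficient and the mean
#' chlorophyll-a in the top 10 m, `Kd = 0.036 Bs10 + 0.049`, used when no
#' usable PAR profile is available (night-time or missing sensor).
#'
#' @param B_s10 mean chlorophyll-a in the top 10 m, mg m^-3
#' @param slope,intercept relation coefficients (m^-1 per mg m^-3, m^-1)
#' @return Kd, m^-1
#' @export
#' @examples
#' kd_from_chl(0) # 0.049, clearest-water intercept
kd_from_chl <- function(B_s10, slope = 0.036, intercept = 0.049) {
  if (any(!is.finite(B_s10)) || any(B_s10 < 0)) {
    stop("kd_from_chl: B_s10 must be finite and >= 0")
  }
  slope * B_s10 + intercept
}

#' Euphotic depth from Kd
#'
#' Depth of the 1% light level, `Z_p = 4.6 / Kd`.
#'
#' @param Kd diffuse attenuation coefficient, m^-1 (> 0)
#' @return euphotic depth, m
#' @export
euphotic_depth <- function(Kd) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) stop("euphotic_depth: Kd must be > 0")
  4.6 / Kd
}

#' Optical depth
#'
#' Dimensionless depth `tau = z * Kd`. By construction `tau(Z_p) = 4.6` and
#' `tau(1.5 Z_p) = 6.9`.
#'
#' @param z geometric depth, m
#' @param Kd diffuse attenuation coefficient, m^-1 (> 0)
#' @return optical depth (dimensionless)
#' @export
optical_depth <- function(z, Kd) {
  if (any(!is.finite(Kd)) || any(Kd <= 0)) stop("optical_depth: Kd must be > 0")
  z * Kd
}

#' Astronomical day length
#'
#' Day length from the standard solar-declination / hour-angle formula.
#'
#' @param doy day of year (1-366)
#' @param latitude degrees north
#' @return day length, hours
#' @export
day_length <- function(doy, latitude) {
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  cosh0 <- -tan(latitude * pi / 180) * tan(decl)
  cosh0 <- pmin(1, pmax(-1, cosh0))
  24 * acos(cosh0) / pi
}

#' Daily PAR integral from one instantaneous measurement
#'
#' Converts an instantaneous PAR value to a daily integral assuming a
#' sinusoidal light cycle: the day length `D` follows from solar declination
#' and latitude, the noon amplitude is inferred from the measurement's
#' position in the day, and the integral is `(2 D / pi) * E_noon`.
#' Measurements taken outside local daylight are disregarded (returns `NA`
#' with a warning), matching how night-time profiles are treated.
#'
#' @param par_instant instantaneous PAR, umol quanta m^-2 s^-1
#' @param time_utc POSIXct UTC time of measurement
#' @param latitude degrees north
#' @param longitude degrees east (used for local solar time)
#' @return daily PAR, mol quanta m^-2 d^-1 (NA for night-time input)
#' @export
daily_par <- function(par_instant, time_utc, latitude, longitude) {
  time_utc <- as.POSIXct(time_utc, tz = "UTC")
  doy <- as.integer(format(time_utc, "%j"))
  D <- day_length(doy, latitude)
  hod_utc <- as.numeric(format(time_utc, "%H")) +
    as.numeric(format(time_utc, "%M")) / 60 +
    as.numeric(format(time_utc, "%S")) / 3600
  local_solar <- (hod_utc + longitude / 15) %% 24
  t_since_rise <- local_solar - (12 - D / 2)
  if (!is.finite(t_since_rise) || t_since_rise <= 0 || t_since_rise >= D) {
    warning("daily_par: measurement outside local daylight; PAR disregarded")
    return(NA_real_)
  }
  e_noon <- par_instant / sin(pi * t_since_rise / D)
  # umol m^-2 s^-1 integrated over D hours -> mol m^-2 d^-1
  (2 * (D * 3600) / pi) * e_noon / 1e6
}

#' In-situ density profile (EOS-80)
#'
#' Thin wrapper over [sw_dens()] for aligned profile arrays.
#'
#' @param temperature deg C
#' @param salinity PSU
#' @param pressure dBar
#' @return in-situ density, kg m^-3
#' @export
density_profile <- function(temperature, salinity, pressure = 0) {
  sw_dens(salinity, temperature, pressure)
}

#' Brunt-Vaisala buoyancy frequency squared
#'
#' `N^2 = (g / rho) * d(rho)/dz` from adjacent differences of a (potential)
#' density profile, evaluated at layer midpoints; depth positive downwards so
#' density increasing with depth gives `N^2 > 0`.
#'
#' @param density (potential) density, kg m^-3
#' @param depth depth, m, strictly increasing
#' @param g gravitational acceleration, m s^-2
#' @return list with `depth` (layer midpoints, m) and `N2` (s^-2)
#' @export
brunt_vaisala <- function(density, depth, g = 9.81) {
  if (length(depth) < 2L) stop("brunt_vaisala: need at least 2 depths")
  if (any(diff(depth) <= 0)) stop("brunt_vaisala: depth must be increasing")
  drho <- diff(density)
  dz <- diff(depth)
  rho_mid <- (density[-1] + density[-length(density)]) / 2
  list(
    depth = (depth[-1] + depth[-length(depth)]) / 2,
    N2 = g / rho_mid * drho / dz
  )
}

#' Epipelagic stratification index
#'
#' Depth-weighted (trapezoid) mean of `N^2` over the layer shallower than a
#' limiting optical depth (default 6.9, i.e. 1.5 times the euphotic depth).
#'
#' @param N2 buoyancy frequency squared, s^-2
#' @param tau optical depth at the `N2` samples
#' @param tau_limit upper optical-depth bound of the averaged layer
#' @return mean N^2, s^-2
#' @export
stratification_index <- function(N2, tau, tau_limit = 6.9) {
  ok <- is.finite(N2) & is.finite(tau) & tau <= tau_limit
  if (!any(ok)) stop("stratification_index: no layers above tau limit")
  x <- tau[ok]; y <- N2[ok]
  if (sum(ok) == 1L) return(y)
  trapz(x, y) / (max(x) - min(x))
}

#' Mixed-layer depth
#'
#' Temperature-based mixed-layer depth. `method = "holte_talley_temp"`
#' follows the candidate-and-select logic of the Holte and Talley temperature
#' algorithm: a threshold candidate (departure of more than `threshold` deg C
#' from the 10 m reference temperature), a gradient candidate, and a fit
#' candidate (intersection of the mixed-layer and thermocline straight-line
#' fits); the fit candidate is chosen when it is consistent with the
#' threshold candidate (within 25%), otherwise the threshold candidate is
#' used. `method = "threshold"` returns the threshold candidate directly.
#'
#' A profile whose temperature range is below `threshold` is flagged fully
#' mixed and the deepest sampled depth is returned (attribute
#' `fully_mixed = TRUE`).
#'
#' @param temperature deg C
#' @param depth m, strictly increasing
#' @param salinity PSU (unused by the temperature algorithm; accepted for
#'   interface symmetry)
#' @param method "holte_talley_temp" or "threshold"
#' @param threshold temperature departure defining the layer, deg C
#' @param ref_depth reference depth, m
#' @return mixed-layer depth, m, with attribute `fully_mixed`
#' @export
mixed_layer_depth <- function(temperature, depth, salinity = NULL,
                              method = c("holte_talley_temp", "threshold"),
                              threshold = 0.2, ref_depth = 10) {
  method <- match.arg(method)
  ok <- is.finite(temperature) & is.finite(depth)
  temperature <- temperature[ok]; depth <- depth[ok]
  if (length(depth) < 3L || max(depth) <= ref_depth) {
    stop("mixed_layer_depth: profile does not reach below ", ref_depth, " m")
  }
  t_ref <- stats::approx(depth, temperature, ref_depth, rule = 2)$y
  if (diff(range(temperature)) < threshold) {
    return(structure(max(depth), fully_mixed = TRUE))
  }

  # threshold candidate: first crossing of |T - T(10 m)| > threshold,
  # linearly interpolated to the exact crossing depth
  dev <- abs(temperature - t_ref)
  below <- which(depth > ref_depth & dev > threshold)
  mld_thr <- if (length(below)) {
    i <- below[1]
    if (i > 1) {
      stats::approx(dev[(i - 1):i], depth[(i - 1):i], threshold)$y
    } else {
      depth[i]
    }
  } else {
    max(depth)
  }
  if (method == "threshold") {
    fm <- !length(below)
    return(structure(mld_thr, fully_mixed = fm))
  }

  # gradient candidate
  grad <- diff(temperature) / diff(depth)
  zmid <- (depth[-1] + depth[-length(depth)]) / 2
  strong <- which(zmid > ref_depth & abs(grad) > 0.005)
  mld_grad <- if (length(strong)) zmid[strong[1]] else zmid[which.max(abs(grad))]

  # fit candidate: horizontal mixed-layer line through the near-surface mean,
  # thermocline line tangent at the maximum-gradient point
  in_ml <- depth <= max(ref_depth, min(mld_thr, mld_grad) * 0.75)
  if (sum(in_ml) < 2L) in_ml <- seq_len(2L)
  t_ml <- mean(temperature[in_ml])
  imax <- which.max(abs(grad))
  slope <- grad[imax]
  z0 <- zmid[imax]
  t0 <- stats::approx(depth, temperature, z0, rule = 2)$y
  mld_fit <- if (abs(slope) > 1e-10) z0 + (t_ml - t0) / slope else mld_thr
  mld_fit <- min(max(mld_fit, min(depth)), max(depth))

  chosen <- if (is.finite(mld_fit) && abs(mld_fit - mld_thr) <= 0.25 * mld_thr) {
    mld_fit
  } else {
    mld_thr
  }
  structure(chosen, fully_mixed = FALSE)
}

#' Mean daily PAR over a depth layer
#'
#' Layer average of the Beer-Lambert light profile
#' `PAR(z) = PAR(0) exp(-Kd z)`, evaluated analytically:
#' `PAR(0) (exp(-Kd z_top) - exp(-Kd z_bottom)) / (Kd (z_bottom - z_top))`.
#' A degenerate layer (`z_top == z_bottom`) returns the point value.
#'
#' @param par_daily_surface daily PAR just below the surface,
#'   mol quanta m^-2 d^-1
#' @param Kd diffuse attenuation coefficient, m^-1 (> 0)
#' @param z_top,z_bottom layer bounds, m, `0 <= z_top <= z_bottom`
#' @return mean daily PAR over the layer, mol quanta m^-2 d^-1
#' @export
mean_light <- function(par_daily_surface, Kd, z_top, z_bottom) {
  if (!is.finite(Kd) || Kd <= 0) stop("mean_light: Kd must be > 0")
  if (z_top < 0 || z_bottom < z_top) {
    stop("mean_light: need 0 <= z_top <= z_bottom")
  }
  if (z_bottom == z_top) {
    return(par_daily_surface * exp(-Kd * z_top))
  }
  par_daily_surface * (exp(-Kd * z_top) - exp(-Kd * z_bottom)) /
    (Kd * (z_bottom - z_top))
}

#' Derive the per-profile optical and physical context
#'
#' Computes the scalar context a profile's partition needs: the diffuse
#' attenuation coefficient `Kd` (Beer-Lambert fit to PAR where available and
#' collected in daylight, otherwise the empirical chlorophyll relation), the
#' euphotic depth `Z_p = 4.6/Kd`, surface chlorophyll `B_s` (median over the
#' first optical depth after discarding values below 0.01 mg m^-3), surface
#' backscattering `b_bp_s` (median over the first optical depth), the
#' mixed-layer depth `Z_m`, the stratification index (mean Brunt-Vaisala
#' `N^2` above 6.9 optical depths, from potential density referenced to the
#' surface), and the mean daily PAR in and below the mixed layer.
#'
#' @param profile a [profile_record()]
#' @param kd_fit_max_depth PAR samples above this depth enter the Kd fit, m
#' @param empirical_kd_slope,empirical_kd_intercept coefficients of the
#'   empirical Kd fallback relation
#' @param mld_method,mld_threshold passed to [mixed_layer_depth()]
#' @param strat_tau_limit optical-depth bound of the stratification index
#' @return object of class `optical_context`
#' @export
derive_context <- function(profile,
                           kd_fit_max_depth = 100,
                           empirical_kd_slope = 0.036,
                           empirical_kd_intercept = 0.049,
                           mld_method = "holte_talley_temp",
                           mld_threshold = 0.2,
                           strat_tau_limit = 6.9) {
  z <- profile$depth
  chl_ok <- is.finite(profile$chl)
  B_s10 <- if (any(chl_ok & z <= 10)) {
    mean(profile$chl[chl_ok & z <= 10])
  } else {
    NA_real_
  }

  kd_fit <- NULL
  par_day0 <- NA_real_
  Kd_source <- "empirical"
  if (any(is.finite(profile$par))) {
    kd_fit <- tryCatch(
      fit_kd(z, profile$par, max_depth = kd_fit_max_depth),
      phytopart_skip = function(e) NULL
    )
  }
  if (!is.null(kd_fit)) {
    Kd <- kd_fit$Kd
    Kd_source <- "fitted"
    par_day0 <- suppressWarnings(
      daily_par(kd_fit$par0, profile$time, profile$latitude, profile$longitude)
    )
  } else {
    if (!is.finite(B_s10)) {
      stop_skip("derive_context: neither PAR nor near-surface chlorophyll available")
    }
    Kd <- kd_from_chl(B_s10, empirical_kd_slope, empirical_kd_intercept)
  }

  Z_p <- euphotic_depth(Kd)
  tau <- optical_depth(z, Kd)

  surf <- chl_ok & tau <= 1 & profile$chl >= 0.01
  B_s <- if (any(surf)) stats::median(profile$chl[surf]) else NA_real_
  bbp_ok <- is.finite(profile$bbp700)
  b_bp_s <- if (any(bbp_ok & tau <= 1)) {
    stats::median(profile$bbp700[bbp_ok & tau <= 1])
  } else {
    NA_real_
  }

  Z_m <- NA_real_
  fully_mixed <- NA
  ts_ok <- is.finite(profile$temperature)
  if (sum(ts_ok) >= 3L && max(z[ts_ok]) > 10) {
    mld <- mixed_layer_depth(profile$temperature[ts_ok], z[ts_ok],
                             method = mld_method, threshold = mld_threshold)
    Z_m <- as.numeric(mld)
    fully_mixed <- isTRUE(attr(mld, "fully_mixed"))
  }

  strat <- NA_real_
  den_ok <- is.finite(profile$temperature) & is.finite(profile$salinity)
  if (sum(den_ok) >= 2L) {
    p <- profile$pressure
    if (all(!is.finite(p))) p <- z # dBar ~ m to leading order
    pden <- sw_pden(profile$salinity[den_ok], profile$temperature[den_ok],
                    p[den_ok])
    bv <- brunt_vaisala(pden, z[den_ok])
    strat <- tryCatch(
      stratification_index(bv$N2, optical_depth(bv$depth, Kd), strat_tau_limit),
      error = function(e) NA_real_
    )
  }

  par_ml <- par_below_ml <- NA_real_
  if (is.finite(par_day0) && is.finite(Z_m)) {
    par_ml <- mean_light(par_day0, Kd, 0, Z_m)
    if (Z_m < Z_p) par_below_ml <- mean_light(par_day0, Kd, Z_m, Z_p)
  }

  structure(list(
    Kd = Kd, Kd_source = Kd_source,
    B_s = B_s, B_s10 = B_s10, b_bp_s = b_bp_s,
    Z_p = Z_p, Z_m = Z_m, fully_mixed = fully_mixed,
    strat_index = strat,
    par_day0 = par_day0, par_ml = par_ml, par_below_ml = par_below_ml
  ), class = "optical_context")
}

#' @export
print.optical_context <- function(x, ...) {
  cat(sprintf(
    "<optical_context> Kd=%.4f m-1 (%s)  Z_p=%.1f m  Z_m=%.1f m\n  B_s=%.3f mg m-3  b_bp_s=%.5f m-1  N2 index=%.3e s-2\n",
    x$Kd, x$Kd_source, x$Z_p, x$Z_m, x$B_s, x$b_bp_s, x$strat_index
  ))
  invisible(x)
}
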