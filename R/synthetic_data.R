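#' Generate one synthetic profile with known ground truth
#'
#' Forward-evaluates the two-community model: chlorophyll from the
#' sigmoid + Gaussian profile scaled by `B_s`, backscattering from the
#' partitioned model with a non-algal background, PAR from Beer-Lambert
#' decay, and a two-layer temperature structure producing the requested
#' mixed-layer depth. Noise is multiplicative Gaussian (fluorometric and
#' backscattering noise scale with signal). The generating parameters are
#' embedded in the record's `truth` field.
#'
#' @param params list with `P1`, `tau1` and optionally `B2m_star`, `tau2`,
#'   `sigma` (omit or set `B2m_star = 0` for a pure one-community profile);
#'   must lie in the model's admissible box (`P1` in 4.6..100,
#'   `tau2 >= 3 sigma`, `B2m_star` in 0..100)
#' @param Kd diffuse attenuation coefficient, m^-1
#' @param B_s surface chlorophyll, mg m^-3
#' @param b_bp_s surface backscattering, m^-1
#' @param bbpk_star,omega2 backscattering partition parameters
#' @param Zm mixed-layer depth, m
#' @param pressure pressure grid, dBar (default 0..300 by 1)
#' @param noise list of relative noise sigmas for `chl`, `bbp`, `par`
#' @param par0 surface instantaneous PAR, umol quanta m^-2 s^-1
#' @param T_surf,T_deep,S0 two-layer hydrography (deg C, deg C, PSU)
#' @param time,latitude,longitude,cycle_id record metadata
#' @param seed optional integer seed (fixed seed gives identical output)
#' @return a [profile_record()] with ground truth attached
#' @export
make_profile <- function(params, Kd, B_s, b_bp_s = 7e-4,
                         bbpk_star = 0.5, omega2 = 0.1, Zm = 50,
                         pressure = seq(0, 300, by = 1),
                         noise = list(chl = 0.05, bbp = 0.05, par = 0.02),
                         par0 = 1500, T_surf = 28, T_deep = 22, S0 = 39.5,
                         time = as.POSIXct("2016-06-15 09:00:00", tz = "UTC"),
                         latitude = 26, longitude = 36, cycle_id = 1L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (is.null(p$B2m_star)) p$B2m_star <- 0
  two <- p$B2m_star > 0
  if (!is.finite(p$P1) || p$P1 < 4.6 || p$P1 > 100 || p$tau1 <= 0) {
    stop("make_profile: inadmissible community-1 parameters")
  }
  if (two && (p$B2m_star > 100 || p$sigma <= 0 || p$tau2 < 3 * p$sigma)) {
    stop("make_profile: inadmissible community-2 parameters")
  }
  mode <- if (two) "two_community" else "one_community"

  z <- pressure_to_depth(pressure, latitude)
  tau <- optical_depth(z, Kd)
  b1 <- community1(tau, p$P1, p$tau1)
  b2 <- if (two) community2(tau, p$B2m_star, p$tau2, p$sigma) else 0 * tau

  mnoise <- function(sigma, n) {
    if (is.null(sigma) || sigma <= 0) rep(1, n) else 1 + stats::rnorm(n, 0, sigma)
  }
  n <- length(z)
  chl <- B_s * (b1 + b2) * mnoise(noise$chl, n)
  bbp_star <- (1 - bbpk_star) * b1 + (if (two) omega2 * b2 else 0) + bbpk_star
  bbp <- b_bp_s * bbp_star * mnoise(noise$bbp, n)
  par <- par0 * exp(-Kd * z) * mnoise(noise$par, n)

  # two-layer thermal structure: sharp (2 m wide) interface at Zm
  f <- 0.5 * (1 - tanh((z - Zm) / 2))
  temperature <- T_deep + (T_surf - T_deep) * f
  salinity <- rep(S0, n)

  profile_record(
    cycle_id = cycle_id, time = time, latitude = latitude,
    longitude = longitude, depth = z, pressure = pressure,
    temperature = temperature, salinity = salinity,
    chl = chl, bbp700 = bbp, par = par,
    truth = list(params = p, mode = mode, Kd = Kd, B_s = B_s,
                 b_bp_s = b_bp_s, bbpk_star = bbpk_star,
                 omega2 = if (two) omega2 else NA_real_,
                 Zm = Zm, par0 = par0)
  )
}

#' Default seasonal scenario specification
#'
#' Conditions emulating a northern Red Sea seasonal cycle: deep convective
#' mixing and elevated, vertically uniform chlorophyll in winter
#' (November-March), transitioning to a shallow summer mixed layer with a
#' deep chlorophyll maximum near 100 m. The winter mixing pulse is a
#' squared-cosine of day-of-year peaking in mid January; the subsurface
#' community is active from mid April to mid October with 15-day ramps.
#'
#' @param n_days profile cadence, days
#' @param start,end date range of the series
#' @param seed integer seed
#' @param ... override any default field
#' @return list of class `scenario_spec`
#' @export
scenario_spec <- function(n_days = 5, start = "2015-10-01", end = "2017-01-31",
                          seed = 42L, ...) {
  spec <- list(
    start = as.Date(start), end = as.Date(end), cadence_days = n_days,
    latitude = 26, longitude = 36,
    Zm_winter = 150, Zm_summer = 20,      # m
    Kd_winter = 0.075, Kd_summer = 0.05,  # m^-1
    B_s_winter = 0.45, B_s_summer = 0.08, # mg m^-3
    b_bp_s_winter = 9e-4, b_bp_s_summer = 5e-4, # m^-1
    bbpk_star = 0.5, omega2 = 0.1,
    B2m_max = 3, dcm_depth = 100, dcm_sigma = 0.8,
    c2_start_doy = 105, c2_end_doy = 288, c2_ramp_days = 15,
    noise = list(chl = 0.05, bbp = 0.05, par = 0.02),
    par0 = 1500, T_surf = 28, T_deep = 22, S0 = 39.5,
    seed = as.integer(seed)
  )
  dots <- list(...)
  spec[names(dots)] <- dots
  class(spec) <- "scenario_spec"
  spec
}

# winter-mixing weight in [0,1], peaking mid January
winter_weight <- function(doy) {
  (0.5 * (1 + cos(2 * pi * (doy - 15) / 365.25)))^2
}

# community-2 activity in [0,1]: boxcar over the active season with
# linear ramps at the edges
c2_activity <- function(doy, start_doy, end_doy, ramp) {
  up <- pmin(1, pmax(0, (doy - start_doy) / ramp))
  down <- pmin(1, pmax(0, (end_doy - doy) / ramp))
  pmin(up, down)
}

#' Generate a seasonal series of synthetic profiles
#'
#' Applies the seasonal cycles of [scenario_spec()] profile by profile:
#' mixed-layer depth, Kd, surface chlorophyll and surface backscattering
#' follow the winter-mixing weight; the community-1 sigmoid parameters are
#' tied to `Zm Kd` through the empirical relations; community 2 switches on
#' in the stratified season with its peak at the scenario's DCM depth.
#'
#' @param spec a `scenario_spec`
#' @return list of [profile_record()] objects (ground truth embedded)
#' @export
make_seasonal_series <- function(spec = scenario_spec()) {
  dates <- seq(spec$start, spec$end, by = spec$cadence_days)
  lapply(seq_along(dates), function(i) {
    d <- dates[i]
    doy <- as.integer(format(d, "%j"))
    w <- winter_weight(doy)
    Kd <- spec$Kd_summer + (spec$Kd_winter - spec$Kd_summer) * w
    Zm <- spec$Zm_summer + (spec$Zm_winter - spec$Zm_summer) * w
    B_s <- spec$B_s_summer + (spec$B_s_winter - spec$B_s_summer) * w
    b_bp_s <- spec$b_bp_s_summer + (spec$b_bp_s_winter - spec$b_bp_s_summer) * w
    tau1 <- empirical_tau1(Zm * Kd)
    P1 <- empirical_p1(tau1)
    act <- c2_activity(doy, spec$c2_start_doy, spec$c2_end_doy, spec$c2_ramp_days)
    # DCM amplitude (relative to the falling surface chlorophyll) builds with
    # stratification, so the absolute subsurface biomass peaks in summer
    B2m <- spec$B2m_max * act * (1 - w)
    params <- list(P1 = P1, tau1 = tau1)
    if (B2m > 0) {
      sigma <- spec$dcm_sigma
      params$B2m_star <- B2m
      params$tau2 <- max(spec$dcm_depth * Kd, 3 * sigma)
      params$sigma <- sigma
    }
    make_profile(
      params, Kd = Kd, B_s = B_s, b_bp_s = b_bp_s,
      bbpk_star = spec$bbpk_star, omega2 = spec$omega2, Zm = Zm,
      noise = spec$noise, par0 = spec$par0,
      T_surf = spec$T_surf - 3 * w, T_deep = spec$T_deep, S0 = spec$S0,
      time = as.POSIXct(paste(d, "09:00:00"), tz = "UTC"),
      latitude = spec$latitude, longitude = spec$longitude,
      cycle_id = i, seed = spec$seed + i
    )
  })
}
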