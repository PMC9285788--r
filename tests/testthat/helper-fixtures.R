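# fixtures built in code: small synthetic records and CSV files

`%||%` <- function(a, b) if (is.null(a)) b else a

fix_summer_params <- list(P1 = 7.8, tau1 = 2.91, B2m_star = 3, tau2 = 5, sigma = 0.8)
fix_winter_params <- list(P1 = 25, tau1 = 9.3)

noiseless <- list(chl = 0, bbp = 0, par = 0)

# a small noiseless record for structural tests (coarse grid keeps IO fast)
fix_record <- function(cycle_id = 1L, time = "2016-06-15 09:00:00",
                       params = fix_summer_params, Kd = 0.05, B_s = 0.2,
                       Zm = 30, noise = noiseless, seed = NULL,
                       pressure = seq(0, 300, by = 5)) {
  make_profile(params, Kd = Kd, B_s = B_s, Zm = Zm, noise = noise,
               pressure = pressure, seed = seed,
               time = as.POSIXct(time, tz = "UTC"), cycle_id = cycle_id)
}

# three-cycle CSV fixture, written deliberately out of time order
fix_csv <- function(path) {
  recs <- list(
    fix_record(2L, "2016-06-20 09:00:00"),
    fix_record(1L, "2016-06-10 09:00:00"),
    fix_record(3L, "2016-06-30 09:00:00")
  )
  write_profiles_csv(recs, path)
  recs
}

# dimensionless profile generated straight from the model equations
eq_profile <- function(params, n = 50, tau_max = 9, noise_sd = 0,
                       mode = c("two_community", "one_community")) {
  mode <- match.arg(mode)
  tau <- seq(0.05, tau_max, length.out = n)
  bstar <- total_chl_star(tau, params, mode = mode)
  if (noise_sd > 0) bstar <- bstar * (1 + stats::rnorm(n, 0, noise_sd))
  structure(list(tau = tau, B_star = bstar, B_s = 1, n = n, Kd = 0.05),
            class = "normalized_profile")
}
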