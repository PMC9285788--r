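test_that("fit_kd recovers the attenuation of an exponential light profile", {
  z <- seq(0, 100, by = 2)
  fit <- fit_kd(z, 100 * exp(-0.05 * z))
  expect_equal(fit$Kd, 0.05, tolerance = 1e-10)
  expect_equal(fit$par0, 100, tolerance = 1e-8)

  # constant light has no decay: Kd = 0 is rejected
  expect_error(fit_kd(z, rep(50, length(z))), "non-positive")
  # too few usable samples signals the empirical fallback
  expect_error(fit_kd(c(0, 5, 10), c(100, 80, 60)), "fewer than 4",
               class = "phytopart_skip")

  set.seed(11)
  par_noisy <- 100 * exp(-0.05 * seq(0, 98, length.out = 50)) *
    exp(rnorm(50, 0, 0.05))
  expect_lt(abs(fit_kd(seq(0, 98, length.out = 50), par_noisy)$Kd - 0.05) / 0.05,
            0.05)
})

test_that("empirical Kd relation reproduces its printed coefficients", {
  expect_equal(kd_from_chl(0), 0.049)
  expect_equal(kd_from_chl(1), 0.085)
  expect_equal(kd_from_chl(2), 0.121)
  expect_error(kd_from_chl(-1), ">= 0")
})

test_that("euphotic and optical depth satisfy their defining identities", {
  expect_equal(euphotic_depth(0.046), 100)
  expect_equal(euphotic_depth(0.092), 50)
  expect_equal(euphotic_depth(0.049), 4.6 / 0.049)
  expect_error(euphotic_depth(0), "> 0")
  for (Kd in c(0.03, 0.05, 0.1)) {
    Zp <- euphotic_depth(Kd)
    expect_equal(optical_depth(Zp, Kd), 4.6)
    expect_equal(optical_depth(1.5 * Zp, Kd), 6.9)
  }
  expect_equal(optical_depth(0, 0.05), 0)
})

test_that("daily PAR integral follows the sinusoidal day model", {
  # equator: 12 h day regardless of season
  expect_equal(day_length(80, 0), 12, tolerance = 1e-6)
  expect_equal(day_length(200, 0), 12, tolerance = 1e-6)

  # noon measurement of E = (pi/2) X integrates to D * X (unit-converted)
  lat <- 0; lon <- 0; X <- 1000
  noon <- as.POSIXct("2016-03-20 12:00:00", tz = "UTC")
  D <- day_length(80, lat)
  got <- daily_par(pi / 2 * X, noon, lat, lon)
  expect_equal(got, D * 3600 * X / 1e6, tolerance = 1e-6)

  # measurements of the same true sinusoid at different times agree,
  # checked against numerical quadrature of the sinusoid
  e_noon <- 1800
  truth <- integrate(function(t) e_noon * sin(pi * t / (D * 3600)),
                     0, D * 3600)$value / 1e6
  for (frac in c(0.25, 0.5, 0.7)) {
    t_meas <- as.POSIXct("2016-03-20 00:00:00", tz = "UTC") +
      ((12 - D / 2) + frac * D) * 3600
    e_meas <- e_noon * sin(pi * frac)
    expect_equal(daily_par(e_meas, t_meas, lat, lon), truth, tolerance = 1e-6)
  }

  # night-time measurement is disregarded
  expect_warning(
    got <- daily_par(1, as.POSIXct("2016-03-20 23:00:00", tz = "UTC"), lat, lon),
    "disregarded")
  expect_true(is.na(got))
})

test_that("EOS-80 density matches published UNESCO check values", {
  # canonical check values from the UNESCO (1983) report
  expect_equal(sw_dens(35, 25, 10000), 1062.53817, tolerance = 1e-7)
  expect_equal(sw_dens(35, 5, 0), 1027.67547, tolerance = 1e-4)
  expect_equal(sw_ptmp(40, 40, 10000, 0), 36.89073, tolerance = 1e-5)
  expect_equal(sw_dens(35, 10, 0), 1026.95, tolerance = 1e-4)

  # physical monotonicity: density rises with salinity at fixed T, p
  expect_true(all(diff(sw_dens(seq(30, 40, 0.5), 10, 0)) > 0))
  # fresh warm water is lighter than salty cold water
  expect_lt(sw_dens(34, 25, 0), sw_dens(39, 5, 0))

  expect_warning(sw_dens(50, 10, 0), "validity range")
})

test_that("Brunt-Vaisala frequency matches closed forms", {
  z <- seq(0, 200, by = 2)
  # uniform density: neutral stratification
  bv <- brunt_vaisala(rep(1025, length(z)), z)
  expect_equal(bv$N2, rep(0, length(z) - 1))

  # linear density gradient 0.01 kg m^-4 around 1025 kg m^-3
  rho <- 1025 + 0.01 * z
  bv <- brunt_vaisala(rho, z)
  expect_equal(bv$N2, 9.81 * 0.01 / ((rho[-1] + rho[-length(rho)]) / 2),
               tolerance = 1e-8)
  expect_equal(mean(bv$N2), 9.81 * 0.01 / 1025, tolerance = 1e-3)

  # two-layer step: N2 peaks at the interface
  rho2 <- ifelse(z < 100, 1024, 1026)
  bv2 <- brunt_vaisala(rho2, z)
  expect_equal(bv2$depth[which.max(bv2$N2)], 99, tolerance = 2)

  expect_error(brunt_vaisala(1025, 10), "at least 2")
})

test_that("stratification index is a depth-weighted mean over the lit layer", {
  tau <- seq(0.1, 10, by = 0.1)
  expect_equal(stratification_index(rep(3e-5, length(tau)), tau), 3e-5)
  # signal entirely below 6.9 optical depths contributes nothing
  n2 <- ifelse(tau > 6.9, 1e-4, 0)
  expect_equal(stratification_index(n2, tau), 0)

  # arbitrary profile vs fine-grid quadrature, and grid-refinement invariance
  f <- function(x) 1e-5 * (1 + sin(x) + 0.3 * x)
  coarse <- stratification_index(f(tau), tau)
  tau_f <- seq(0.1, 10, by = 0.001)
  fine <- stratification_index(f(tau_f), tau_f)
  expect_equal(coarse, fine, tolerance = 0.01)
})

test_that("mixed-layer depth finds a sharp interface and flags mixed columns", {
  z <- seq(0, 500, by = 2)
  t2 <- ifelse(z <= 50, 28, 22)
  for (m in c("holte_talley_temp", "threshold")) {
    mld <- mixed_layer_depth(t2, z, method = m)
    expect_equal(as.numeric(mld), 50, tolerance = 2.1)
  }

  iso <- mixed_layer_depth(rep(20, length(z)), z)
  expect_equal(as.numeric(iso), 500)
  expect_true(attr(iso, "fully_mixed"))

  # smooth thermocline: the two algorithms agree within 10 m
  tsm <- 22 + 6 * 0.5 * (1 - tanh((z - 80) / 25))
  ht <- mixed_layer_depth(tsm, z, method = "holte_talley_temp")
  thr <- mixed_layer_depth(tsm, z, method = "threshold")
  expect_lt(abs(as.numeric(ht) - as.numeric(thr)), 10)

  expect_error(mixed_layer_depth(c(28, 27), c(0, 5)), "below")
})

test_that("layer-mean light matches the analytic Beer-Lambert average", {
  # vanishing attenuation: mean tends to the surface value
  expect_equal(mean_light(50, 1e-9, 0, 30), 50, tolerance = 1e-6)
  # full euphotic layer closed form
  Kd <- 0.05; Zp <- 4.6 / Kd
  expect_equal(mean_light(50, Kd, 0, Zp), 50 * (1 - exp(-4.6)) / 4.6)
  # arbitrary layer vs numeric quadrature
  q <- integrate(function(z) 50 * exp(-0.08 * z), 20, 75)$value / 55
  expect_equal(mean_light(50, 0.08, 20, 75), q, tolerance = 1e-3 * q)
  # degenerate layer returns the point value
  expect_equal(mean_light(50, 0.08, 30, 30), 50 * exp(-0.08 * 30))
  expect_error(mean_light(50, 0.08, 40, 30), "z_top")
})

test_that("derive_context assembles a consistent per-profile context", {
  rec <- fix_record(Zm = 30)
  ctx <- derive_context(rec)
  expect_equal(ctx$Z_p * ctx$Kd, 4.6, tolerance = 1e-10)
  expect_equal(ctx$Kd, 0.05, tolerance = 1e-6)
  expect_identical(ctx$Kd_source, "fitted")
  expect_equal(ctx$Z_m, 30, tolerance = 5)
  expect_gt(ctx$strat_index, 0)
  expect_true(is.finite(ctx$par_ml) && ctx$par_ml > ctx$par_below_ml)

  # no PAR: falls back to the empirical chlorophyll relation
  rec2 <- rec
  rec2$par <- rep(NA_real_, length(rec2$par))
  ctx2 <- derive_context(rec2)
  expect_identical(ctx2$Kd_source, "empirical")
  expect_equal(ctx2$Kd, kd_from_chl(ctx2$B_s10))
})
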