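test_that("community-1 sigmoid has the right midpoint, limits and monotonicity", {
  expect_equal(community1(4, 9, 4), 0.5) # tau = tau1: midpoint
  # surface limit with the lowest admissible P1 exceeds 99%
  expect_equal(community1(0, 4.6, 2), 1 - 1 / (1 + exp(4.6)))
  expect_gt(community1(0, 4.6, 2), 0.99)
  expect_equal(community1(1e6, 9, 4), 0)
  tau <- seq(0, 12, by = 0.1)
  expect_true(all(diff(community1(tau, 9, 4)) < 0))
  expect_error(community1(1, 9, 0), "tau1")
})

test_that("community-2 Gaussian peaks at tau2 and vanishes at the surface", {
  expect_equal(community2(5, 2, 5, 1), 2) # peak value at tau2
  expect_equal(community2(5 + 1, 2, 5, 1), 2 / exp(1))
  expect_equal(community2(5 - 1, 2, 5, 1), 2 / exp(1)) # symmetric
  # surface suppression: B2m* = 80 at tau2 = 3 sigma stays below 1%
  expect_equal(community2(0, 80, 3, 1), 80 * exp(-9))
  expect_lt(community2(0, 80, 3, 1), 0.01)
  expect_error(community2(1, 2, 5, 0), "sigma")
  expect_error(community2(1, -1, 5, 1), "B2m")
})

test_that("total profile conserves the community sum and its surface bound", {
  params <- list(P1 = 9, tau1 = 4, B2m_star = 2, tau2 = 5, sigma = 1)
  tau <- seq(0, 10, by = 0.05)
  expect_identical(
    total_chl_star(tau, params, "two_community"),
    community1(tau, 9, 4) + community2(tau, 2, 5, 1)
  )
  expect_identical(total_chl_star(tau, params, "one_community"),
                   community1(tau, 9, 4))

  # grid search over the admissible box: surface total within 1% of unity
  grid <- expand.grid(P1 = c(4.6, 10, 50, 100), tau1 = c(0.5, 2, 5, 10),
                      B2m = c(0, 1, 10, 80), sigma = c(0.3, 1, 2))
  surf <- mapply(function(P1, tau1, B2m, sigma) {
    total_chl_star(0, list(P1 = P1, tau1 = tau1, B2m_star = B2m,
                           tau2 = 3 * sigma, sigma = sigma), "two_community")
  }, grid$P1, grid$tau1, grid$B2m, grid$sigma)
  expect_true(all(surf > 0.99 & surf < 1.01))
})

test_that("normalization applies the surface-median and truncation rules", {
  rec <- fix_record(params = list(P1 = 9, tau1 = 4), Kd = 0.05, B_s = 0.5,
                    pressure = seq(0, 280, by = 2))
  ctx <- derive_context(rec)
  # constant chlorophyll: B_s equals it and B* is 1 everywhere
  rec$chl <- rep(0.5, length(rec$depth))
  np <- normalize_chl(rec, ctx)
  expect_equal(np$B_s, 0.5)
  expect_equal(np$B_star, rep(1, np$n))

  # unrealistically low values are dropped before the surface median
  rec2 <- profile_record(
    cycle_id = 1L, time = "2016-06-15 09:00:00", latitude = 26, longitude = 36,
    depth = c(2, 8, 14, 30, 45, 60, 75, 90),
    chl = c(0.005, 0.3, 0.4, 0.3, 0.25, 0.2, 0.15, 0.1)
  )
  ctx2 <- ctx; ctx2$Kd <- 1 / 20; ctx2$Z_m <- 300 # first optical depth = 20 m
  np2 <- normalize_chl(rec2, ctx2)
  expect_equal(np2$B_s, median(c(0.3, 0.4)))

  # stratified truncation: Zm Kd < 9.2 keeps only tau < 9.2
  ctx3 <- ctx; ctx3$Z_m <- 60 # Zm Kd = 3
  np3 <- normalize_chl(rec, ctx3)
  expect_lt(max(np3$tau), 9.2)
  # well-mixed profiles keep the full range
  ctx4 <- ctx; ctx4$Z_m <- 250 # Zm Kd = 12.5
  np4 <- normalize_chl(rec, ctx4)
  expect_gt(max(np4$tau), 9.2)

  # N > 6 rule
  rec5 <- rec
  rec5$chl[-(1:5)] <- NA
  expect_error(normalize_chl(rec5, ctx), class = "phytopart_skip")
})

test_that("empirical mixed-layer relations reproduce their coefficients", {
  expect_equal(empirical_tau1(0), 2.29)
  expect_equal(empirical_tau1(10), 8.49)
  expect_equal(empirical_p1(2.29), 10^(0.08 * 2.29 + 0.66))
  expect_equal(empirical_p1(2.29), 6.968, tolerance = 1e-3)
  # clipping to the admissible box
  expect_equal(empirical_p1(40), 100)
  expect_error(empirical_tau1(-1), ">= 0")
})

test_that("step-1 fit recovers sigmoid parameters and gates on variance", {
  # noiseless: recovery to much better than 0.1%, near-perfect r2
  np <- eq_profile(list(P1 = 9, tau1 = 4), n = 50, mode = "one_community")
  s1 <- fit_step1(np, Zm_Kd = 3, boot_n = 0)
  expect_lt(abs(s1$P1 - 9) / 9, 1e-3)
  expect_lt(abs(s1$tau1 - 4) / 4, 1e-3)
  expect_gt(s1$r2, 0.999)

  # noisy: truth falls inside the 95% bootstrap CI
  set.seed(21)
  npn <- eq_profile(list(P1 = 9, tau1 = 4), n = 50, noise_sd = 0.05,
                    mode = "one_community")
  s1n <- fit_step1(npn, Zm_Kd = 3, boot_n = 200)
  expect_true(s1n$ci["P1", 1] <= 9 && 9 <= s1n$ci["P1", 2])
  expect_true(s1n$ci["tau1", 1] <= 4 && 4 <= s1n$ci["tau1", 2])
  expect_true(all(s1n$ci[, 1] <= c(s1n$P1, s1n$tau1) &
                    c(s1n$P1, s1n$tau1) <= s1n$ci[, 2]))

  # a strong DCM breaks the sigmoid-only description
  npd <- eq_profile(list(P1 = 9, tau1 = 4, B2m_star = 3, tau2 = 5, sigma = 0.8),
                    n = 50)
  expect_lt(fit_step1(npd, Zm_Kd = 3, boot_n = 0)$r2, 0.9)
})

test_that("step-2 fit recovers the Gaussian and honours tau2 >= 3 sigma", {
  np <- eq_profile(list(P1 = 9, tau1 = 4, B2m_star = 2, tau2 = 5, sigma = 1),
                   n = 50)
  s2 <- fit_step2(np, P1 = 9, tau1 = 4, boot_n = 0)
  expect_lt(abs(s2$B2m_star - 2) / 2, 1e-3)
  expect_lt(abs(s2$tau2 - 5) / 5, 1e-3)
  expect_lt(abs(s2$sigma - 1), 1e-3)

  # constraint enforcement: a shallow broad peak cannot push tau2 below 3 sigma
  set.seed(22)
  for (i in 1:5) {
    npc <- eq_profile(list(P1 = 9, tau1 = 4, B2m_star = 1.5, tau2 = 3.6,
                           sigma = 1.2), n = 60, noise_sd = 0.05)
    s2c <- fit_step2(npc, P1 = 9, tau1 = 4, boot_n = 50)
    expect_gte(s2c$tau2, 3 * s2c$sigma - 1e-9)
  }

  # pure-sigmoid profiles gain nothing from the Gaussian (AIC selection)
  set.seed(23)
  worse <- replicate(10, {
    nps <- eq_profile(list(P1 = 9, tau1 = 4), n = 50, noise_sd = 0.05,
                      mode = "one_community")
    s1 <- fit_step1(nps, Zm_Kd = 3, boot_n = 0)
    s2 <- fit_step2(nps, P1 = s1$P1, tau1 = s1$tau1, boot_n = 0)
    s2$aic >= s1$aic
  })
  expect_gt(mean(worse), 0.7)
})

test_that("profile partition selects the community structure by season", {
  # summer: shallow mixed layer, strong DCM -> two communities
  ps <- fix_record(params = fix_summer_params, Kd = 0.05, B_s = 0.08,
                   Zm = 20, noise = list(chl = 0.03, bbp = 0.03, par = 0.01),
                   seed = 31, pressure = seq(0, 300, by = 2))
  ctx <- derive_context(ps)
  fs <- partition_profile(ps, ctx, boot_n = 50)
  expect_identical(fs$mode, "two_community")
  expect_gte(fs$tau2, 3 * fs$sigma - 1e-9)
  expect_lt(fs$r2_step1, 0.9)
  expect_lt(fs$aic_step2, fs$aic_step1)
  expect_equal(fs$B2m_star, 3, tolerance = 0.25)

  # winter: deep mixing, uniform chlorophyll -> one community
  pw <- fix_record(params = fix_winter_params, Kd = 0.075, B_s = 0.45,
                   Zm = 150, noise = list(chl = 0.03, bbp = 0.03, par = 0.01),
                   seed = 32, pressure = seq(0, 300, by = 2))
  ctxw <- derive_context(pw)
  fw <- partition_profile(pw, ctxw, boot_n = 50)
  expect_identical(fw$mode, "one_community")
  expect_gt(fw$r2_step1, 0.9)
  expect_true(fw$P1 >= 4.6 && fw$P1 <= 100)

  # too few samples: profile skipped
  p5 <- ps
  p5$chl[-(1:5)] <- NA
  expect_error(partition_profile(p5, ctx), class = "phytopart_skip")
})

test_that("column integration matches closed forms and fine quadrature", {
  z <- seq(0, 100, by = 5)
  expect_equal(integrate_column(rep(3, length(z)), z, 100), 300)
  expect_equal(integrate_column(2 * z, z, 100), 100^2) # exact for linears
  # interpolation at the integration bound
  expect_equal(integrate_column(rep(3, length(z)), z, 92.5), 3 * 92.5)

  set.seed(33)
  v <- cumsum(rnorm(length(z)))
  zf <- seq(0, 100, length.out = 1000)
  vf <- approx(z, v, zf)$y
  expect_equal(integrate_column(v, z, 100), integrate_column(vf, zf, 100),
               tolerance = 0.01)

  expect_error(integrate_column(v[-1], z[-1], 2), "shallowest")
})
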