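test_that("the generator is deterministic under a fixed seed", {
  a <- make_profile(fix_summer_params, Kd = 0.05, B_s = 0.1, Zm = 25, seed = 61)
  b <- make_profile(fix_summer_params, Kd = 0.05, B_s = 0.1, Zm = 25, seed = 61)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  s1 <- make_seasonal_series(scenario_spec(n_days = 30, seed = 62))
  s2 <- make_seasonal_series(scenario_spec(n_days = 30, seed = 62))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("the generator rejects inadmissible parameters", {
  expect_error(make_profile(list(P1 = 3, tau1 = 2), Kd = 0.05, B_s = 0.1),
               "inadmissible")
  expect_error(
    make_profile(list(P1 = 9, tau1 = 4, B2m_star = 2, tau2 = 1, sigma = 1),
                 Kd = 0.05, B_s = 0.1),
    "inadmissible") # tau2 < 3 sigma
})

test_that("zero-noise profiles close the generator-fitter loop", {
  rec <- make_profile(list(P1 = 9, tau1 = 4, B2m_star = 2, tau2 = 5, sigma = 1),
                      Kd = 0.05, B_s = 0.2, Zm = 40, noise = noiseless)
  ctx <- derive_context(rec)
  expect_equal(ctx$Kd, 0.05, tolerance = 1e-8)
  np <- normalize_chl(rec, ctx)
  s2 <- fit_step2(np, P1 = 9, tau1 = 4, boot_n = 0)
  expect_lt(abs(s2$B2m_star - 2) / 2, 1e-3)
  expect_lt(abs(s2$tau2 - 5) / 5, 1e-3)
  expect_lt(abs(s2$sigma - 1), 1e-3)

  # sigmoid-only profile: the end-to-end recovery floor of P1 is set by the
  # operational surface normalization (median over the first optical depth),
  # which rescales B* by a fraction of a percent and P1 is surface-sensitive
  rec1 <- make_profile(list(P1 = 9, tau1 = 4), Kd = 0.05, B_s = 0.2,
                       Zm = 80, noise = noiseless)
  ctx1 <- derive_context(rec1)
  np1 <- normalize_chl(rec1, ctx1)
  s1 <- fit_step1(np1, Zm_Kd = ctx1$Z_m * ctx1$Kd, boot_n = 0)
  expect_lt(abs(s1$tau1 - 4) / 4, 1e-3)
  expect_lt(abs(s1$P1 - 9) / 9, 5e-3)

  nb <- normalize_bbp(rec, ctx)
  fb <- fit_bbp(nb$bbp_star, nb$tau,
                community1(nb$tau, 9, 4), community2(nb$tau, 2, 5, 1),
                boot_n = 0)
  expect_lt(abs(fb$bbpk_star - 0.5) / 0.5, 1e-2)
  expect_lt(abs(fb$omega2 - 0.1) / 0.1, 5e-2)
})

test_that("a B2m* = 0 scenario is classified as one community", {
  rec <- make_profile(list(P1 = 9, tau1 = 4, B2m_star = 0), Kd = 0.05,
                      B_s = 0.2, Zm = 80, seed = 63,
                      noise = list(chl = 0.03, bbp = 0.03, par = 0.01))
  ctx <- derive_context(rec)
  fit <- partition_profile(rec, ctx, boot_n = 0)
  expect_identical(fit$mode, "one_community")
})

test_that("the seasonal scenario produces the winter-summer structure", {
  spec <- scenario_spec(n_days = 10, seed = 64)
  series <- make_seasonal_series(spec)
  months <- as.integer(format(as.Date(vapply(series, function(r) {
    format(r$time, "%Y-%m-%d")
  }, character(1))), "%m"))
  truth <- lapply(series, function(r) r$truth)

  jan <- months == 1L
  jul <- months == 7L
  zm <- vapply(truth, `[[`, numeric(1), "Zm")
  expect_gt(min(zm[jan]), 100) # deep winter mixing
  expect_lt(max(zm[jul]), 40)  # shallow summer mixed layer

  b2 <- vapply(truth, function(t) t$params$B2m_star %||% 0, numeric(1))
  expect_equal(max(b2[jan]), 0)      # no winter DCM
  expect_gt(min(b2[jul]), 0.95 * spec$B2m_max) # fully developed summer DCM
  # summer DCM sits near the scenario depth
  dcm_z <- vapply(truth[jul], function(t) t$params$tau2 / t$Kd, numeric(1))
  expect_true(all(abs(dcm_z - spec$dcm_depth) < 1))

  # community-integrated series peak in opposite seasons
  fits <- lapply(series, function(r) {
    p <- r$truth$params
    structure(list(mode = r$truth$mode, P1 = p$P1, tau1 = p$tau1,
                   B2m_star = p$B2m_star %||% NA_real_,
                   tau2 = p$tau2 %||% NA_real_, sigma = p$sigma %||% NA_real_,
                   B_s = r$truth$B_s, Kd = r$truth$Kd),
              class = "chl_partition")
  })
  times <- as.Date(vapply(series, function(r) format(r$time, "%Y-%m-%d"),
                          character(1)))
  c1 <- community_series(fits, times, community = 1)
  c2 <- community_series(fits, times, community = 2)
  expect_true(months[which.max(c1$value)] %in% c(12L, 1L, 2L))
  expect_true(months[which.max(c2$value)] %in% 5:9)
})
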