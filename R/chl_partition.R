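#' Community-1 (mixed-layer) dimensionless chlorophyll profile
#'
#' Sigmoid profile of the surface community in optical depth,
#' `B1*(tau) = 1 - 1 / (1 + exp(-(P1/tau1) (tau - tau1)))`.
#' `P1 = S1 tau1` couples the decline rate `S1` to the mid-point `tau1`;
#' with `P1 >= 4.6` the surface value exceeds 0.99, so community 1 is
#' effectively the whole surface signal.
#'
#' @param tau optical depth (>= 0)
#' @param P1 dimensionless slope-midpoint product (>= 4.6 in fits)
#' @param tau1 mid-point of the sigmoid decline (> 0)
#' @return dimensionless chlorophyll, in (0, 1), strictly decreasing in tau
#' @export
#' @examples
#' community1(0, 4.6, 2) # > 0.99: surface dominance
community1 <- function(tau, P1, tau1) {
  if (any(!is.finite(tau1)) || any(tau1 <= 0)) stop("community1: tau1 must be > 0")
  1 - 1 / (1 + exp(-(P1 / tau1) * (tau - tau1)))
}

#' Community-2 (deep chlorophyll maximum) dimensionless profile
#'
#' Gaussian profile of the subsurface community in optical depth,
#' `B2*(tau) = B2m* exp(-((tau - tau2)/sigma)^2)`, peaking at `tau2` with
#' width `sigma`. With `tau2 >= 3 sigma` (enforced in fits) the surface
#' contribution is below 1% of the surface total for `B2m* < 80`.
#'
#' @param tau optical depth
#' @param B2m_star peak dimensionless chlorophyll (>= 0)
#' @param tau2 optical depth of the peak
#' @param sigma peak width (> 0)
#' @return dimensionless chlorophyll, symmetric about `tau2`
#' @export
community2 <- function(tau, B2m_star, tau2, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("community2: sigma must be > 0")
  if (any(B2m_star < 0)) stop("community2: B2m_star must be >= 0")
  B2m_star * exp(-((tau - tau2) / sigma)^2)
}

#' Total dimensionless chlorophyll profile
#'
#' Sum of the two community profiles, `B*(tau) = B1*(tau) + B2*(tau)`, or
#' the sigmoid alone in one-community mode. Multiply by the surface
#' chlorophyll `B_s` and map `tau = z Kd` to reconstruct concentration units.
#'
#' @param tau optical depth
#' @param params list with `P1`, `tau1` and (two-community mode) `B2m_star`,
#'   `tau2`, `sigma`
#' @param mode "one_community" or "two_community"
#' @return dimensionless total chlorophyll
#' @export
total_chl_star <- function(tau, params, mode = c("two_community", "one_community")) {
  mode <- match.arg(mode)
  b1 <- community1(tau, params$P1, params$tau1)
  if (mode == "one_community") return(b1)
  b1 + community2(tau, params$B2m_star, params$tau2, params$sigma)
}

#' Normalize a chlorophyll profile to dimensionless coordinates
#'
#' Maps depth to optical depth (`tau = z Kd`) and chlorophyll to its surface
#' value: `B_s` is the median chlorophyll within the first optical depth
#' after discarding unrealistically low values (< 0.01 mg m^-3), and
#' `B* = B / B_s`. Profiles from well-mixed water columns carry signal to
#' depth, so the fit window is the full profile when `Z_m Kd >= 9.2`;
#' otherwise only samples shallower than 9.2 optical depths (twice the
#' euphotic depth) are kept.
#'
#' @param profile a [profile_record()]
#' @param context an `optical_context` from [derive_context()]
#' @param tau_fit_limit optical-depth truncation for stratified profiles
#' @param min_points minimum samples required (profiles with fewer are
#'   skipped, classed condition `phytopart_skip`)
#' @param min_chl surface samples below this are discarded from the median
#' @return object of class `normalized_profile`: list with `tau`, `B_star`,
#'   `B_s`, `n`, `Kd`
#' @export
normalize_chl <- function(profile, context, tau_fit_limit = 9.2,
                          min_points = 7, min_chl = 0.01) {
  Kd <- context$Kd
  ok <- is.finite(profile$chl) & profile$chl > 0
  z <- profile$depth[ok]
  chl <- profile$chl[ok]
  tau <- optical_depth(z, Kd)

  surf <- tau <= 1 & chl >= min_chl
  if (!any(surf)) {
    stop_skip("normalize_chl: no valid chlorophyll sample in the first optical depth")
  }
  B_s <- stats::median(chl[surf])

  Zm_Kd <- context$Z_m * Kd
  keep <- if (is.finite(Zm_Kd) && Zm_Kd < tau_fit_limit) {
    tau < tau_fit_limit
  } else {
    rep(TRUE, length(tau))
  }
  tau <- tau[keep]; chl <- chl[keep]
  if (length(tau) < min_points) {
    stop_skip("normalize_chl: only ", length(tau), " samples (need >= ",
              min_points, ")")
  }
  structure(list(tau = tau, B_star = chl / B_s, B_s = B_s,
                 n = length(tau), Kd = Kd),
            class = "normalized_profile")
}

# --- bounded Levenberg-Marquardt + bootstrap machinery -----------------------

# one bounded LM fit; returns parameter vector or NULL on non-convergence
lm_fit_once <- function(par0, lower, upper, resid_fn) {
  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ptol = 1e-8, ftol = 1e-8)
    )),
    error = function(e) NULL
  )
  if (is.null(res) || !(res$info %in% 1:4)) return(NULL)
  unlist(res$par)
}

# case-resampling bootstrap around lm_fit_once. make_resid(idx) must return
# the residual closure for the resampled observations. Returns list(par,
# ci, n_dropped) where par are per-parameter bootstrap medians. More than
# 50% dropped replicates is a fit failure.
boot_lm <- function(par0, lower, upper, make_resid, n_obs, boot_n,
                    conf = c(0.025, 0.975)) {
  full <- lm_fit_once(par0, lower, upper, make_resid(seq_len(n_obs)))
  if (is.null(full)) stop_skip("fit failure: optimizer did not converge")
  if (boot_n <= 0) {
    return(list(par = full, ci = NULL, n_dropped = 0L, boot_n = 0L))
  }
  draws <- matrix(NA_real_, nrow = boot_n, ncol = length(full),
                  dimnames = list(NULL, names(full)))
  dropped <- 0L
  for (b in seq_len(boot_n)) {
    idx <- sample.int(n_obs, n_obs, replace = TRUE)
    p <- lm_fit_once(par0, lower, upper, make_resid(idx))
    if (is.null(p)) dropped <- dropped + 1L else draws[b, ] <- p
  }
  if (dropped > boot_n / 2) {
    stop_skip("fit failure: >50% of bootstrap replicates did not converge")
  }
  ok <- stats::complete.cases(draws)
  list(
    par = apply(draws[ok, , drop = FALSE], 2, stats::median),
    ci = t(apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = conf)),
    n_dropped = dropped, boot_n = boot_n, draws = draws[ok, , drop = FALSE]
  )
}

# least-squares AIC with k fitted parameters
aic_ls <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Step-1 fit: sigmoid-only profile
#'
#' Bounded Levenberg-Marquardt fit of the one-community (sigmoid) profile to
#' a normalized chlorophyll profile, with initial guess `tau1 = Zm Kd`,
#' `P1 = 9`, bounds `4.6 <= P1 <= 100` and `tau1 >= 0`. Reported parameters
#' are per-parameter medians over a case-resampling bootstrap (default 1,000
#' replicates) with 2.5%/97.5% confidence bounds; `r2` is the squared
#' Pearson correlation between observed and fitted values.
#'
#' @param np a `normalized_profile` from [normalize_chl()]
#' @param Zm_Kd mixed-layer depth in optical-depth units (initial guess)
#' @param boot_n bootstrap replicates (0 = point fit only, no CIs)
#' @param p1_bounds lower/upper bounds on `P1`
#' @return list with `P1`, `tau1`, `ci`, `r2`, `rss`, `aic`, `n`
#' @export
fit_step1 <- function(np, Zm_Kd, boot_n = 1000, p1_bounds = c(4.6, 100)) {
  tau <- np$tau; bs <- np$B_star
  n <- length(tau)
  make_resid <- function(idx) {
    ti <- tau[idx]; bi <- bs[idx]
    function(par) bi - community1(ti, par[1], par[2])
  }
  par0 <- c(P1 = 9, tau1 = max(Zm_Kd, 0.1, na.rm = TRUE))
  bf <- boot_lm(par0, lower = c(p1_bounds[1], 1e-6),
                upper = c(p1_bounds[2], Inf),
                make_resid, n_obs = n, boot_n = boot_n)
  P1 <- unname(bf$par["P1"]); tau1 <- unname(bf$par["tau1"])
  pred <- community1(tau, P1, tau1)
  rss <- sum((bs - pred)^2)
  r2 <- if (stats::sd(pred) > 0) stats::cor(bs, pred)^2 else 0
  list(P1 = P1, tau1 = tau1, ci = bf$ci, r2 = r2, rss = rss,
       aic = aic_ls(rss, n, k = 2), n = n, n_dropped = bf$n_dropped)
}

#' Empirical sigmoid mid-point from the mixed layer
#'
#' Linear relation `tau1 = 0.62 Zm Kd + 2.29` used to fix the sigmoid
#' mid-point in step 2, derived from one-community fits in well-mixed
#' conditions.
#'
#' @param Zm_Kd mixed-layer depth in optical-depth units (>= 0)
#' @param slope,intercept relation coefficients
#' @return tau1 (dimensionless)
#' @export
empirical_tau1 <- function(Zm_Kd, slope = 0.62, intercept = 2.29) {
  if (any(!is.finite(Zm_Kd)) || any(Zm_Kd < 0)) {
    stop("empirical_tau1: Zm_Kd must be finite and >= 0")
  }
  slope * Zm_Kd + intercept
}

#' Empirical sigmoid slope product from its mid-point
#'
#' Log-linear relation `P1 = 10^(0.08 tau1 + 0.66)` used to fix `P1` in
#' step 2, clipped to the admissible box.
#'
#' @param tau1 sigmoid mid-point
#' @param slope,intercept relation coefficients (log10 space)
#' @param bounds admissible `P1` range
#' @return P1 (dimensionless), clipped to `bounds`
#' @export
empirical_p1 <- function(tau1, slope = 0.08, intercept = 0.66,
                         bounds = c(4.6, 100)) {
  p1 <- 10^(slope * tau1 + intercept)
  pmin(bounds[2], pmax(bounds[1], p1))
}

#' Step-2 fit: add the deep-chlorophyll-maximum Gaussian
#'
#' With `P1` and `tau1` held fixed (from the empirical relations), fits the
#' Gaussian parameters `B2m*`, `tau2`, `sigma` of the two-community profile
#' by bounded Levenberg-Marquardt. The surface-suppression constraint
#' `tau2 >= 3 sigma` is enforced exactly by the reparameterization
#' `tau2 = 3 sigma + delta`, `delta >= 0`; `B2m*` is bounded to `[0, 100]`
#' and `sigma > 0`. Parameters are bootstrap medians with 2.5%/97.5% bounds;
#' if the per-parameter medians violate the joint constraint, `tau2` is
#' projected back onto it and the result flagged (`projected = TRUE`).
#'
#' @param np a `normalized_profile`
#' @param P1,tau1 fixed sigmoid parameters
#' @param boot_n bootstrap replicates (0 = point fit only)
#' @param b2m_bounds bounds on `B2m*`
#' @return list with `B2m_star`, `tau2`, `sigma`, `ci`, `rss`, `aic`,
#'   `projected`
#' @export
fit_step2 <- function(np, P1, tau1, boot_n = 1000, b2m_bounds = c(0, 100)) {
  tau <- np$tau; bs <- np$B_star
  n <- length(tau)
  base1 <- community1(tau, P1, tau1)
  make_resid <- function(idx) {
    ti <- tau[idx]; bi <- bs[idx]; b1i <- base1[idx]
    function(par) {
      # par = (B2m, sigma, delta); tau2 = 3 sigma + delta keeps tau2 >= 3 sigma
      bi - b1i - community2(ti, par[1], 3 * par[2] + par[3], par[2])
    }
  }
  resid0 <- bs - base1
  ipk <- which.max(resid0)
  sigma0 <- 1
  par0 <- c(B2m = max(resid0[ipk], 0.1),
            sigma = sigma0,
            delta = max(tau[ipk] - 3 * sigma0, 0))
  bf <- boot_lm(par0, lower = c(b2m_bounds[1], 1e-3, 0),
                upper = c(b2m_bounds[2], Inf, Inf),
                make_resid, n_obs = n, boot_n = boot_n)

  if (!is.null(bf$draws)) {
    tau2_draws <- 3 * bf$draws[, "sigma"] + bf$draws[, "delta"]
    tau2 <- stats::median(tau2_draws)
    tau2_ci <- stats::quantile(tau2_draws, c(0.025, 0.975))
  } else {
    tau2 <- 3 * bf$par["sigma"] + bf$par["delta"]
    tau2_ci <- NULL
  }
  B2m <- unname(bf$par["B2m"]); sigma <- unname(bf$par["sigma"])
  projected <- FALSE
  if (tau2 < 3 * sigma) { # per-parameter medians can step off the constraint set
    tau2 <- 3 * sigma
    projected <- TRUE
  }
  ci <- if (!is.null(bf$ci)) {
    rbind(B2m_star = bf$ci["B2m", ], sigma = bf$ci["sigma", ], tau2 = tau2_ci)
  } else {
    NULL
  }
  pred <- base1 + community2(tau, B2m, tau2, sigma)
  rss <- sum((bs - pred)^2)
  list(B2m_star = B2m, tau2 = unname(tau2), sigma = sigma, ci = ci,
       rss = rss, aic = aic_ls(rss, n, k = 3), n = n,
       n_dropped = bf$n_dropped, projected = projected)
}

#' Partition a chlorophyll profile into two communities
#'
#' Two-step tuning. Step 1 fits the sigmoid alone; if it explains more than
#' `r2_gate` (default 90%) of the variance, community 2 is taken to be
#' absent and the step-1 parameters are kept. Otherwise `P1` and `tau1` are
#' fixed from the empirical mixed-layer relations ([empirical_tau1()],
#' [empirical_p1()]) and the Gaussian is added in step 2; the two-community
#' description is retained only if it lowers the AIC, otherwise the profile
#' falls back to one community.
#'
#' @param profile a [profile_record()]
#' @param context an `optical_context`
#' @param boot_n bootstrap replicates for each fit
#' @param r2_gate explained-variance gate for skipping step 2
#' @param tau_fit_limit,min_points passed to [normalize_chl()]
#' @param p1_bounds,b2m_bounds parameter boxes
#' @return object of class `chl_partition`
#' @export
partition_profile <- function(profile, context, boot_n = 1000,
                              r2_gate = 0.9, tau_fit_limit = 9.2,
                              min_points = 7, p1_bounds = c(4.6, 100),
                              b2m_bounds = c(0, 100)) {
  np <- normalize_chl(profile, context, tau_fit_limit = tau_fit_limit,
                      min_points = min_points)
  Zm_Kd <- context$Z_m * context$Kd
  if (!is.finite(Zm_Kd)) Zm_Kd <- 1
  s1 <- fit_step1(np, Zm_Kd, boot_n = boot_n, p1_bounds = p1_bounds)

  res <- list(
    mode = "one_community",
    P1 = s1$P1, tau1 = s1$tau1,
    B2m_star = NA_real_, tau2 = NA_real_, sigma = NA_real_,
    ci = s1$ci,
    r2_step1 = s1$r2, aic_step1 = s1$aic, aic_step2 = NA_real_,
    n_points = s1$n, B_s = np$B_s, Kd = np$Kd, projected = FALSE
  )
  if (s1$r2 <= r2_gate) {
    tau1_e <- empirical_tau1(Zm_Kd)
    p1_e <- empirical_p1(tau1_e, bounds = p1_bounds)
    s2 <- tryCatch(
      fit_step2(np, p1_e, tau1_e, boot_n = boot_n, b2m_bounds = b2m_bounds),
      phytopart_skip = function(e) NULL
    )
    if (!is.null(s2)) {
      res$aic_step2 <- s2$aic
      if (s2$aic < s1$aic) {
        res$mode <- "two_community"
        res$P1 <- p1_e; res$tau1 <- tau1_e
        res$B2m_star <- s2$B2m_star; res$tau2 <- s2$tau2; res$sigma <- s2$sigma
        res$ci <- rbind(
          P1 = c(`2.5%` = p1_e, `97.5%` = p1_e),
          tau1 = c(tau1_e, tau1_e),
          s2$ci
        )
        res$projected <- s2$projected
      }
    }
  }
  structure(res, class = "chl_partition")
}

#' @export
print.chl_partition <- function(x, ...) {
  cat(sprintf("<chl_partition> mode=%s  P1=%.2f tau1=%.2f", x$mode, x$P1, x$tau1))
  if (x$mode == "two_community") {
    cat(sprintf("  B2m*=%.2f tau2=%.2f sigma=%.2f", x$B2m_star, x$tau2, x$sigma))
  }
  cat(sprintf("\n  r2(step1)=%.3f  AIC %.1f -> %s  (n=%d)\n",
              x$r2_step1, x$aic_step1,
              ifelse(is.na(x$aic_step2), "-", sprintf("%.1f", x$aic_step2)),
              x$n_points))
  invisible(x)
}

#' Reconstruct community chlorophyll in concentration units
#'
#' Evaluates a fitted partition on a depth grid and rescales to mg m^-3
#' via `B(z) = B_s B*(z Kd)`.
#'
#' @param z depth, m
#' @param fit a `chl_partition`
#' @param community "total", "1" or "2"
#' @param Kd,B_s override the values stored in the fit
#' @return chlorophyll-a, mg m^-3
#' @export
reconstruct_chl <- function(z, fit, community = c("total", "1", "2"),
                            Kd = fit$Kd, B_s = fit$B_s) {
  community <- match.arg(community)
  tau <- optical_depth(z, Kd)
  bstar <- switch(community,
    total = total_chl_star(tau, fit, mode = fit$mode),
    "1" = community1(tau, fit$P1, fit$tau1),
    "2" = if (fit$mode == "two_community") {
      community2(tau, fit$B2m_star, fit$tau2, fit$sigma)
    } else {
      rep(0, length(tau))
    }
  )
  B_s * bstar
}

#' Re-derive the empirical mixed-layer relations from fitted profiles
#'
#' Pools one-community fits from well-mixed profiles (`Z_p < Z_m`) and
#' regresses `tau1` on `Zm Kd` (linear) and `log10 P1` on `tau1`, giving the
#' coefficient set used by [empirical_tau1()] and [empirical_p1()].
#'
#' @param fits list of `chl_partition` objects
#' @param contexts list of matching `optical_context` objects
#' @return list with `tau1_slope`, `tau1_intercept`, `p1_slope`,
#'   `p1_intercept`, `n`
#' @export
derive_empirical_relations <- function(fits, contexts) {
  rows <- mapply(function(f, ctx) {
    if (f$mode != "one_community" || !is.finite(ctx$Z_m)) return(NULL)
    if (!(ctx$Z_p < ctx$Z_m)) return(NULL)
    c(tau1 = f$tau1, P1 = f$P1, Zm_Kd = ctx$Z_m * ctx$Kd)
  }, fits, contexts, SIMPLIFY = FALSE)
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(rows) || nrow(rows) < 3L) {
    stop("derive_empirical_relations: need >= 3 mixed-water one-community fits")
  }
  df <- as.data.frame(rows)
  f1 <- stats::lm(tau1 ~ Zm_Kd, data = df)
  f2 <- stats::lm(log10(P1) ~ tau1, data = df)
  list(
    tau1_slope = unname(stats::coef(f1)[2]),
    tau1_intercept = unname(stats::coef(f1)[1]),
    p1_slope = unname(stats::coef(f2)[2]),
    p1_intercept = unname(stats::coef(f2)[1]),
    n = nrow(df)
  )
}
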