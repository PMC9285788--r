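#' Normalize a particle backscattering profile
#'
#' Maps depth to optical depth and bbp at 700 nm to its surface value:
#' `b_bp_s` is the median bbp within the first optical depth and
#' `b*bp = bbp / b_bp_s`. Only samples shallower than `max_depth`
#' (default 500 m) are used, and profiles with 6 or fewer samples are
#' skipped.
#'
#' @param profile a [profile_record()]
#' @param context an `optical_context`
#' @param max_depth deepest sample admitted to the fit, m
#' @param min_points minimum samples required
#' @return list with `tau`, `bbp_star`, `b_bp_s`, `n`, `Kd`
#' @export
normalize_bbp <- function(profile, context, max_depth = 500, min_points = 7) {
  Kd <- context$Kd
  ok <- is.finite(profile$bbp700) & profile$bbp700 > 0 &
    profile$depth < max_depth
  z <- profile$depth[ok]
  bbp <- profile$bbp700[ok]
  tau <- optical_depth(z, Kd)
  surf <- tau <= 1
  if (!any(surf)) {
    stop_skip("normalize_bbp: no valid bbp sample in the first optical depth")
  }
  b_bp_s <- stats::median(bbp[surf])
  if (length(tau) < min_points) {
    stop_skip("normalize_bbp: only ", length(tau), " samples (need >= ",
              min_points, ")")
  }
  structure(list(tau = tau, bbp_star = bbp / b_bp_s, b_bp_s = b_bp_s,
                 n = length(tau), Kd = Kd),
            class = "normalized_bbp")
}

#' Fit the backscattering partition
#'
#' Bounded Levenberg-Marquardt fit of the normalized backscattering model
#' `b*bp(tau) = (1 - b*bp,k) B1*(tau) + omega2 B2*(tau) + b*bp,k`
#' (two-community mode) or its one-community reduction without the `omega2`
#' term. The surface identity `omega1 + b*bp,k = 1` is built into the model,
#' so `omega1 = 1 - b*bp,k` holds exactly. `b*bp,k` is bounded to
#' `[0.01, 0.95]` (the background may not exceed 95% of the surface signal)
#' and `omega2 >= 0.01`; initial guesses are 0.2 and 0.3. Parameters are
#' case-resampling bootstrap medians with 2.5%/97.5% bounds.
#'
#' @param bbp_star normalized backscattering
#' @param tau optical depth at the samples
#' @param B1_star,B2_star community profiles evaluated from the chlorophyll
#'   partition's median parameters at `tau`
#' @param mode "two_community" or "one_community"
#' @param boot_n bootstrap replicates (0 = point fit only)
#' @param bbpk_bounds bounds on `b*bp,k`
#' @param omega2_lower lower bound on `omega2`
#' @param init initial guesses `c(bbpk_star, omega2)`
#' @return list with `bbpk_star`, `omega2` (NA in one-community mode),
#'   `omega1`, `ci`, `rss`, `aic`, `n`
#' @export
fit_bbp <- function(bbp_star, tau, B1_star, B2_star = NULL,
                    mode = c("two_community", "one_community"),
                    boot_n = 1000, bbpk_bounds = c(0.01, 0.95),
                    omega2_lower = 0.01, init = c(0.2, 0.3)) {
  mode <- match.arg(mode)
  n <- length(tau)
  stopifnot(length(bbp_star) == n, length(B1_star) == n)
  if (mode == "two_community") {
    stopifnot(length(B2_star) == n)
    make_resid <- function(idx) {
      yi <- bbp_star[idx]; b1 <- B1_star[idx]; b2 <- B2_star[idx]
      function(par) yi - ((1 - par[1]) * b1 + par[2] * b2 + par[1])
    }
    bf <- boot_lm(c(bbpk = init[1], omega2 = init[2]),
                  lower = c(bbpk_bounds[1], omega2_lower),
                  upper = c(bbpk_bounds[2], Inf),
                  make_resid, n_obs = n, boot_n = boot_n)
    bbpk_star <- unname(bf$par["bbpk"])
    omega2 <- unname(bf$par["omega2"])
    pred <- (1 - bbpk_star) * B1_star + omega2 * B2_star + bbpk_star
    k <- 2
    ci <- if (!is.null(bf$ci)) {
      rbind(bbpk_star = bf$ci["bbpk", ], omega2 = bf$ci["omega2", ])
    }
  } else {
    make_resid <- function(idx) {
      yi <- bbp_star[idx]; b1 <- B1_star[idx]
      function(par) yi - ((1 - par[1]) * b1 + par[1])
    }
    bf <- boot_lm(c(bbpk = init[1]),
                  lower = bbpk_bounds[1], upper = bbpk_bounds[2],
                  make_resid, n_obs = n, boot_n = boot_n)
    bbpk_star <- unname(bf$par["bbpk"])
    omega2 <- NA_real_
    pred <- (1 - bbpk_star) * B1_star + bbpk_star
    k <- 1
    ci <- if (!is.null(bf$ci)) rbind(bbpk_star = bf$ci["bbpk", ])
  }
  rss <- sum((bbp_star - pred)^2)
  list(bbpk_star = bbpk_star, omega2 = omega2, omega1 = 1 - bbpk_star,
       ci = ci, rss = rss, aic = aic_ls(rss, n, k), n = n,
       n_dropped = bf$n_dropped, mode = mode)
}

#' Chlorophyll-specific and background backscattering coefficients
#'
#' Dimensional coefficients from the fitted dimensionless partition:
#' `b^B_bp,1 = (1 - b*bp,k) / (B_s / b_bp_s)` (community 1, m^-1 per
#' mg m^-3), `b^B_bp,2 = omega2 / (B_s / b_bp_s)` (community 2), and the
#' non-algal background `b^k_bp = b*bp,k b_bp_s` (m^-1).
#'
#' @param omega2 community-2 scaling factor (NA in one-community mode)
#' @param bbpk_star dimensionless background
#' @param B_s surface chlorophyll, mg m^-3 (> 0)
#' @param b_bp_s surface backscattering, m^-1 (> 0)
#' @return list with `bbp1B`, `bbp2B`, `bbpk`
#' @export
derive_coefficients <- function(omega2, bbpk_star, B_s, b_bp_s) {
  if (!is.finite(B_s) || B_s <= 0 || !is.finite(b_bp_s) || b_bp_s <= 0) {
    stop("derive_coefficients: B_s and b_bp_s must be > 0")
  }
  list(
    bbp1B = (1 - bbpk_star) * b_bp_s / B_s,
    bbp2B = if (is.finite(omega2)) omega2 * b_bp_s / B_s else NA_real_,
    bbpk = bbpk_star * b_bp_s
  )
}

#' Partition a backscattering profile using the chlorophyll communities
#'
#' Convenience wrapper: normalizes the bbp profile, evaluates the community
#' shapes from a fitted chlorophyll partition, fits the backscattering
#' model, and derives the dimensional coefficients.
#'
#' @param profile a [profile_record()]
#' @param context an `optical_context`
#' @param chl_fit a `chl_partition`
#' @param boot_n bootstrap replicates
#' @param max_depth deepest bbp sample admitted, m
#' @param ... passed to [fit_bbp()]
#' @return object of class `bbp_partition`
#' @export
partition_bbp <- function(profile, context, chl_fit, boot_n = 1000,
                          max_depth = 500, ...) {
  nb <- normalize_bbp(profile, context, max_depth = max_depth)
  b1 <- community1(nb$tau, chl_fit$P1, chl_fit$tau1)
  b2 <- if (chl_fit$mode == "two_community") {
    community2(nb$tau, chl_fit$B2m_star, chl_fit$tau2, chl_fit$sigma)
  } else {
    NULL
  }
  fit <- fit_bbp(nb$bbp_star, nb$tau, b1, b2, mode = chl_fit$mode,
                 boot_n = boot_n, ...)
  co <- derive_coefficients(fit$omega2, fit$bbpk_star,
                            B_s = chl_fit$B_s, b_bp_s = nb$b_bp_s)
  structure(c(fit, co, list(b_bp_s = nb$b_bp_s, n_points = nb$n)),
            class = "bbp_partition")
}

#' @export
print.bbp_partition <- function(x, ...) {
  cat(sprintf(
    "<bbp_partition> mode=%s  b*bp,k=%.3f omega1=%.3f omega2=%s\n  bbp1B=%.2e  bbp2B=%s  bbpk=%.2e m-1  (n=%d)\n",
    x$mode, x$bbpk_star, x$omega1,
    ifelse(is.finite(x$omega2), sprintf("%.3f", x$omega2), "-"),
    x$bbp1B,
    ifelse(is.finite(x$bbp2B), sprintf("%.2e", x$bbp2B), "-"),
    x$bbpk, x$n_points
  ))
  invisible(x)
}

#' Reconstruct the backscattering profile in m^-1
#'
#' Evaluates `bbp(z) = b^B_bp,1 B1(z) + b^B_bp,2 B2(z) + b^k_bp` on a depth
#' grid, where `B1` and `B2` are the community chlorophyll profiles in
#' concentration units. In the abyssal limit (both communities zero) the
#' profile tends to the non-algal background `b^k_bp`.
#'
#' @param z depth, m
#' @param chl_fit a `chl_partition`
#' @param bbp_fit a `bbp_partition`
#' @param Kd,B_s override the values stored in the chlorophyll fit
#' @return bbp at 700 nm, m^-1
#' @export
reconstruct_bbp <- function(z, chl_fit, bbp_fit, Kd = chl_fit$Kd,
                            B_s = chl_fit$B_s) {
  B1 <- reconstruct_chl(z, chl_fit, community = "1", Kd = Kd, B_s = B_s)
  B2 <- reconstruct_chl(z, chl_fit, community = "2", Kd = Kd, B_s = B_s)
  b2B <- if (is.finite(bbp_fit$bbp2B)) bbp_fit$bbp2B else 0
  bbp_fit$bbp1B * B1 + b2B * B2 + bbp_fit$bbpk
}

#' Despike a backscattering profile with a running median
#'
#' Window-11 running median with nearest-edge padding, used to remove
#' spikes for reporting and plotting (fits use the raw normalized data).
#' For short profiles the window shrinks to the largest odd length that
#' fits.
#'
#' @param bbp backscattering samples, m^-1
#' @param window odd window length
#' @return filtered array, same length
#' @export
despike_bbp <- function(bbp, window = 11) {
  n <- length(bbp)
  if (n == 0L) return(bbp)
  k <- min(window, if (n %% 2 == 1) n else n - 1)
  if (k < 3L) return(bbp)
  h <- (k - 1) / 2
  padded <- c(rep(bbp[1], h), bbp, rep(bbp[n], h))
  out <- stats::runmed(padded, k, endrule = "keep")
  out[(h + 1):(h + n)]
}
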