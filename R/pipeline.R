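#' Build a pipeline run configuration
#'
#' Collects every tunable of the workflow with its default. Either `input`
#' (a profiles CSV) or `scenario` (a [scenario_spec()] to simulate) must be
#' supplied to [run_pipeline()].
#'
#' @param input optional path to a long-format profiles CSV
#' @param scenario optional `scenario_spec` for synthetic input
#' @param output_dir optional directory for result tables
#' @param seed integer seed applied before any randomness
#' @param boot_n bootstrap replicates per fit
#' @param r2_gate step-1 explained-variance gate
#' @param tau_fit_limit,min_points chlorophyll fit-window controls
#' @param bbp_fit_max_depth deepest bbp sample admitted, m
#' @param mld_method,mld_threshold mixed-layer depth controls
#' @param strat_tau_limit stratification-index optical-depth bound
#' @param threshold_factor,persistence_days,sg_window,sg_order phenology
#'   controls
#' @param community1_window,community2_window optional annual windows
#'   (Date pairs) for the two communities' phenology
#' @param verbose log per-profile progress with `message()`
#' @return list of class `run_config`
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, output_dir = NULL,
                            seed = 1L, boot_n = 1000, r2_gate = 0.9,
                            tau_fit_limit = 9.2, min_points = 7,
                            bbp_fit_max_depth = 500,
                            mld_method = "holte_talley_temp",
                            mld_threshold = 0.2, strat_tau_limit = 6.9,
                            threshold_factor = 1.05, persistence_days = 15,
                            sg_window = 15, sg_order = 2,
                            community1_window = NULL,
                            community2_window = NULL, verbose = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full partitioning workflow
#'
#' Reads (or simulates) profiles, derives each profile's optical context,
#' partitions chlorophyll and backscattering, builds the two communities'
#' column-integrated daily series, runs the phenology algorithm on each,
#' and correlates the community series with the stratification index.
#' A profile failing its preconditions is skipped with a logged reason;
#' no per-profile failure aborts the run. The run is deterministic for a
#' fixed seed.
#'
#' @param config a [pipeline_config()]
#' @return list of class `run_summary`: counts, per-profile fits, series,
#'   phenology, correlations, skip log, output paths
#' @export
run_pipeline <- function(config = pipeline_config()) {
  set.seed(config$seed)
  if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      stop("run_pipeline: unreadable input: ", config$input)
    }
    records <- read_profiles_csv(config$input)
  } else if (!is.null(config$scenario)) {
    records <- make_seasonal_series(config$scenario)
  } else {
    stop("run_pipeline: config needs either 'input' or 'scenario'")
  }
  if (!length(records)) stop("run_pipeline: no profiles in input")

  fits <- vector("list", length(records))
  skips <- character(0)
  for (i in seq_along(records)) {
    rec <- records[[i]]
    out <- tryCatch({
      ctx <- derive_context(rec,
        mld_method = config$mld_method, mld_threshold = config$mld_threshold,
        strat_tau_limit = config$strat_tau_limit)
      chl <- partition_profile(rec, ctx,
        boot_n = config$boot_n, r2_gate = config$r2_gate,
        tau_fit_limit = config$tau_fit_limit, min_points = config$min_points)
      bbp <- tryCatch(
        partition_bbp(rec, ctx, chl, boot_n = config$boot_n,
                      max_depth = config$bbp_fit_max_depth),
        phytopart_skip = function(e) NULL
      )
      if (config$verbose) {
        message(sprintf("cycle %d: %s r2=%.3f AIC %.1f/%s", rec$cycle_id,
                        chl$mode, chl$r2_step1, chl$aic_step1,
                        ifelse(is.na(chl$aic_step2), "-",
                               sprintf("%.1f", chl$aic_step2))))
      }
      list(cycle_id = rec$cycle_id, time = rec$time, context = ctx,
           chl = chl, bbp = bbp)
    }, phytopart_skip = function(e) {
      skips <<- c(skips, sprintf("cycle %d: %s", rec$cycle_id,
                                 conditionMessage(e)))
      if (config$verbose) message("skipped ", conditionMessage(e))
      NULL
    })
    fits[[i]] <- out
  }

  fitted <- Filter(Negate(is.null), fits)
  modes <- vapply(fitted, function(f) f$chl$mode, character(1))
  times <- as.POSIXct(vapply(fitted, function(f) as.numeric(f$time),
                             numeric(1)), tz = "UTC",
                      origin = "1970-01-01")

  series <- phen <- list()
  if (length(fitted) >= 2L) {
    chl_fits <- lapply(fitted, `[[`, "chl")
    for (comm in c(1L, 2L)) {
      raw <- community_series(chl_fits, times, community = comm)
      daily <- to_daily(raw$time, raw$value)
      if (nrow(daily) >= config$sg_window) {
        daily$smoothed <- smooth_series(daily$value, window = config$sg_window,
                                        order = config$sg_order)
        win <- config[[paste0("community", comm, "_window")]]
        ws <- if (is.null(win)) min(daily$time) else as.Date(win[1])
        we <- if (is.null(win)) max(daily$time) else as.Date(win[2])
        phen[[as.character(comm)]] <- tryCatch(
          detect_bloom(daily$time, daily$smoothed, ws, we,
                       threshold_factor = config$threshold_factor,
                       persistence_days = config$persistence_days,
                       community = comm),
          error = function(e) NULL
        )
      }
      series[[as.character(comm)]] <- daily
    }
  }

  correlations <- list()
  if (length(fitted) >= 3L) {
    strat <- vapply(fitted, function(f) f$context$strat_index, numeric(1))
    for (comm in c("1", "2")) {
      chl_fits <- lapply(fitted, `[[`, "chl")
      v <- community_series(chl_fits, seq_along(fitted), community = comm)$value
      correlations[[paste0("community", comm, "_vs_strat")]] <- tryCatch(
        correlate_series(v, strat), error = function(e) NULL
      )
    }
  }

  paths <- NULL
  if (!is.null(config$output_dir)) {
    series_df <- do.call(rbind, lapply(names(series), function(k) {
      data.frame(time = series[[k]]$time, community = as.integer(k),
                 value = series[[k]]$value, smoothed = series[[k]]$smoothed)
    }))
    phen_df <- do.call(rbind, lapply(phen, function(p) {
      if (is.null(p)) return(NULL)
      data.frame(community = p$community, bloom = p$bloom,
                 initiation = p$initiation, termination = p$termination,
                 duration = p$duration, window_start = p$window_start,
                 window_end = p$window_end)
    }))
    paths <- write_results(records, fitted, phenology = phen_df,
                           series = series_df, dir = config$output_dir)
  }

  structure(list(
    n_profiles = length(records),
    n_fitted = length(fitted),
    n_one_community = sum(modes == "one_community"),
    n_two_community = sum(modes == "two_community"),
    n_skipped = length(skips),
    skip_log = skips,
    fits = fitted, series = series, phenology = phen,
    correlations = correlations, paths = paths
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "<run_summary> %d profiles: %d fitted (%d one-community, %d two-community), %d skipped\n",
    x$n_profiles, x$n_fitted, x$n_one_community, x$n_two_community, x$n_skipped
  ))
  for (p in x$phenology) if (!is.null(p)) print(p)
  invisible(x)
}

#' Pearson correlation between two series
#'
#' Pairwise-complete Pearson correlation with optional log10 transform of
#' both series (non-positive values dropped under the transform).
#'
#' @param x,y numeric series of equal length
#' @param log10 transform both series with log10 first
#' @return list with `r`, `p`, `n`
#' @export
correlate_series <- function(x, y, log10 = FALSE) {
  stopifnot(length(x) == length(y))
  if (log10) {
    bad <- !is.finite(x) | !is.finite(y) | x <= 0 | y <= 0
    x <- base::log10(x[!bad]); y <- base::log10(y[!bad])
  }
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("correlate_series: need >= 3 paired finite values")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
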