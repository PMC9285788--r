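#' Read profiles from long-format CSV
#'
#' Reads float profiles from the package's CSV interchange dialect: one row
#' per (cycle, depth level) with named columns. Mandatory columns are
#' `cycle_id`, `time` (ISO-8601, UTC), `latitude`, `longitude`, one of
#' `pressure_dbar` or `depth_m`, `temperature_c`, `salinity_psu`,
#' `chl_mg_m3` and `bbp700_m1`; `par_umol_m2_s` and `oxygen_umol_kg` are
#' optional. Optional per-variable quality-flag columns (`chl_qc`,
#' `bbp700_qc`, `par_qc`) follow the Argo convention: flags 1, 2, 5 and 8
#' are accepted, any other flag masks the sample to `NA`.
#'
#' Pressure is converted to depth with the latitude-dependent hydrostatic
#' formula ([pressure_to_depth()]). Records are sorted by time. A cycle
#' whose depth array is not strictly increasing is rejected with a warning.
#'
#' @param path path to a CSV file
#' @return list of [profile_record()] objects, sorted by time
#' @seealso [write_profiles_csv()], [write_results()]
#' @export
parse_utc <- function(x) {
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                            "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
}

read_profiles_csv <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("cycle_id", "time", "latitude", "longitude",
                 "temperature_c", "salinity_psu", "chl_mg_m3", "bbp700_m1")
  missing_cols <- setdiff(mandatory, names(df))
  if (!("pressure_dbar" %in% names(df)) && !("depth_m" %in% names(df))) {
    missing_cols <- c(missing_cols, "pressure_dbar (or depth_m)")
  }
  if (length(missing_cols)) {
    stop("missing mandatory variable(s): ", paste(missing_cols, collapse = ", "))
  }

  qc_ok <- function(flag) flag %in% c(1L, 2L, 5L, 8L)
  apply_qc <- function(values, qc_col) {
    if (qc_col %in% names(df)) {
      values[!qc_ok(df[[qc_col]])] <- NA_real_
    }
    values
  }
  df$chl_mg_m3 <- apply_qc(df$chl_mg_m3, "chl_qc")
  df$bbp700_m1 <- apply_qc(df$bbp700_m1, "bbp700_qc")
  if ("par_umol_m2_s" %in% names(df)) {
    df$par_umol_m2_s <- apply_qc(df$par_umol_m2_s, "par_qc")
  }

  records <- list()
  for (cid in unique(df$cycle_id)) {
    sub <- df[df$cycle_id == cid, , drop = FALSE]
    lat <- sub$latitude[1]
    if ("depth_m" %in% names(sub) && any(is.finite(sub$depth_m))) {
      depth <- sub$depth_m
      pressure <- if ("pressure_dbar" %in% names(sub)) sub$pressure_dbar else NULL
    } else {
      pressure <- sub$pressure_dbar
      depth <- pressure_to_depth(pressure, lat)
    }
    if (any(!is.finite(depth)) || any(diff(depth) <= 0)) {
      warning("cycle ", cid, ": depth not strictly increasing; record rejected")
      next
    }
    rec <- profile_record(
      cycle_id = cid,
      time = parse_utc(sub$time[1]),
      latitude = lat,
      longitude = sub$longitude[1],
      depth = depth,
      pressure = pressure,
      temperature = sub$temperature_c,
      salinity = sub$salinity_psu,
      chl = sub$chl_mg_m3,
      bbp700 = sub$bbp700_m1,
      par = if ("par_umol_m2_s" %in% names(sub)) sub$par_umol_m2_s else NULL,
      oxygen = if ("oxygen_umol_kg" %in% names(sub)) sub$oxygen_umol_kg else NULL
    )
    records[[length(records) + 1L]] <- rec
  }
  ord <- order(vapply(records, function(r) as.numeric(r$time), numeric(1)))
  records[ord]
}

#' Write profiles to long-format CSV
#'
#' Inverse of [read_profiles_csv()]: writes one row per (cycle, depth level).
#' The reader/writer pair round-trips all numeric fields at full double
#' precision.
#'
#' @param records list of [profile_record()] objects
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profiles_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(
      cycle_id = r$cycle_id,
      time = format(r$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      latitude = r$latitude,
      longitude = r$longitude,
      depth_m = r$depth,
      pressure_dbar = r$pressure,
      temperature_c = r$temperature,
      salinity_psu = r$salinity,
      chl_mg_m3 = r$chl,
      bbp700_m1 = r$bbp700,
      par_umol_m2_s = r$par,
      oxygen_umol_kg = r$oxygen
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write fitted parameters and phenology tables
#'
#' Writes the pipeline outputs as CSV: a per-profile parameter table
#' (`fit_parameters.csv`), a per-community phenology table
#' (`phenology.csv`, if given) and the daily community time series
#' (`community_series.csv`, if given). `fits` must be aligned to `records`
#' by `cycle_id`.
#'
#' @param records list of [profile_record()] objects
#' @param fits list of per-profile fit results (elements with `cycle_id`,
#'   `context`, `chl`, and optionally `bbp`), as produced by [run_pipeline()]
#' @param phenology optional data.frame of phenology metrics
#' @param series optional data.frame of daily community series
#'   (columns `time`, `community`, `value`)
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_results <- function(records, fits, phenology = NULL, series = NULL, dir) {
  rec_ids <- vapply(records, function(r) r$cycle_id, integer(1))
  fit_ids <- vapply(fits, function(f) as.integer(f$cycle_id), integer(1))
  if (!all(fit_ids %in% rec_ids)) {
    stop("fits are misaligned with records: unknown cycle_id(s) ",
         paste(setdiff(fit_ids, rec_ids), collapse = ", "))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x) || length(x) == 0) NA_character_ else x
  fit_row <- function(f) {
    ctx <- f$context; chl <- f$chl; bbp <- f$bbp
    ci <- function(fit, par, which) {
      if (is.null(fit) || is.null(fit$ci) || !(par %in% rownames(fit$ci))) {
        return(NA_real_)
      }
      fit$ci[par, which]
    }
    data.frame(
      cycle_id = as.integer(f$cycle_id),
      time = format(f$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      mode = chr(chl$mode),
      Kd = num(ctx$Kd), Kd_source = chr(ctx$Kd_source),
      B_s = num(if (is.null(chl)) NULL else chl$B_s),
      b_bp_s = num(ctx$b_bp_s),
      Z_p = num(ctx$Z_p), Z_m = num(ctx$Z_m),
      strat_index = num(ctx$strat_index),
      P1 = num(chl$P1), P1_lo = ci(chl, "P1", 1), P1_hi = ci(chl, "P1", 2),
      tau1 = num(chl$tau1), tau1_lo = ci(chl, "tau1", 1), tau1_hi = ci(chl, "tau1", 2),
      B2m_star = num(chl$B2m_star),
      B2m_star_lo = ci(chl, "B2m_star", 1), B2m_star_hi = ci(chl, "B2m_star", 2),
      tau2 = num(chl$tau2), tau2_lo = ci(chl, "tau2", 1), tau2_hi = ci(chl, "tau2", 2),
      sigma = num(chl$sigma), sigma_lo = ci(chl, "sigma", 1), sigma_hi = ci(chl, "sigma", 2),
      r2_step1 = num(chl$r2_step1),
      aic_step1 = num(chl$aic_step1), aic_step2 = num(chl$aic_step2),
      n_points = if (is.null(chl)) NA_integer_ else chl$n_points,
      bbpk_star = num(bbp$bbpk_star),
      bbpk_star_lo = ci(bbp, "bbpk_star", 1), bbpk_star_hi = ci(bbp, "bbpk_star", 2),
      omega2 = num(bbp$omega2),
      omega2_lo = ci(bbp, "omega2", 1), omega2_hi = ci(bbp, "omega2", 2),
      omega1 = num(bbp$omega1),
      bbp1B = num(bbp$bbp1B), bbp2B = num(bbp$bbp2B), bbpk = num(bbp$bbpk),
      stringsAsFactors = FALSE
    )
  }
  params <- if (length(fits)) {
    do.call(rbind, lapply(fits, fit_row))
  } else {
    fit_row(list(cycle_id = NA_integer_, time = as.POSIXct(NA),
                 context = list(), chl = NULL, bbp = NULL))[0, ]
  }
  paths <- c(fit_parameters = file.path(dir, "fit_parameters.csv"))
  utils::write.csv(params, paths[["fit_parameters"]], row.names = FALSE, na = "")

  if (!is.null(phenology)) {
    paths["phenology"] <- file.path(dir, "phenology.csv")
    utils::write.csv(phenology, paths[["phenology"]], row.names = FALSE, na = "")
  }
  if (!is.null(series)) {
    paths["community_series"] <- file.path(dir, "community_series.csv")
    utils::write.csv(series, paths[["community_series"]], row.names = FALSE, na = "")
  }
  invisible(paths)
}
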