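#' Pipeline configuration
#'
#' Bundles inputs and every stage threshold for [run_pipeline()].  Thresholds
#' default to the values the processing chain is defined with: GPS kept at
#' >= 5 satellites and residual <= 35 with a 50 m ellipse assigned; Argos
#' kept at semi-major axis <= 3 km; speed filter 5 m/s; spike angles 15/25
#' degrees with 2500/5000 m excursions; Argos within 10 min of GPS dropped;
#' > 500 m error fixes within 20 min of a <= 500 m fix dropped; segments
#' split at > 6 h gaps and kept at >= 4 locations spanning >= 3 h; posterior
#' state threshold 0.9; kernel bandwidths 75 km (summer) / 100 km (winter).
#'
#' Either `sim` (a [sim_config()]) or all three input `paths` must be given.
#'
#' @param sim a [sim_config()] describing synthetic input, or `NULL`.
#' @param paths named list `locations`, `dives`, `mask` of CSV paths, or
#'   `NULL`.
#' @param coastline coastline polygons ([read_geojson()] format or GeoJSON
#'   path); defaults to [synthetic_coastline()] when simulating, none
#'   otherwise.
#' @param out_dir directory for intermediate tables (`NULL` = do not write).
#' @param gap_h,min_locs,min_span_h segmentation thresholds.
#' @param share_ctcrw fit one CTCRW per animal instead of per segment.
#' @param multi_start run the full m1-m5 multi-start HMM protocol (default)
#'   or the m1 start only.
#' @param threshold posterior probability for a hard state label.
#' @param bandwidth_summer_km,bandwidth_winter_km,ud_cell_km,reach_km
#'   utilization-distribution parameters.
#' @param seed overrides the simulation seed when given.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, coastline = NULL,
                            out_dir = NULL, gap_h = 6, min_locs = 4,
                            min_span_h = 3, share_ctcrw = FALSE,
                            multi_start = TRUE, threshold = 0.9,
                            bandwidth_summer_km = 75, bandwidth_winter_km = 100,
                            ud_cell_km = 10, reach_km = 100, seed = NULL) {
  if (is.null(sim) && is.null(paths))
    stop("either a sim_config or input paths must be supplied")
  if (!is.null(sim)) {
    validate_sim_config(sim)
    if (!is.null(seed)) sim$seed <- as.integer(seed)
    if (is.null(coastline)) coastline <- synthetic_coastline()
  }
  stopifnot(gap_h > 0, min_locs > 0, min_span_h > 0, threshold > 0,
            bandwidth_summer_km > 0, bandwidth_winter_km > 0,
            ud_cell_km > 0, reach_km >= 0)
  structure(list(sim = sim, paths = paths, coastline = coastline,
                 out_dir = out_dir, gap_h = gap_h, min_locs = min_locs,
                 min_span_h = min_span_h, share_ctcrw = share_ctcrw,
                 multi_start = multi_start, threshold = threshold,
                 bandwidth_summer_km = bandwidth_summer_km,
                 bandwidth_winter_km = bandwidth_winter_km,
                 ud_cell_km = ud_cell_km, reach_km = reach_km),
            class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema checks for the three CSV inputs: required columns, timestamp
#' parseability (offending row indices are reported), per-source quality
#' fields, and duplicate rows.
#'
#' @param paths named list with elements `locations` and optionally `dives`
#'   and `mask`.
#' @return invisibly, a character vector of problems (empty when valid);
#'   errors are also raised as one itemized message.
#' @export
validate_inputs <- function(paths) {
  probs <- character(0)
  note <- function(...) probs <<- c(probs, sprintf(...))
  if (!is.null(paths$locations)) {
    x <- read.csv(paths$locations, stringsAsFactors = FALSE)
    need <- c("id", "timestamp", "lon", "lat", "source", "n_sat", "residual",
              "smaj_m", "smin_m", "orient_deg")
    miss <- setdiff(need, names(x))
    if (length(miss)) note("locations: missing column(s) %s", paste(miss, collapse = ", "))
    if ("timestamp" %in% names(x)) {
      tp <- .parse_time_lenient(x$timestamp)
      if (any(is.na(tp)))
        note("locations: unparseable timestamp at row(s) %s",
             paste(head(which(is.na(tp)), 10), collapse = ", "))
    }
    if (all(c("lon", "lat") %in% names(x))) {
      if (any(abs(x$lat) > 90, na.rm = TRUE)) note("locations: latitude outside [-90, 90]")
      if (any(abs(x$lon) > 180, na.rm = TRUE)) note("locations: longitude outside [-180, 180]")
    }
    if (all(c("source", "smaj_m") %in% names(x))) {
      a <- x$source == "Argos"
      if (any(a & is.na(x$smaj_m)))
        note("locations: missing smaj_m on %d Argos row(s)", sum(a & is.na(x$smaj_m)))
    }
    if (anyDuplicated(x)) note("locations: %d duplicate row(s)", sum(duplicated(x)))
  } else note("locations path missing")
  if (!is.null(paths$dives)) {
    d <- read.csv(paths$dives, stringsAsFactors = FALSE)
    need <- c("id", "start", "dive_type")
    miss <- setdiff(need, names(d))
    if (length(miss)) note("dives: missing column(s) %s", paste(miss, collapse = ", "))
    if ("start" %in% names(d)) {
      tp <- .parse_time_lenient(d$start)
      if (any(is.na(tp)))
        note("dives: unparseable start at row(s) %s",
             paste(head(which(is.na(tp)), 10), collapse = ", "))
    }
  }
  if (!is.null(paths$mask)) {
    m <- read.csv(paths$mask, stringsAsFactors = FALSE)
    miss <- setdiff(c("id", "hour_start", "has_depth_data"), names(m))
    if (length(miss)) note("mask: missing column(s) %s", paste(miss, collapse = ", "))
  }
  if (length(probs))
    stop("input validation failed:\n  - ", paste(probs, collapse = "\n  - "))
  invisible(probs)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> QC -> CTCRW hourly interpolation -> HMM
#' fitting and decoding -> seasonal utilization distributions and phase
#' labelling -> dive linkage and foraging summaries, from a single
#' configuration.  All intermediate tables are written to `out_dir` when
#' given, and the returned report carries per-stage record counts so the
#' whole filtering cascade is auditable.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a list of class `pipeline_result`: `truth` (synthetic runs only),
#'   `locations`, `qc` (segments + report), `hourly`, `ctcrw_params`
#'   (per-segment fits), `hmm` (the fitted
#'   `move_hmm`), `decoded`, `uds` (summer/winter `seasonal_ud`), `phased`,
#'   `counts` (per-hour dive counts), `summary` (the `foraging_summary`),
#'   and `report` (named record counts through the stages).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulating %d animals (seed %d)", config$sim$n_animals, config$sim$seed)
    sim <- .stage("simulate", {
      tr <- simulate_tracks(config$sim)
      dv <- simulate_dives(tr$truth, config$sim)
      c(tr, dv)
    })
    truth <- sim$truth
    locations <- sim$locations
    dives <- sim$dives
    mask <- sim$mask
  } else {
    say("loading inputs")
    locations <- .stage("load", {
      validate_inputs(config$paths)
      read_locations_csv(config$paths$locations)
    })
    dives <- if (!is.null(config$paths$dives))
      .stage("load", read_dives_csv(config$paths$dives)) else NULL
    mask <- if (!is.null(config$paths$mask))
      .stage("load", read_dives_csv(config$paths$mask)) else NULL
  }

  say("QC filtering %d raw locations", nrow(locations))
  qc <- .stage("track_qc", qc_track(locations, gap_h = config$gap_h,
                                    min_locs = config$min_locs,
                                    min_span_h = config$min_span_h))
  say("CTCRW interpolation of %d segments", length(unique(qc$segments$segment)))
  interp <- .stage("ctcrw", interpolate_hourly(qc$segments,
                                               share_params = config$share_ctcrw))
  hourly <- interp$hourly
  ctcrw_params <- interp$params

  say("fitting movement HMM on %d hourly locations", nrow(hourly))
  series <- .stage("hmm", steps_and_angles(hourly))
  hmm <- .stage("hmm", {
    f1 <- fit_hmm(series)
    if (config$multi_start) {
      inits <- c(list(m1 = hmm_m1_init()), hmm_init_protocol(f1, series))
      fit_hmm(series, init_sets = inits)
    } else f1
  })
  decoded <- .stage("hmm", decode_locations(hmm, hourly, config$threshold))

  say("seasonal utilization distributions")
  ctr <- .centroid_lonlat(decoded$lon, decoded$lat)
  uds <- .stage("phases", {
    su <- seasonal_ars_ud(decoded, "summer",
                          bandwidth_km = config$bandwidth_summer_km,
                          cell_km = config$ud_cell_km, proj_centre = ctr)
    wu <- seasonal_ars_ud(decoded, "winter",
                          bandwidth_km = config$bandwidth_winter_km,
                          cell_km = config$ud_cell_km, proj_centre = ctr)
    if (!is.null(config$coastline)) {
      su <- extend_to_land(su, config$coastline, config$reach_km)
      wu <- extend_to_land(wu, config$coastline, config$reach_km)
    }
    list(summer = su, winter = wu)
  })
  phased <- .stage("phases", label_phase(decoded, uds$summer, uds$winter))

  summary <- NULL; counts <- NULL
  if (!is.null(dives) && !is.null(mask)) {
    say("linking %d dive events", nrow(dives))
    counts <- .stage("dives", {
      cm <- mark_complete_hours(dives, mask)
      count_foraging_per_hour(dives, phased, cm)
    })
    summary <- .stage("dives", summarize_foraging(phased, counts))
  }

  report <- c(raw_locations = nrow(locations),
              qc_passed = nrow(qc$segments),
              segments = length(unique(qc$segments$segment)),
              hourly = nrow(hourly),
              decoded = nrow(decoded),
              non_uncertain = sum(decoded$label != "Uncertain"),
              long_distance = sum(phased$phase %in% c("fall", "spring") &
                                    phased$label != "Uncertain"),
              complete_dive_hours = if (!is.null(summary))
                unname(summary$n["complete"]) else NA_integer_)

  res <- structure(list(truth = truth, locations = locations, qc = qc,
                        hourly = hourly, ctcrw_params = ctcrw_params,
                        hmm = hmm, decoded = decoded,
                        uds = uds, phased = phased, counts = counts,
                        summary = summary, report = report,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  res
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x)) write_table_csv(x, file.path(out_dir, f))
  w(res$locations, "locations_raw.csv")
  w(res$qc$segments, "locations_qc.csv")
  w(res$qc$report, "qc_report.csv")
  w(res$hourly, "hourly.csv")
  w(res$ctcrw_params, "ctcrw_params.csv")
  w(res$hmm$diagnostics, "hmm_fits.csv")
  w(res$decoded, "decoded.csv")
  w(res$phased, "decoded_phased.csv")
  w(res$counts, "hourly_dive_counts.csv")
  if (!is.null(res$truth)) w(res$truth, "truth.csv")
  if (!is.null(res$summary)) {
    w(res$summary$cells, "foraging_summary.csv")
    w(res$summary$histogram, "foraging_histogram.csv")
  }
  for (season in names(res$uds)) {
    ud <- res$uds[[season]]
    polys <- if (!is.null(ud$contours_ext)) ud$contours_ext else ud$contours
    ctr <- ud$proj_centre
    geo <- lapply(polys, function(r) {
      ll <- aeqd_unproject(r[, 1], r[, 2], ctr["lon"], ctr["lat"])
      list(cbind(ll$lon, ll$lat))
    })
    if (length(geo))
      write_geojson(geo, file.path(out_dir, paste0("ud_", season, ".geojson")),
                    properties = rep(list(list(season = season,
                                               bandwidth_km = ud$bandwidth_km,
                                               extended = ud$extended)),
                                     length(geo)))
  }
  write_table_csv(data.frame(stage = names(res$report), n = unname(res$report)),
                  file.path(out_dir, "pipeline_report.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Movement-state pipeline run\n")
  for (nm in names(x$report))
    cat(sprintf("  %-20s %s\n", nm, format(x$report[[nm]], big.mark = ",")))
  if (!is.null(x$summary)) { cat("\n"); print(x$summary) }
  invisible(x)
}
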