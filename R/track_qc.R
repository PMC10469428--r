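#' Location quality-control filters
#'
#' The filtering cascade applied to mixed Fastloc-GPS/Argos tracks before
#' state-space interpolation.  Each filter only removes rows (and, for GPS,
#' assigns a nominal error ellipse); none reorders timestamps or edits
#' coordinates.  The full cascade, in its fixed order, is available as
#' [qc_track()].
#'
#' * `qc_gps()` drops GPS fixes computed from fewer than 5 satellites and/or
#'   with a residual above 35, then assigns survivors a 50 m circular error
#'   ellipse (orientation 0); GPS rows with missing quality fields are dropped
#'   with a warning.
#' * `qc_argos_error()` drops Argos fixes whose semi-major axis error exceeds
#'   3 km (strictly; 3000 m is kept).
#' * `dedup_argos_near_gps()` drops Argos fixes strictly within 10 min of any
#'   GPS fix (exactly 10 min is kept); GPS rows are never removed.
#' * `prune_low_accuracy()` drops fixes with semi-major axis error > 500 m
#'   that occur within 20 min of a fix with error <= 500 m.
#'
#' @param locations data frame of raw locations (columns `id`, `timestamp`,
#'   `lon`, `lat`, `source`, `n_sat`, `residual`, `smaj_m`, `smin_m`,
#'   `orient_deg`).
#' @param track a single-animal data frame in the same layout.
#' @param n_sat_min,residual_max GPS quality thresholds.
#' @param gps_ellipse_m nominal error ellipse radius assigned to surviving
#'   GPS fixes (m).
#' @param smaj_max_m Argos semi-major axis cutoff (m).
#' @param window_min time window (minutes).
#' @param err_m semi-major axis error defining a low-accuracy fix (m).
#' @return the filtered data frame (same columns, possibly fewer rows).
#' @name track-filters
NULL

#' @rdname track-filters
#' @export
qc_gps <- function(locations, n_sat_min = 5, residual_max = 35,
                   gps_ellipse_m = 50) {
  g <- locations$source == "GPS"
  miss <- g & (is.na(locations$n_sat) | is.na(locations$residual))
  if (any(miss))
    warning(sum(miss), " GPS location(s) missing quality fields removed")
  bad <- g & (miss | locations$n_sat < n_sat_min | locations$residual > residual_max)
  out <- locations[!bad, , drop = FALSE]
  g2 <- out$source == "GPS"
  out$smaj_m[g2] <- gps_ellipse_m
  out$smin_m[g2] <- gps_ellipse_m
  out$orient_deg[g2] <- 0
  rownames(out) <- NULL
  out
}

#' @rdname track-filters
#' @export
qc_argos_error <- function(locations, smaj_max_m = 3000) {
  a <- locations$source == "Argos"
  bad <- a & (is.na(locations$smaj_m) | locations$smaj_m > smaj_max_m)
  out <- locations[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# great-circle distances (m) between consecutive rows
.seg_dist_m <- function(track) {
  n <- nrow(track)
  if (n < 2) return(numeric(0))
  geosphere::distGeo(cbind(track$lon[-n], track$lat[-n]),
                     cbind(track$lon[-1], track$lat[-1]))
}

#' Speed-distance-angle prefilter for Argos locations
#'
#' Removes implausible Argos fixes from a single animal's chronologically
#' ordered track using two deterministic stages.  First, any interior point
#' whose implied speed both from its previous and to its next retained
#' neighbour exceeds `vmax_ms` is removed, worst violator first, until no
#' violations remain.  Second, "spike" points are removed: a point whose inner
#' angle (between the vectors to its neighbours) is below `angles_deg[1]`
#' (resp. `angles_deg[2]`) while both adjacent segment lengths are at least
#' `spike_limits_m[1]` (resp. `spike_limits_m[2]`), iterated to a fixed point.
#' The filter is idempotent on its own output and returns tracks with fewer
#' than 3 locations unchanged.
#'
#' @param argos_track single-animal, chronologically ordered Argos locations.
#' @param vmax_ms maximum plausible sustained speed (m/s).
#' @param angles_deg the two spike angle thresholds (degrees).
#' @param spike_limits_m the excursion lengths (m) above which the respective
#'   angle thresholds apply.
#' @return the filtered track.
#' @export
sda_filter <- function(argos_track, vmax_ms = 5, angles_deg = c(15, 25),
                       spike_limits_m = c(2500, 5000)) {
  tr <- argos_track
  if (nrow(tr) < 3) return(tr)
  if (is.unsorted(as.numeric(tr$timestamp)))
    stop("sda_filter expects a chronologically ordered track")

  # stage 1: iterative worst-first speed filter
  repeat {
    n <- nrow(tr)
    if (n < 3) break
    d <- .seg_dist_m(tr)
    dt <- diff(as.numeric(tr$timestamp))          # s
    sp <- d / pmax(dt, 1e-9)                      # m/s per segment
    v_in <- sp[-(n - 1)]                          # into point 2..n-1
    v_out <- sp[-1]                               # out of point 2..n-1
    viol <- pmin(v_in, v_out)                     # both sides must exceed vmax
    if (all(viol <= vmax_ms)) break
    worst <- which.max(viol) + 1L
    tr <- tr[-worst, , drop = FALSE]
  }

  # stage 2: spike (angle/distance) filter, iterated to a fixed point
  repeat {
    n <- nrow(tr)
    if (n < 3) break
    removed <- FALSE
    d <- .seg_dist_m(tr)
    b_fwd <- geosphere::bearing(cbind(tr$lon[-n], tr$lat[-n]),
                                cbind(tr$lon[-1], tr$lat[-1]))
    # inner angle at interior point i: between vectors i->i-1 and i->i+1
    ang <- abs(.wrap_angle((b_fwd[-1] - b_fwd[-(n - 1)]) * pi / 180)) * 180 / pi
    inner <- 180 - ang
    exc <- pmin(d[-(n - 1)], d[-1])
    spike <- (inner < angles_deg[1] & exc >= spike_limits_m[1]) |
             (inner < angles_deg[2] & exc >= spike_limits_m[2])
    if (any(spike)) {
      worst <- which.min(ifelse(spike, inner, Inf)) + 1L
      tr <- tr[-worst, , drop = FALSE]
      removed <- TRUE
    }
    if (!removed) break
  }
  rownames(tr) <- NULL
  tr
}

#' @rdname track-filters
#' @export
dedup_argos_near_gps <- function(track, window_min = 10) {
  a <- which(track$source == "Argos")
  g <- which(track$source == "GPS")
  if (!length(a) || !length(g)) return(track)
  ta <- as.numeric(track$timestamp[a])
  tg <- sort(as.numeric(track$timestamp[g]))
  idx <- findInterval(ta, tg)
  d_lo <- ifelse(idx >= 1, ta - tg[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(tg), tg[pmin(idx + 1, length(tg))] - ta, Inf)
  near <- pmin(d_lo, d_hi) < window_min * 60   # strict "within"
  out <- track[-a[near], , drop = FALSE]
  if (!any(near)) out <- track
  rownames(out) <- NULL
  out
}

#' @rdname track-filters
#' @export
prune_low_accuracy <- function(track, err_m = 500, window_min = 20) {
  lowacc <- which(!is.na(track$smaj_m) & track$smaj_m > err_m)
  good <- which(!is.na(track$smaj_m) & track$smaj_m <= err_m)
  if (!length(lowacc) || !length(good)) return(track)
  tl <- as.numeric(track$timestamp[lowacc])
  tg <- sort(as.numeric(track$timestamp[good]))
  idx <- findInterval(tl, tg)
  d_lo <- ifelse(idx >= 1, tl - tg[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(tg), tg[pmin(idx + 1, length(tg))] - tl, Inf)
  near <- pmin(d_lo, d_hi) <= window_min * 60
  if (!any(near)) return(track)
  out <- track[-lowacc[near], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a QC-passed track into segments at long gaps
#'
#' Splits at every inter-fix gap strictly greater than `gap_h` hours, then
#' drops segments with fewer than `min_locs` locations or spanning less than
#' `min_span_h` hours.  Surviving segments get ids `<animal>_s<k>`.
#'
#' @param track single-animal, chronologically ordered QC-passed locations.
#' @param gap_h gap threshold (hours, strict).
#' @param min_locs minimum locations per segment.
#' @param min_span_h minimum segment time span (hours).
#' @return data frame with an added `segment` column; zero rows if nothing
#'   survives.
#' @export
segment_track <- function(track, gap_h = 6, min_locs = 4, min_span_h = 3) {
  if (!nrow(track)) {
    track$segment <- character(0)
    return(track)
  }
  tt <- as.numeric(track$timestamp)
  if (is.unsorted(tt)) stop("segment_track expects a chronologically ordered track")
  brk <- c(0, cumsum(diff(tt) > gap_h * 3600))
  keep <- logical(nrow(track))
  seg_id <- character(nrow(track))
  k <- 0L
  for (b in unique(brk)) {
    i <- which(brk == b)
    span_h <- (tt[max(i)] - tt[min(i)]) / 3600
    if (length(i) >= min_locs && span_h >= min_span_h) {
      k <- k + 1L
      keep[i] <- TRUE
      seg_id[i] <- sprintf("%s_s%02d", track$id[i[1]], k)
    }
  }
  out <- track[keep, , drop = FALSE]
  out$segment <- seg_id[keep]
  rownames(out) <- NULL
  out
}

#' Full location QC cascade
#'
#' Applies, per animal and in fixed order: GPS quality filter, Argos ellipse
#' filter, speed-distance-angle filter (Argos only), removal of Argos fixes
#' near GPS fixes, merge, low-accuracy pruning, and gap-based segmentation.
#' Rerunning the cascade on its own output changes nothing.
#'
#' @param locations raw location data frame (all animals).
#' @param gap_h,min_locs,min_span_h segmentation parameters, see
#'   [segment_track()].
#' @param verbose print per-stage removal counts.
#' @return list with `segments` (segmented locations) and `report` (data
#'   frame of per-stage row counts).
#' @export
qc_track <- function(locations, gap_h = 6, min_locs = 4, min_span_h = 3,
                     verbose = FALSE) {
  locations <- locations[order(locations$id, locations$timestamp), , drop = FALSE]
  counts <- c(raw = nrow(locations))
  x <- qc_gps(locations);            counts["gps_qc"] <- nrow(x)
  x <- qc_argos_error(x);            counts["argos_ellipse"] <- nrow(x)
  # every removal can expose new violations among the surviving neighbours
  # (and segment dropping removes rows too), so the per-animal chain
  # sda -> dedup -> prune -> segment is swept to a fixed point; the order
  # within each sweep is as specified and 1-2 sweeps normally suffice
  per_animal <- lapply(split(x, x$id), function(tr) {
    repeat {
      n0 <- nrow(tr)
      a <- tr[tr$source == "Argos", , drop = FALSE]
      g <- tr[tr$source != "Argos", , drop = FALSE]
      a <- sda_filter(a)
      tr <- rbind(g, a)
      tr <- tr[order(tr$timestamp), , drop = FALSE]
      tr <- dedup_argos_near_gps(tr)
      tr <- prune_low_accuracy(tr)
      seg <- segment_track(tr, gap_h = gap_h, min_locs = min_locs,
                           min_span_h = min_span_h)
      if (nrow(seg) == n0) return(seg)
      tr <- seg[setdiff(names(seg), "segment")]
    }
  })
  segs <- do.call(rbind, per_animal)
  rownames(segs) <- NULL
  counts["segmented"] <- nrow(segs)
  report <- data.frame(stage = names(counts), n = unname(counts))
  if (verbose) {
    for (i in seq_len(nrow(report)))
      message(sprintf("%-16s %d", report$stage[i], report$n[i]))
  }
  list(segments = segs, report = report)
}
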