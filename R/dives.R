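#' Foraging dive-type vocabulary
#'
#' The four dive-profile classes treated as foraging throughout the package
#' (`Deep Benthic`, `Deep Pelagic V`, `Deep Pelagic W`, `Intermediate
#' Benthic`), plus the known non-foraging classes that are silently ignored
#' when counting.  Dive-type classification itself is taken as an input.
#'
#' @return character vector of the four foraging type labels.
#' @export
foraging_dive_types <- function() .foraging_types

.known_nonforaging <- c("Skew", "Shallow", "Surface", "Transit Shallow", "Other")

#' Flag hours with complete dive data
#'
#' An hour is complete when its depth time-series data are present and no
#' dive starting in it crosses into an hour whose depth data are missing (a
#' crossing dive cannot be characterised, so the hour it started in is
#' unusable).
#'
#' @param dives dive-event data frame (`id`, `start`, `duration_s`, ...).
#'   A missing `duration_s` column disables the crossing rule with a
#'   warning.
#' @param depth_coverage_mask data frame `id`, `hour_start` (POSIXct, on the
#'   hour), `has_depth_data` (logical); hours absent from the mask are
#'   treated as missing data.
#' @return the mask with an added logical `complete` column.
#' @export
mark_complete_hours <- function(dives, depth_coverage_mask) {
  m <- depth_coverage_mask
  m$complete <- m$has_depth_data
  if (!nrow(dives)) return(m)
  if (is.null(dives$duration_s)) {
    warning("dive table has no duration_s; cannot apply the crossing-dive rule")
    return(m)
  }
  key <- function(id, t) paste(id, as.numeric(t))
  has <- setNames(m$has_depth_data, key(m$id, m$hour_start))
  h0 <- as.POSIXct(floor(as.numeric(dives$start) / 3600) * 3600,
                   origin = "1970-01-01", tz = "UTC")
  dive_end <- as.numeric(dives$start) + dives$duration_s
  crosses <- dive_end > as.numeric(h0) + 3600
  if (any(crosses)) {
    nxt <- key(dives$id[crosses], as.numeric(h0[crosses]) + 3600)
    nxt_missing <- !(nxt %in% names(has)) | !has[nxt]
    bad <- key(dives$id[crosses][nxt_missing], h0[crosses][nxt_missing])
    m$complete[key(m$id, m$hour_start) %in% bad] <- FALSE
  }
  m
}

#' Count foraging dives per decoded hour
#'
#' Counts, for every decoded hourly location, the foraging dives that start
#' during that hour (half-open bin `[t, t+1h)` aligned to the location
#' timestamp).  Only the four foraging dive types are counted; known
#' non-foraging types (including the skew-shaped class) are excluded, and
#' unknown labels are excluded with a warning.
#'
#' @param dives dive-event data frame (`id`, `start`, `dive_type`).
#' @param decoded decoded hourly locations (`id`, `timestamp`).
#' @param mask optional completeness mask (from [mark_complete_hours()]);
#'   when supplied, a `complete` flag is joined on (hours absent from the
#'   mask are flagged incomplete).
#' @return data frame `id`, `hour_start`, `n_foraging`, and `complete` if a
#'   mask was given.
#' @export
count_foraging_per_hour <- function(dives, decoded, mask = NULL) {
  unknown <- !(dives$dive_type %in% c(.foraging_types, .known_nonforaging))
  if (any(unknown))
    warning(sum(unknown), " dive(s) with unknown type label not counted: ",
            paste(unique(dives$dive_type[unknown]), collapse = ", "))
  fg <- dives[dives$dive_type %in% .foraging_types, , drop = FALSE]
  key <- function(id, t) paste(id, as.numeric(t))
  hb <- floor(as.numeric(fg$start) / 3600) * 3600
  cnt <- table(key(fg$id, hb))
  out <- data.frame(id = decoded$id, hour_start = decoded$timestamp)
  k <- key(out$id, out$hour_start)
  out$n_foraging <- as.integer(cnt[k])
  out$n_foraging[is.na(out$n_foraging)] <- 0L
  if (!is.null(mask)) {
    mk <- key(mask$id, mask$hour_start)
    cm <- setNames(mask$complete, mk)
    out$complete <- !is.na(cm[k]) & cm[k]
  }
  out
}

#' Foraging and transit-time summaries by state and phase
#'
#' Produces the quantities that answer whether foraging is suppressed during
#' long-distance movements: for each behavioural state and long-distance leg
#' (Fall, Spring), the percentage of complete decoded hours with at least 1
#' and at least 2 foraging dives, the full dive-count histogram, and -- from
#' all long-distance decoded hours regardless of dive data -- the per-animal
#' and pooled percentage of time in the Transit state.  Uncertain-state
#' hours and incomplete-dive-data hours are excluded (for the dive
#' summaries) before any percentage is formed; the exclusions commute.
#'
#' Percentages are reported both pooled across animals and as the mean of
#' per-animal percentages.
#'
#' @param decoded decoded hourly locations with `label` and `phase` columns
#'   ([label_phase()] output).
#' @param counts per-hour foraging counts with `complete` flags
#'   ([count_foraging_per_hour()] output).
#' @return an object of class `foraging_summary`: `cells` (one row per state
#'   x phase: hours, pct >= 1, pct >= 2, per-animal means; empty cells are
#'   `NA`, not 0), `histogram` (state x phase x dive-count percentages),
#'   `transit_time` (per-animal % Transit during the long-distance phase,
#'   plus pooled mean and range), and `n` bookkeeping.
#' @export
summarize_foraging <- function(decoded, counts) {
  stopifnot(all(c("label", "phase") %in% names(decoded)),
            all(c("n_foraging", "complete") %in% names(counts)))
  key <- function(id, t) paste(id, as.numeric(t))
  k <- key(decoded$id, decoded$timestamp)
  ck <- key(counts$id, counts$hour_start)
  idx <- match(k, ck)
  d <- decoded
  d$n_foraging <- counts$n_foraging[idx]
  d$complete <- !is.na(idx) & counts$complete[idx]

  ld <- d[d$phase %in% c("fall", "spring") & d$label != "Uncertain", , drop = FALSE]

  # transit-time summary (all long-distance decoded hours)
  per_animal <- vapply(split(ld$label, ld$id),
                       function(l) 100 * mean(l == "Transit"), numeric(1))
  transit_time <- list(per_animal = per_animal,
                       mean = mean(per_animal), range = range(per_animal),
                       pooled = 100 * mean(ld$label == "Transit"))

  dd <- ld[ld$complete, , drop = FALSE]
  cells <- list(); hist_rows <- list()
  for (st in .states) for (ph in c("fall", "spring")) {
    x <- dd[dd$label == st & dd$phase == ph, , drop = FALSE]
    nm <- paste(st, ph, sep = ".")
    if (!nrow(x)) {
      cells[[nm]] <- data.frame(state = st, phase = ph, n_hours = 0L,
                                pct_ge1 = NA_real_, pct_ge2 = NA_real_,
                                pct_ge1_animal_mean = NA_real_,
                                pct_ge2_animal_mean = NA_real_)
      next
    }
    pa1 <- vapply(split(x$n_foraging, x$id), function(v) 100 * mean(v >= 1), numeric(1))
    pa2 <- vapply(split(x$n_foraging, x$id), function(v) 100 * mean(v >= 2), numeric(1))
    cells[[nm]] <- data.frame(state = st, phase = ph, n_hours = nrow(x),
                              pct_ge1 = 100 * mean(x$n_foraging >= 1),
                              pct_ge2 = 100 * mean(x$n_foraging >= 2),
                              pct_ge1_animal_mean = mean(pa1),
                              pct_ge2_animal_mean = mean(pa2))
    tb <- table(factor(x$n_foraging, levels = 0:max(x$n_foraging, 0)))
    hist_rows[[nm]] <- data.frame(state = st, phase = ph,
                                  n_dives = as.integer(names(tb)),
                                  n_hours = as.integer(tb),
                                  pct = 100 * as.integer(tb) / nrow(x))
  }
  structure(list(cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 histogram = do.call(rbind, c(hist_rows, make.row.names = FALSE)),
                 transit_time = transit_time,
                 n = c(decoded = nrow(d),
                       long_distance = nrow(ld),
                       complete = nrow(dd))),
            class = "foraging_summary")
}

#' @export
print.foraging_summary <- function(x, ...) {
  cat("Foraging by state and long-distance leg\n")
  cat(sprintf("  hours: %d decoded, %d long-distance non-Uncertain, %d with complete dive data\n",
              x$n["decoded"], x$n["long_distance"], x$n["complete"]))
  tt <- x$transit_time
  cat(sprintf("  %% time in Transit (long-distance): mean %.1f%% (range %.1f-%.1f%%) across %d animals\n",
              tt$mean, tt$range[1], tt$range[2], length(tt$per_animal)))
  cells <- x$cells
  for (i in seq_len(nrow(cells))) {
    if (cells$n_hours[i] == 0) {
      cat(sprintf("  %-7s %-6s : no complete hours\n", cells$state[i], cells$phase[i]))
    } else {
      cat(sprintf("  %-7s %-6s : %4d h, >=1 dive %.1f%%, >=2 dives %.1f%%\n",
                  cells$state[i], cells$phase[i], cells$n_hours[i],
                  cells$pct_ge1[i], cells$pct_ge2[i]))
    }
  }
  invisible(x)
}
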