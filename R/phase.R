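#' Seasonal utilization distribution from ARS-decoded locations
#'
#' Pools the ARS-labelled hourly locations of all animals falling in the
#' season's calendar months (summer: April-September; winter:
#' October-March), computes a bivariate Gaussian kernel density with a fixed
#' bandwidth (the kernel standard deviation: 75 km in summer, 100 km in
#' winter) on a shared projected grid, and extracts the 50% volume contour --
#' the smallest region containing half of the estimated utilization mass.
#'
#' @param decoded decoded hourly locations ([decode_locations()] output):
#'   columns `timestamp`, `lon`, `lat`, `label`.
#' @param season `"summer"` or `"winter"`.
#' @param bandwidth_km kernel standard deviation (km); defaults to 75
#'   (summer) / 100 (winter).
#' @param cell_km grid cell size (km).
#' @param prob contour probability level (default 0.5).
#' @param proj_centre optional named (lon, lat) projection centre; by default
#'   the pooled centroid of all rows of `decoded`, so both seasonal calls on
#'   the same data share one planar frame.
#' @param min_points minimum number of seasonal ARS locations required.
#' @return an object of class `seasonal_ud`: grid vectors `gx`, `gy` (km),
#'   density matrix `z` (integrating to 1 over the grid), contour `level`,
#'   logical `mask` of cells inside the contour, `contours` (list of ring
#'   matrices, planar km), `mass` actually enclosed, the projection centre,
#'   and the season metadata.
#' @export
seasonal_ars_ud <- function(decoded, season = c("summer", "winter"),
                            bandwidth_km = NULL, cell_km = 10, prob = 0.5,
                            proj_centre = NULL, min_points = 30) {
  season <- match.arg(season)
  months <- if (season == "summer") 4:9 else c(10:12, 1:3)
  if (is.null(bandwidth_km)) bandwidth_km <- if (season == "summer") 75 else 100
  if (is.null(proj_centre))
    proj_centre <- .centroid_lonlat(decoded$lon, decoded$lat)
  mo <- as.integer(format(decoded$timestamp, "%m"))
  sel <- decoded$label == "ARS" & mo %in% months
  if (sum(sel) < min_points)
    stop("only ", sum(sel), " ARS locations in ", season,
         " months; kernel density would be unreliable (need >= ", min_points, ")")
  p <- aeqd_project(decoded$lon[sel], decoded$lat[sel],
                    proj_centre["lon"], proj_centre["lat"])
  pad <- 3 * bandwidth_km
  gx <- seq(floor(min(p$x) - pad), ceiling(max(p$x) + pad), by = cell_km)
  gy <- seq(floor(min(p$y) - pad), ceiling(max(p$y) + pad), by = cell_km)
  A <- stats::dnorm(outer(gx, p$x, "-"), sd = bandwidth_km)
  B <- stats::dnorm(outer(gy, p$y, "-"), sd = bandwidth_km)
  z <- (A %*% t(B)) / nrow(p)                       # nx x ny density (km^-2)
  mass <- z * cell_km^2
  ord <- order(z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= prob)[1]
  zk <- z[ord[k]]
  # place the level strictly between the last included and first excluded
  # cell values: same cell set, but no grid node sits exactly on the contour
  # (which would make contour extraction ambiguous)
  below <- z[ord[-seq_len(k)]]
  znext <- if (length(below)) max(below) else 0
  level <- (zk + znext) / 2
  mask <- z >= level
  cl <- contourLines(gx, gy, z, levels = level)
  contours <- lapply(cl, function(c0) cbind(c0$x, c0$y))
  structure(list(season = season, months = months,
                 bandwidth_km = bandwidth_km, cell_km = cell_km, prob = prob,
                 gx = gx, gy = gy, z = z, level = level, mask = mask,
                 mass = sum(mass[mask]), contours = contours,
                 proj_centre = proj_centre, n_points = sum(sel),
                 mask_ext = NULL, extended = FALSE),
            class = "seasonal_ud")
}

#' @export
print.seasonal_ud <- function(x, ...) {
  cat(sprintf("%d%% utilization distribution, %s (months %s)\n",
              round(100 * x$prob), x$season,
              paste(x$months, collapse = ",")))
  cat(sprintf("  %d ARS locations, bandwidth %g km, %d x %d grid @ %g km\n",
              x$n_points, x$bandwidth_km, length(x$gx), length(x$gy), x$cell_km))
  cat(sprintf("  enclosed mass %.3f in %d contour ring(s)%s\n", x$mass,
              length(x$contours),
              if (x$extended) "; extended to land" else ""))
  invisible(x)
}

# bilinear interpolation of matrix M (rows ~ gx, cols ~ gy); 0 outside grid
.bilinear <- function(gx, gy, M, px, py) {
  nx <- length(gx); ny <- length(gy)
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  fx <- (px - gx[1]) / dx; fy <- (py - gy[1]) / dy
  i <- floor(fx); j <- floor(fy)
  ok <- i >= 0 & i <= nx - 1 & j >= 0 & j <= ny - 1
  out <- numeric(length(px))
  ii <- pmin(i[ok], nx - 2); jj <- pmin(j[ok], ny - 2)
  tx <- fx[ok] - ii; ty <- fy[ok] - jj
  i1 <- ii + 1; j1 <- jj + 1       # 1-based lower indices
  out[ok] <- M[cbind(i1, j1)] * (1 - tx) * (1 - ty) +
    M[cbind(i1 + 1, j1)] * tx * (1 - ty) +
    M[cbind(i1, j1 + 1)] * (1 - tx) * ty +
    M[cbind(i1 + 1, j1 + 1)] * tx * ty
  out
}

#' Extend a utilization polygon to the nearest land barrier
#'
#' Unions the 50% utilization region with the strip between its boundary and
#' the nearest coastline, so that short on-shelf movements between the
#' contour and the shore are still treated as residency.  Operationally the
#' coastline rings are densified, each boundary cell of the utilization mask
#' is connected to its nearest coast point when that lies within `reach_km`,
#' and the cells along those connecting segments (with a light morphological
#' closing) are added to the mask.  If no coast lies within reach
#' the region is returned unchanged.  Extension only ever adds area.
#'
#' @param ud a [seasonal_ars_ud()] object.
#' @param coastline coastline polygons: a GeoJSON path or the list format of
#'   [read_geojson()] (lon/lat rings).
#' @param reach_km maximum distance (km) over which to extend.
#' @return the `seasonal_ud` with `mask_ext`, extended `contours_ext`, and
#'   `extended = TRUE` when any extension occurred.
#' @export
extend_to_land <- function(ud, coastline, reach_km = 100) {
  stopifnot(inherits(ud, "seasonal_ud"))
  if (is.character(coastline)) coastline <- read_geojson(coastline)
  ctr <- ud$proj_centre
  # densified, projected coast boundary points
  coast <- list()
  for (geom in coastline) for (r in geom) {
    pr <- aeqd_project(r[, 1], r[, 2], ctr["lon"], ctr["lat"])
    xy <- cbind(pr$x, pr$y)
    for (i in seq_len(nrow(xy) - 1)) {
      a <- xy[i, ]; b <- xy[i + 1, ]
      len <- sqrt(sum((b - a)^2))
      tfrac <- seq(0, 1, length.out = max(2, ceiling(len / (ud$cell_km / 2)) + 1))
      coast[[length(coast) + 1]] <- cbind(a[1] + tfrac * (b[1] - a[1]),
                                          a[2] + tfrac * (b[2] - a[2]))
    }
  }
  ud$mask_ext <- ud$mask
  ud$extended <- FALSE
  ud$reach_km <- reach_km
  if (!length(coast)) {
    ud$contours_ext <- ud$contours
    return(ud)
  }
  coast <- do.call(rbind, coast)
  # keep coast points anywhere near the grid
  gx <- ud$gx; gy <- ud$gy; cell <- ud$cell_km
  nearg <- coast[, 1] >= gx[1] - reach_km & coast[, 1] <= gx[length(gx)] + reach_km &
           coast[, 2] >= gy[1] - reach_km & coast[, 2] <= gy[length(gy)] + reach_km
  coast <- coast[nearg, , drop = FALSE]
  mask <- ud$mask
  if (nrow(coast)) {
    # boundary cells: masked cells with an unmasked 4-neighbour
    nx <- length(gx); ny <- length(gy)
    pad <- matrix(FALSE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- mask
    nb <- pad[1:nx, 2:(ny + 1)] & pad[3:(nx + 2), 2:(ny + 1)] &
          pad[2:(nx + 1), 1:ny] & pad[2:(nx + 1), 3:(ny + 2)]
    bidx <- which(mask & !nb, arr.ind = TRUE)
    ext <- mask
    for (k in seq_len(nrow(bidx))) {
      bx <- gx[bidx[k, 1]]; by <- gy[bidx[k, 2]]
      d2 <- (coast[, 1] - bx)^2 + (coast[, 2] - by)^2
      jmin <- which.min(d2)
      if (sqrt(d2[jmin]) > reach_km) next
      tx <- coast[jmin, 1]; ty <- coast[jmin, 2]
      npt <- max(2, ceiling(sqrt(d2[jmin]) / (cell / 2)) + 1)
      sx <- seq(bx, tx, length.out = npt); sy <- seq(by, ty, length.out = npt)
      ci <- round((sx - gx[1]) / cell) + 1
      cj <- round((sy - gy[1]) / cell) + 1
      ok <- ci >= 1 & ci <= nx & cj >= 1 & cj <= ny
      ext[cbind(ci[ok], cj[ok])] <- TRUE
    }
    if (any(ext & !mask)) {
      ud$extended <- TRUE
      # light closing pass: fill cells with >= 3 extended 4-neighbours
      for (pass in 1:2) {
        pad[] <- FALSE
        pad[2:(nx + 1), 2:(ny + 1)] <- ext
        cnt <- pad[1:nx, 2:(ny + 1)] + pad[3:(nx + 2), 2:(ny + 1)] +
               pad[2:(nx + 1), 1:ny] + pad[2:(nx + 1), 3:(ny + 2)]
        ext <- ext | (cnt >= 3)
      }
      ud$mask_ext <- ext
    }
  }
  cl <- contourLines(gx, gy, (ud$mask_ext + 0), levels = 0.5)
  ud$contours_ext <- lapply(cl, function(c0) cbind(c0$x, c0$y))
  ud
}

#' Membership test against a (possibly extended) utilization region
#'
#' Points exactly on the contour count as inside: membership is bilinear
#' interpolation of the density surface at or above the contour level (or of
#' the extended mask at or above 0.5), the same surfaces the contour lines
#' are drawn from.
#'
#' @param ud a `seasonal_ud`.
#' @param lon,lat point coordinates.
#' @param extended use the land-extended region if available.
#' @return logical vector.
#' @export
in_ud <- function(ud, lon, lat, extended = TRUE) {
  p <- aeqd_project(lon, lat, ud$proj_centre["lon"], ud$proj_centre["lat"])
  inside <- .bilinear(ud$gx, ud$gy, ud$z, p$x, p$y) >= ud$level * (1 - 1e-6)
  if (extended && !is.null(ud$mask_ext)) {
    inside_ext <- .bilinear(ud$gx, ud$gy, ud$mask_ext + 0, p$x, p$y) >= 0.5 * (1 - 1e-6)
    inside <- inside | inside_ext
  }
  inside
}

#' Label decoded locations by movement phase
#'
#' Partitions every decoded location into `residency` (inside either
#' extended seasonal utilization region), `fall` (outside both, and the
#' animal most recently departed the summer region or has not yet entered
#' any), or `spring` (most recently departed the winter region).  Labels are
#' assigned per animal in chronological order.
#'
#' Departures refer to sustained residency: consecutive residency hours form
#' a run, and the run as a whole is attributed to the season whose
#' utilization density (relative to its own 50% contour level) dominates
#' over the run.  Pooled seasonal kernels can overlap -- early-winter
#' locations falling in the summer month window put summer-UD mass over the
#' winter area -- and an instantaneous polygon-identity rule would let a
#' brief flicker into such an overlap flip the label of the whole next leg.
#'
#' @param decoded decoded hourly locations.
#' @param summer_ud,winter_ud `seasonal_ud` objects (extended with
#'   [extend_to_land()] if a coastline is available).
#' @return `decoded` with an added `phase` column.
#' @export
label_phase <- function(decoded, summer_ud, winter_ud) {
  in_s <- in_ud(summer_ud, decoded$lon, decoded$lat)
  in_w <- in_ud(winter_ud, decoded$lon, decoded$lat)
  # density relative to each season's contour level: which core is the
  # animal actually in?
  sc_s <- .ud_score(summer_ud, decoded$lon, decoded$lat)
  sc_w <- .ud_score(winter_ud, decoded$lon, decoded$lat)
  phase <- character(nrow(decoded))
  for (id in unique(decoded$id)) {
    i <- which(decoded$id == id)
    i <- i[order(decoded$timestamp[i])]
    res <- in_s[i] | in_w[i]
    if (!any(res))
      warning("animal ", id, " never enters a residency polygon; ",
              "all its locations labelled long-distance")
    r <- rle(res)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    last_res <- NA_character_
    for (b in seq_along(r$values)) {
      k <- i[starts[b]:ends[b]]
      if (r$values[b]) {
        phase[k] <- "residency"
        last_res <- if (mean(sc_s[k] >= sc_w[k]) >= 0.5) "summer" else "winter"
      } else {
        phase[k] <- if (is.na(last_res) || last_res == "summer") "fall" else "spring"
      }
    }
  }
  decoded$phase <- phase
  decoded
}

.ud_score <- function(ud, lon, lat) {
  p <- aeqd_project(lon, lat, ud$proj_centre["lon"], ud$proj_centre["lat"])
  .bilinear(ud$gx, ud$gy, ud$z, p$x, p$y) / ud$level
}

#' Synthetic coastline for simulated tracks
#'
#' A deliberately simple, synthetic stand-in for a coastline GeoJSON input:
#' one land polygon south of the simulated movement corridor with a gently
#' undulating shoreline.  It is not a real coastline and exists so that the
#' land-extension step has a barrier to work against in examples and tests.
#'
#' @param shore_lat mean shoreline latitude (degrees).
#' @param lon_range longitude extent of the polygon.
#' @param amplitude_deg amplitude of the shoreline undulation (degrees
#'   latitude).
#' @return a single-geometry list in the [read_geojson()] format.
#' @export
synthetic_coastline <- function(shore_lat = 68.8, lon_range = c(-179.5, -120.5),
                                amplitude_deg = 0.3) {
  lon <- seq(lon_range[1], lon_range[2], by = 0.5)
  lat <- shore_lat + amplitude_deg * sin(lon * pi / 15)
  ring <- rbind(cbind(lon, lat),
                c(lon_range[2], 60), c(lon_range[1], 60),
                cbind(lon[1], lat[1]))
  list(list(ring))
}
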