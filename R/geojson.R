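#' Minimal GeoJSON polygon I/O
#'
#' Reads and writes GeoJSON `Polygon`/`MultiPolygon` geometries (optionally
#' wrapped in Features/FeatureCollections) as plain R lists.  A geometry is
#' represented as a list of rings, each ring a two-column matrix of (lon,
#' lat) with the first vertex repeated at the end.  This covers the
#' coastline-input and utilization-distribution-output needs of the pipeline;
#' it is not a general GIS reader.
#'
#' @param path file path.
#' @return `read_geojson()`: a list of geometries (each a list of ring
#'   matrices).
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geoms <- list()
  push_geom <- function(geom) {
    ring_mat <- function(r)
      do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    if (geom$type == "Polygon") {
      geoms[[length(geoms) + 1]] <<- lapply(geom$coordinates, ring_mat)
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates)
        geoms[[length(geoms) + 1]] <<- lapply(poly, ring_mat)
    } else stop("unsupported GeoJSON geometry: ", geom$type)
  }
  walk <- function(node) {
    if (is.null(node$type)) return()
    switch(node$type,
           FeatureCollection = for (f in node$features) walk(f),
           Feature = push_geom(node$geometry),
           push_geom(node))
  }
  walk(g)
  geoms
}

#' @rdname read_geojson
#' @param polygons list of geometries (list of ring matrices, lon/lat).
#' @param properties optional list of property lists, one per geometry.
#' @export
write_geojson <- function(polygons, path, properties = NULL) {
  features <- lapply(seq_along(polygons), function(i) {
    rings <- lapply(polygons[[i]], function(r) {
      if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1], r[j, 2]))
    })
    list(type = "Feature",
         properties = if (is.null(properties)) list() else properties[[i]],
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

# even-odd point-in-polygon over a list of rings; boundary points count as
# inside (within a small tolerance of an edge)
.point_in_rings <- function(px, py, rings, tol = 1e-9) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (r in rings) {
    x <- r[, 1]; y <- r[, 2]
    n <- nrow(r)
    if (all(r[1, ] == r[n, ])) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
    j <- n
    for (i in seq_len(n)) {
      xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
      # edge hit test
      dx <- xj - xi; dy <- yj - yi
      len2 <- dx^2 + dy^2
      if (len2 > 0) {
        t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
        d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
        on_edge <- on_edge | d2 <= tol^2
      }
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi + (yj == yi) * 1e-300) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside | on_edge
}
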