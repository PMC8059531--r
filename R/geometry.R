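# Planar polygon utilities for spatial filtering of occurrence records.
# Coordinates are WGS84 decimal degrees treated as planar lon/lat; study
# regions here are small enough that great-circle effects are negligible
# relative to the coarseness of historical georeferences.

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd (ray crossing) membership test for a set of points against one
#' polygon ring. Points lying exactly on an edge or vertex are counted as
#' inside, so records georeferenced to a region border are never silently
#' dropped.
#'
#' @param lon,lat numeric vectors of equal length; point coordinates in
#'   decimal degrees (or any planar units consistent with `ring`).
#' @param ring two-column numeric matrix of polygon vertices (lon, lat).
#'   The ring may be open or closed; it is closed internally.
#' @return logical vector, `TRUE` where the point is inside or on the
#'   boundary. `NA` coordinates give `FALSE`.
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' point_in_polygon(c(0.5, 2, 1), c(0.5, 0.5, 0.5), sq)
#' @export
point_in_polygon <- function(lon, lat, ring) {
  stopifnot(length(lon) == length(lat))
  ring <- as.matrix(ring)
  if (ncol(ring) < 2L || nrow(ring) < 3L)
    stop("polygon ring needs at least 3 vertices with (lon, lat) columns")
  # close the ring
  if (any(ring[1L, 1:2] != ring[nrow(ring), 1:2]))
    ring <- rbind(ring, ring[1L, , drop = FALSE])
  n <- length(lon)
  inside <- logical(n)
  on_edge <- logical(n)
  ok <- !is.na(lon) & !is.na(lat)
  eps <- 1e-12
  for (i in seq_len(nrow(ring) - 1L)) {
    x1 <- ring[i, 1L]; y1 <- ring[i, 2L]
    x2 <- ring[i + 1L, 1L]; y2 <- ring[i + 1L, 2L]
    # boundary check: collinear and within the segment bounding box
    cross <- (x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1)
    seg <- abs(cross) <= eps * pmax(1, abs(x2 - x1) + abs(y2 - y1)) &
      lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    on_edge <- on_edge | (ok & seg)
    # ray crossing (half-open rule keeps vertex crossings consistent)
    crosses <- ((y1 > lat) != (y2 > lat))
    if (any(crosses, na.rm = TRUE)) {
      xint <- x1 + (lat - y1) * (x2 - x1) / (y2 - y1)
      flip <- ok & crosses & (lon < xint)
      inside <- xor(inside, !is.na(flip) & flip)
    }
  }
  out <- (inside | on_edge) & ok
  out[!ok] <- FALSE
  out
}

#' Test points against a set of polygons
#'
#' @param lon,lat point coordinates.
#' @param polys a `polygon_set` (see [read_polygons_geojson()]) or a single
#'   ring matrix.
#' @return logical vector, `TRUE` where the point falls in (or on the
#'   boundary of) any polygon of the set.
#' @export
in_polygon_set <- function(lon, lat, polys) {
  if (is.matrix(polys)) polys <- polygon_set(list(polys))
  if (length(polys) == 0L) return(rep(FALSE, length(lon)))
  hit <- rep(FALSE, length(lon))
  for (ring in polys) hit <- hit | point_in_polygon(lon, lat, ring)
  hit
}

#' Construct a polygon set
#'
#' @param rings list of two-column (lon, lat) vertex matrices, one per
#'   simple polygon. Holes are not supported.
#' @return an object of class `polygon_set`.
#' @export
polygon_set <- function(rings) {
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    storage.mode(r) <- "double"
    if (ncol(r) < 2L || nrow(r) < 3L)
      stop("each ring needs >= 3 vertices with (lon, lat) columns")
    r[, 1:2, drop = FALSE]
  })
  structure(rings, class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat("<polygon_set>", length(x), "polygon(s)\n")
  for (i in seq_along(x)) {
    bb <- apply(x[[i]], 2, range)
    cat(sprintf("  [%d] %d vertices, lon %.3f..%.3f, lat %.3f..%.3f\n",
                i, nrow(x[[i]]), bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]))
  }
  invisible(x)
}

#' Read polygons from GeoJSON
#'
#' Reads `Polygon` and `MultiPolygon` geometries (also inside `Feature` /
#' `FeatureCollection` wrappers) in lon-lat vertex order. Only outer rings
#' are used; holes are ignored.
#'
#' @param path path to a GeoJSON file.
#' @return a [polygon_set()].
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  grab_geometry <- function(geom) {
    if (is.null(geom) || is.null(geom$type)) return()
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (geom$type == "Polygon") {
      rings[[length(rings) + 1L]] <<- ring_mat(geom$coordinates[[1]])
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates)
        rings[[length(rings) + 1L]] <<- ring_mat(poly[[1]])
    } else if (geom$type == "GeometryCollection") {
      for (g in geom$geometries) grab_geometry(g)
    }
  }
  walk <- function(node) {
    if (is.null(node$type)) return()
    switch(node$type,
      FeatureCollection = for (f in node$features) walk(f),
      Feature = grab_geometry(node$geometry),
      grab_geometry(node)
    )
  }
  walk(gj)
  if (length(rings) == 0L)
    stop("no Polygon/MultiPolygon geometry found in ", path)
  polygon_set(rings)
}

#' Write a polygon set as GeoJSON
#'
#' @param polys a [polygon_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  if (is.matrix(polys)) polys <- polygon_set(list(polys))
  geoms <- lapply(polys, function(r) {
    if (any(r[1L, ] != r[nrow(r), ])) r <- rbind(r, r[1L, ])
    list(type = "Polygon",
         coordinates = list(lapply(seq_len(nrow(r)),
                                   function(i) c(r[i, 1L], r[i, 2L]))))
  })
  fc <- list(
    type = "FeatureCollection",
    features = lapply(geoms, function(g)
      list(type = "Feature", properties = setNames(list(), character(0)),
           geometry = g))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
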