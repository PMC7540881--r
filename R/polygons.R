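#' Language-territory polygons
#'
#' A territory is a (possibly multi-part) planar polygon in lon/lat degrees.
#' Each part is a closed ring stored as a two-column matrix (lon, lat); the
#' last vertex need not repeat the first. Holes are not supported: parts are
#' treated as a union of filled rings.
#'
#' @param rings A two-column matrix or a list of two-column matrices.
#' @return An object of class `eln_polygon`.
#' @export
eln_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    stopifnot(ncol(r) == 2, nrow(r) >= 3)
    # drop an explicitly repeated closing vertex
    if (all(r[1, ] == r[nrow(r), ]) && nrow(r) > 3) r <- r[-nrow(r), , drop = FALSE]
    unname(r)
  })
  if (length(rings) == 0) stop("polygon has no rings")
  structure(list(rings = rings), class = "eln_polygon")
}

#' Planar polygon area (shoelace, summed over parts)
#'
#' @param poly An [eln_polygon()].
#' @return Area in squared degrees.
#' @export
polygon_area <- function(poly) {
  sum(vapply(poly$rings, function(r) {
    x <- r[, 1]; y <- r[, 2]
    xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
    abs(sum(x * ys - xs * y)) / 2
  }, numeric(1)))
}

# even-odd ray casting for one ring; points exactly on an edge count inside
ring_contains <- function(ring, lon, lat, eps = 1e-12) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xj <- c(x[n], x[-n]); yj <- c(y[n], y[-n])
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (k in seq_len(n)) {
    x1 <- xj[k]; y1 <- yj[k]; x2 <- x[k]; y2 <- y[k]
    # boundary test: point within the segment's bounding box and collinear
    dx <- x2 - x1; dy <- y2 - y1
    cross <- (lon - x1) * dy - (lat - y1) * dx
    within <- lon >= pmin(x1, x2) - eps & lon <= pmax(x1, x2) + eps &
      lat >= pmin(y1, y2) - eps & lat <= pmax(y1, y2) + eps
    on_edge <- on_edge | (abs(cross) <= eps * max(1, abs(dx) + abs(dy)) & within)
    crosses <- ((y1 > lat) != (y2 > lat))
    xi <- x1 + (lat - y1) / (y2 - y1) * dx
    flip <- crosses & lon < xi
    flip[is.na(flip)] <- FALSE
    inside <- xor(inside, flip)
  }
  inside | on_edge
}

#' Point-in-polygon test
#'
#' Even-odd rule over all parts; points on a boundary edge count as inside.
#'
#' @param poly An [eln_polygon()].
#' @param lon,lat Point coordinates.
#' @return Logical vector.
#' @export
polygon_contains <- function(poly, lon, lat) {
  res <- rep(FALSE, length(lon))
  for (r in poly$rings) res <- res | ring_contains(r, lon, lat)
  res
}

#' Read language-group polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features. Feature
#' properties `group_id`, `family` and (optionally) `n_languages` populate
#' the group table; outer rings are kept, holes ignored.
#'
#' @param path GeoJSON file path.
#' @return A list of groups, each `list(group_id, family, n_languages,
#'   polygon)` with `polygon` an [eln_polygon()].
#' @export
read_groups_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    geom <- f$geometry
    coords_to_ring <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = list(coords_to_ring(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(pp) coords_to_ring(pp[[1]])),
      stop("unsupported geometry type: ", geom$type))
    props <- f$properties
    list(group_id = as.character(props$group_id),
         family = if (is.null(props$family)) NA_character_ else props$family,
         n_languages = if (is.null(props$n_languages)) NA_integer_
                       else as.integer(props$n_languages),
         polygon = eln_polygon(rings))
  })
}

#' Write language-group polygons to GeoJSON
#'
#' @param groups List of groups as returned by [read_groups_geojson()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_groups_geojson <- function(groups, path) {
  features <- lapply(groups, function(g) {
    polys <- lapply(g$polygon$rings, function(r) {
      r <- rbind(r, r[1, ])                       # close the ring
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    })
    list(type = "Feature",
         properties = list(group_id = g$group_id, family = g$family,
                           n_languages = g$n_languages),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
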