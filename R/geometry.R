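#' Planar region polygons
#'
#' Regions are simple polygons in a projected coordinate system with
#' kilometre units. A region is a list with a `coords` matrix (two columns,
#' `x` and `y`, one row per vertex, not repeating the first vertex) and an
#' optional `name`. All geometric operations in this package are Euclidean
#' in km; geographic (lon/lat) coordinates must be projected upstream.
#'
#' @param coords numeric matrix or data frame with two columns (x, y km).
#' @param name optional region name.
#' @return An object of class `se_region`.
#' @export
region_polygon <- function(coords, name = "region") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L || nrow(coords) < 3L) {
    stop("`coords` must be a numeric matrix with two columns and >= 3 vertices")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("region vertices must be finite")
  }
  # drop an explicitly closed ring's repeated last vertex
  n <- nrow(coords)
  if (all(coords[1L, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
  if (nrow(coords) < 3L) stop("degenerate region polygon")
  if (abs(polygon_area(coords)) < .Machine$double.eps) {
    stop("degenerate region polygon (zero area)")
  }
  structure(list(coords = coords, name = name), class = "se_region")
}

#' Axis-aligned rectangular region
#'
#' Default extent is 160 km x 850 km, a Malawi-like aspect ratio, with the
#' origin at the south-west corner.
#'
#' @param width_km,height_km rectangle dimensions in km.
#' @return An `se_region`.
#' @export
region_rectangle <- function(width_km = 160, height_km = 850) {
  stopifnot(width_km > 0, height_km > 0)
  region_polygon(rbind(
    c(0, 0), c(width_km, 0), c(width_km, height_km), c(0, height_km)
  ), name = sprintf("rectangle %gx%g km", width_km, height_km))
}

polygon_area <- function(coords) {
  x <- coords[, 1L]; y <- coords[, 2L]
  j <- c(seq_len(nrow(coords))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

region_bbox <- function(region) {
  c(xmin = min(region$coords[, 1L]), xmax = max(region$coords[, 1L]),
    ymin = min(region$coords[, 2L]), ymax = max(region$coords[, 2L]))
}

#' Test whether points fall inside a region polygon
#'
#' Even-odd (ray casting) rule; points exactly on an edge follow the
#' crossing convention and should not be relied upon.
#'
#' @param x,y numeric vectors of coordinates (km).
#' @param region an `se_region`.
#' @return Logical vector.
#' @export
point_in_region <- function(x, y, region) {
  stopifnot(inherits(region, "se_region"), length(x) == length(y))
  px <- region$coords[, 1L]; py <- region$coords[, 2L]
  nv <- length(px)
  jx <- px[c(nv, seq_len(nv - 1L))]; jy <- py[c(nv, seq_len(nv - 1L))]
  inside <- logical(length(x))
  for (k in seq_len(nv)) {
    crosses <- ((py[k] > y) != (jy[k] > y)) &
      (x < (jx[k] - px[k]) * (y - py[k]) / (jy[k] - py[k]) + px[k])
    inside <- xor(inside, crosses)
  }
  inside
}

# minimum distance from points (x, y) to the segment (ax,ay)-(bx,by)
dist_point_segment <- function(x, y, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((x - ax)^2 + (y - ay)^2))
  t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
  sqrt((x - ax - t * dx)^2 + (y - ay - t * dy)^2)
}

#' Geographic features for proximity covariates
#'
#' A feature is a polygon (e.g. a mapped vertisol unit) or a polyline
#' (e.g. a lake shore or river course) in the same planar km system as the
#' survey coordinates.
#'
#' @param coords two-column coordinate matrix (km).
#' @param type `"polygon"` or `"line"`.
#' @return An object of class `se_feature`.
#' @export
feature <- function(coords, type = c("polygon", "line")) {
  type <- match.arg(type)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L) {
    stop("feature coords must be a two-column numeric matrix")
  }
  min_rows <- if (type == "polygon") 3L else 2L
  if (nrow(coords) < min_rows) stop("too few vertices for feature type")
  structure(list(coords = coords, type = type), class = "se_feature")
}

# distance from each point to one feature: 0 inside a polygon, else minimum
# distance to the boundary segments (polyline features are open chains)
dist_to_feature <- function(x, y, feat) {
  stopifnot(inherits(feat, "se_feature"))
  cc <- feat$coords
  n <- nrow(cc)
  segs <- if (feat$type == "polygon") {
    cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  } else {
    cbind(seq_len(n - 1L), seq_len(n)[-1L])
  }
  d <- rep(Inf, length(x))
  for (s in seq_len(nrow(segs))) {
    a <- cc[segs[s, 1L], ]; b <- cc[segs[s, 2L], ]
    d <- pmin(d, dist_point_segment(x, y, a[1L], a[2L], b[1L], b[2L]))
  }
  if (feat$type == "polygon") {
    reg <- region_polygon(cc)
    d[point_in_region(x, y, reg)] <- 0
  }
  d
}

#' Minimum distance from points to a set of features
#'
#' @param x,y point coordinates (km).
#' @param features a single `se_feature` or a list of them.
#' @return Numeric vector of minimum Euclidean distances in km.
#' @export
dist_to_features <- function(x, y, features) {
  if (inherits(features, "se_feature")) features <- list(features)
  if (length(features) == 0L) stop("no features supplied")
  d <- rep(Inf, length(x))
  for (f in features) d <- pmin(d, dist_to_feature(x, y, f))
  d
}

#' Read and write region polygons as GeoJSON
#'
#' Supports a single `Polygon` geometry (optionally wrapped in a `Feature`
#' or a one-feature `FeatureCollection`). Coordinates are taken verbatim
#' (planar km); only the exterior ring is used.
#'
#' @param path file path.
#' @param region an `se_region` (for writing).
#' @return `read_region_geojson()` returns an `se_region`.
#' @export
read_region_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- g
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) < 1L) stop("empty FeatureCollection in ", path)
    geom <- if (is.data.frame(g$features)) {
      list(type = g$features$geometry$type[1L],
           coordinates = g$features$geometry$coordinates[[1L]])
    } else g$features[[1L]]$geometry
  } else if (identical(g$type, "Feature")) {
    geom <- g$geometry
  }
  if (!identical(geom$type, "Polygon")) {
    stop("expected a Polygon geometry in ", path)
  }
  ring <- geom$coordinates
  if (is.list(ring)) ring <- ring[[1L]]
  if (length(dim(ring)) == 3L) ring <- ring[1L, , ]  # jsonlite array form
  region_polygon(ring, name = basename(path))
}

#' @rdname read_region_geojson
#' @export
write_region_geojson <- function(region, path) {
  stopifnot(inherits(region, "se_region"))
  ring <- rbind(region$coords, region$coords[1L, ])
  obj <- list(
    type = "Feature",
    properties = list(name = region$name, units = "km"),
    geometry = list(type = "Polygon",
                    coordinates = list(apply(ring, 1L, as.numeric,
                                             simplify = FALSE)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
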