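#' Lightweight polygon collections
#'
#' All geometry in karstflora is carried by `karst_polygons` objects: a list
#' of outer rings in WGS84 decimal degrees. Each ring is a `list(x, y)` pair
#' of equal-length numeric vectors (longitude, latitude), open (the first
#' vertex is not repeated). Holes are not supported; multipolygon features
#' are flattened to their outer rings.
#'
#' @param rings A list of rings. Each ring may be a `list(x, y)`, a two-column
#'   matrix, or a data frame with columns interpretable as (lon, lat).
#' @return An object of class `karst_polygons`.
#' @export
karst_polygons <- function(rings = list()) {
  rings <- lapply(rings, as_ring)
  structure(rings, class = "karst_polygons")
}

as_ring <- function(r) {
  if (is.list(r) && !is.null(r$x) && !is.null(r$y)) {
    x <- as.numeric(r$x); y <- as.numeric(r$y)
  } else {
    m <- as.matrix(r)
    if (ncol(m) != 2) stop_config("polygon rings need two columns (lon, lat)")
    x <- as.numeric(m[, 1]); y <- as.numeric(m[, 2])
  }
  if (length(x) != length(y)) stop_config("ring x and y lengths differ")
  # drop a closing vertex if present
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1
  }
  if (n < 3) stop_config("polygon ring has fewer than 3 distinct vertices")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_config("polygon ring contains non-finite coordinates")
  list(x = x, y = y)
}

#' @export
print.karst_polygons <- function(x, ...) {
  cat("<karst_polygons> ", length(x), " ring(s)\n", sep = "")
  invisible(x)
}

#' @export
length.karst_polygons <- function(x) length(unclass(x))

#' Axis-aligned rectangle ring
#'
#' @param x0,y0,x1,y1 Rectangle bounds (lon/lat degrees), `x0 < x1`,
#'   `y0 < y1`.
#' @return A single ring usable inside [karst_polygons()].
#' @export
rect_ring <- function(x0, y0, x1, y1) {
  list(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

#' Read polygons from GeoJSON
#'
#' Accepts a FeatureCollection, a bare (Multi)Polygon geometry, or a
#' GeometryCollection. Only outer rings are retained.
#'
#' @param path Path to a GeoJSON file.
#' @return A [karst_polygons()] collection.
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop_config(paste0("polygon file not found: ", path))
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rings <- list()
  add_geom <- function(geom) {
    if (is.null(geom$type)) stop_config("GeoJSON geometry without type")
    if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1]]
      rings[[length(rings) + 1]] <<- list(
        x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
        y = vapply(ring, function(p) as.numeric(p[[2]]), 0)
      )
    } else if (geom$type == "MultiPolygon") {
      for (poly in geom$coordinates) {
        ring <- poly[[1]]
        rings[[length(rings) + 1]] <<- list(
          x = vapply(ring, function(p) as.numeric(p[[1]]), 0),
          y = vapply(ring, function(p) as.numeric(p[[2]]), 0)
        )
      }
    } else if (geom$type == "GeometryCollection") {
      for (sub in geom$geometries) add_geom(sub)
    } else {
      stop_config(paste0("unsupported GeoJSON geometry type: ", geom$type))
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) add_geom(f$geometry)
  } else if (identical(g$type, "Feature")) {
    add_geom(g$geometry)
  } else {
    add_geom(g)
  }
  karst_polygons(rings)
}

#' Write polygons to GeoJSON
#'
#' Writes a FeatureCollection with one Polygon feature per ring. Output is
#' deterministic (fixed key order, 12 significant digits), so identical
#' collections produce byte-identical files.
#'
#' @param polys A [karst_polygons()] collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polys, path) {
  feat <- function(ring) {
    xs <- signif(ring$x, 12); ys <- signif(ring$y, 12)
    coords <- paste0(
      "[", paste0("[", fmt_num(c(xs, xs[1])), ",", fmt_num(c(ys, ys[1])), "]",
                  collapse = ","), "]"
    )
    paste0('{"type":"Feature","properties":{},"geometry":',
           '{"type":"Polygon","coordinates":[', coords, ']}}')
  }
  txt <- paste0('{"type":"FeatureCollection","features":[',
                paste(vapply(polys, feat, ""), collapse = ","), "]}")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x) {
  # deterministic, locale-independent number formatting
  sub("\\.?0+$", "", formatC(x, format = "f", digits = 10, drop0trailing = FALSE))
}

#' Point-in-polygon membership
#'
#' Tests each point against every ring; a point on a ring edge or vertex
#' counts as inside (boundary-inclusive convention, used for both biome
#' clipping and landmass checks).
#'
#' @param lon,lat Numeric vectors of coordinates (degrees). `NA` coordinates
#'   yield `FALSE`.
#' @param polys A [karst_polygons()] collection.
#' @return Logical vector, one element per point.
#' @export
points_in_polygons <- function(lon, lat, polys) {
  stopifnot(length(lon) == length(lat))
  inside <- logical(length(lon))
  ok <- is.finite(lon) & is.finite(lat)
  if (!any(ok) || length(polys) == 0) return(inside)
  for (ring in polys) {
    code <- sp::point.in.polygon(lon[ok], lat[ok], ring$x, ring$y)
    inside[ok] <- inside[ok] | code > 0
  }
  inside
}

# Signed shoelace area of one ring (in the units of its coordinates^2).
ring_area <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# Total area of a set of (possibly signed) rings, e.g. polyclip output where
# holes come back with opposite orientation.
rings_area <- function(rings) {
  if (length(rings) == 0) return(0)
  abs(sum(vapply(rings, ring_area, 0)))
}

# Area of intersection between a rectangle and the union of the collection's
# rings, in degree^2. Uses polyclip (Vatti) after self-union to avoid double
# counting overlapping rings.
rect_intersection_area <- function(x0, y0, x1, y1, polys) {
  if (length(polys) == 0) return(0)
  rings <- unclass(polys)
  merged <- if (length(rings) > 1) polyclip::polyclip(rings, rings, "union") else rings
  rect <- list(rect_ring(x0, y0, x1, y1))
  out <- polyclip::polyclip(rect, merged, "intersection",
                            x0 = x0, y0 = y0, eps = 1e-7)
  rings_area(out)
}

# internal condition helpers shared across modules ---------------------------

stop_config <- function(message) {
  rlang::abort(message, class = "karstflora_config_error")
}

stop_data <- function(message) {
  rlang::abort(message, class = "karstflora_data_error")
}
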