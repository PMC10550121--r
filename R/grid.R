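#' Grid specification
#'
#' A global longitude/latitude grid anchored at (-180, -90) with half-open
#' cells `[lower, upper)` on both axes, so every coordinate falls in exactly
#' one cell. Cell indices are `col = floor((lon - lon0)/size)`,
#' `row = floor((lat - lat0)/size)`.
#'
#' @param cell_size Cell edge in degrees (> 0); 0.5 for the analysis grid,
#'   0.08 for collection-level deduplication.
#' @param origin Grid origin `c(lon0, lat0)`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(cell_size = 0.5, origin = c(-180, -90)) {
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop_config("cell_size must be a positive number")
  structure(list(cell_size = cell_size, origin = origin), class = "grid_spec")
}

#' Map coordinates to grid cells
#'
#' @param lon,lat Numeric vectors of WGS84 coordinates. Values must be
#'   finite and within \[-180, 180\] x \[-90, 90\]; anything else errors (run
#'   the coordinate-validity filters first).
#' @param grid A [grid_spec()].
#' @return A tibble with integer columns `col`, `row` and a string key
#'   `cell` (`"col_row"`).
#' @export
cell_of <- function(lon, lat, grid = grid_spec()) {
  stopifnot(length(lon) == length(lat))
  bad <- !is.finite(lon) | !is.finite(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad))
    stop_data(paste0("coordinates outside the valid domain at position ",
                     which(bad)[1]))
  col <- as.integer(floor((lon - grid$origin[1]) / grid$cell_size))
  row <- as.integer(floor((lat - grid$origin[2]) / grid$cell_size))
  tibble::tibble(col = col, row = row, cell = paste(col, row, sep = "_"))
}

#' Rectangle bounds of grid cells
#'
#' @param col,row Integer cell indices.
#' @param grid A [grid_spec()].
#' @return A tibble with `x0`, `y0`, `x1`, `y1` (degrees).
#' @export
cell_bounds <- function(col, row, grid = grid_spec()) {
  s <- grid$cell_size
  tibble::tibble(
    x0 = grid$origin[1] + col * s, y0 = grid$origin[2] + row * s,
    x1 = grid$origin[1] + (col + 1) * s, y1 = grid$origin[2] + (row + 1) * s
  )
}

#' Classify grid cells against biome polygons
#'
#' A cell entirely covered by the polygon union is `KARST`, a cell with zero
#' intersection is `NON_KARST`, anything in between is `MIXED`. Coverage is
#' decided geometrically on the cell rectangle in degree space (not by
#' centroid sampling), because the affinity rule needs to know about partial
#' overlap.
#'
#' @param polys Biome polygons ([karst_polygons()]).
#' @param grid A [grid_spec()].
#' @param cells Tibble with `col`, `row` (e.g. from [cell_of()]); duplicates
#'   are collapsed.
#' @param tol Relative area tolerance distinguishing full/zero coverage from
#'   clipping noise.
#' @return A biome mask: tibble `col`, `row`, `cell`, `class` with `class`
#'   one of `"KARST"`, `"NON_KARST"`, `"MIXED"`.
#' @export
classify_cells <- function(polys, grid, cells, tol = 1e-6) {
  cells <- dplyr::distinct(tibble::as_tibble(cells[c("col", "row")]))
  b <- cell_bounds(cells$col, cells$row, grid)
  cell_area <- grid$cell_size^2
  cls <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- rect_intersection_area(b$x0[i], b$y0[i], b$x1[i], b$y1[i], polys)
    cls[i] <- if (a >= cell_area * (1 - tol)) "KARST"
      else if (a <= cell_area * tol) "NON_KARST"
      else "MIXED"
  }
  tibble::tibble(col = cells$col, row = cells$row,
                 cell = paste(cells$col, cells$row, sep = "_"), class = cls)
}

#' Clip records to a polygon collection
#'
#' Boundary-inclusive point-in-polygon subset; records with missing
#' coordinates are dropped (they cannot be located).
#'
#' @param records Occurrence tibble.
#' @param polys [karst_polygons()].
#' @return The subset of `records` inside `polys`.
#' @export
clip_records <- function(records, polys) {
  records[points_in_polygons(records$longitude, records$latitude, polys), ,
          drop = FALSE]
}
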