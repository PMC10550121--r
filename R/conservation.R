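#' IUCN criterion-B threshold configuration
#'
#' Numeric thresholds of the Red List categories under criterion B:
#' B1 bounds on extent of occurrence (EOO) and B2 bounds on area of
#' occupancy (AOO), both in km^2, plus the AOO grid cell edge (2 km by
#' convention).
#'
#' @param eoo_cr,eoo_en,eoo_vu EOO upper bounds (exclusive) for CR/EN/VU.
#' @param aoo_cr,aoo_en,aoo_vu AOO upper bounds (exclusive) for CR/EN/VU.
#' @param aoo_cell_km AOO grid cell edge in km.
#' @return A named list.
#' @export
threshold_config <- function(eoo_cr = 100, eoo_en = 5000, eoo_vu = 20000,
                             aoo_cr = 10, aoo_en = 500, aoo_vu = 2000,
                             aoo_cell_km = 2) {
  if (!(eoo_cr < eoo_en && eoo_en < eoo_vu))
    stop_config("EOO thresholds must increase CR < EN < VU")
  if (!(aoo_cr < aoo_en && aoo_en < aoo_vu))
    stop_config("AOO thresholds must increase CR < EN < VU")
  list(eoo = c(CR = eoo_cr, EN = eoo_en, VU = eoo_vu),
       aoo = c(CR = aoo_cr, EN = aoo_en, VU = aoo_vu),
       aoo_cell_km = aoo_cell_km)
}

# Cylindrical equal-area projection (km) with standard parallel lat0 and
# central meridian lon0. Equal-area by construction:
#   x = R cos(lat0) * (lon - lon0),  y = R sin(lat) / cos(lat0).
project_cea <- function(lon, lat, lon0 = 0, lat0 = 0) {
  R <- 6371
  c0 <- cos(lat0 * pi / 180)
  list(x = R * c0 * (lon - lon0) * pi / 180,
       y = R * sin(lat * pi / 180) / c0)
}

#' Extent of occurrence (EOO)
#'
#' Area (km^2) of the convex hull of a species' unique records, computed on
#' a cylindrical equal-area projection centred on the point cloud (the
#' projection identity is attached as attribute `projection`). Fewer than 3
#' unique points, or a degenerate (collinear) hull, give 0; reconcile
#' against AOO afterwards ([reconcile_eoo()]).
#'
#' @param points Tibble/data frame with `longitude`, `latitude`.
#' @return EOO in km^2 with attribute `projection`.
#' @export
eoo <- function(points) {
  pts <- unique(data.frame(longitude = points$longitude,
                           latitude = points$latitude))
  pts <- pts[is.finite(pts$longitude) & is.finite(pts$latitude), ]
  if (nrow(pts) == 0) stop_data("EOO needs at least one valid point")
  lon0 <- mean(pts$longitude)
  lat0 <- mean(pts$latitude)
  proj_id <- sprintf("cea +lon_0=%.6f +lat_ts=%.6f +R=6371km", lon0, lat0)
  if (nrow(pts) < 3)
    return(structure(0, projection = proj_id))
  p <- project_cea(pts$longitude, pts$latitude, lon0, lat0)
  h <- grDevices::chull(p$x, p$y)
  area <- abs(ring_area(list(x = p$x[h], y = p$y[h])))
  if (area < 1e-9) area <- 0
  structure(area, projection = proj_id)
}

#' Area of occupancy (AOO)
#'
#' Number of occupied cells on a fixed equal-area grid (default 2 x 2 km,
#' anchored at the projection origin) times the cell area. Occupancy is by
#' point containment in half-open cells, so AOO is invariant to how many
#' records share a cell and never decreases when points are added. The
#' optional `shift_km` moves the grid origin for sensitivity diagnostics;
#' the default is the fixed anchor (no origin optimisation).
#'
#' @param points Tibble/data frame with `longitude`, `latitude`.
#' @param cell_edge_km AOO cell edge in km.
#' @param shift_km Length-2 numeric, grid origin shift (km) in x and y.
#' @return AOO in km^2.
#' @export
aoo <- function(points, cell_edge_km = 2, shift_km = c(0, 0)) {
  ok <- is.finite(points$longitude) & is.finite(points$latitude)
  if (!any(ok)) return(0)
  p <- project_cea(points$longitude[ok], points$latitude[ok])
  cx <- floor((p$x - shift_km[1]) / cell_edge_km)
  cy <- floor((p$y - shift_km[2]) / cell_edge_km)
  n_cells <- nrow(unique(cbind(cx, cy)))
  n_cells * cell_edge_km^2
}

#' Reconcile EOO against AOO
#'
#' By convention the extent of occurrence may not be smaller than the area
#' of occupancy; degenerate hulls (EOO 0) inherit the AOO.
#'
#' @param eoo,aoo Numeric vectors, km^2.
#' @return `pmax(eoo, aoo)`.
#' @export
reconcile_eoo <- function(eoo, aoo) pmax(eoo, aoo)

#' Assign a preliminary criterion-B category
#'
#' B1 grades the (reconciled) EOO and B2 the AOO against their thresholds;
#' the final category is the more severe of the two, and `basis` records
#' which subcriterion drove it (`"B1"`, `"B2"` or `"B1+B2"`; `NA` for LC).
#' This is a *preliminary* assessment: the criterion-B subconditions
#' (fragmentation, number of locations, continuing decline) are assumed to
#' hold, as preliminary-assessment tools do. NT is never assigned; the
#' bottom category is LC.
#'
#' @param eoo,aoo Numeric vectors (km^2), already reconciled.
#' @param thresholds See [threshold_config()].
#' @return Tibble with `category` (factor LC < VU < EN < CR) and `basis`.
#' @export
assign_category <- function(eoo, aoo, thresholds = threshold_config()) {
  if (any(eoo < 0) || any(aoo < 0)) stop_data("negative EOO/AOO")
  grade <- function(x, th) ifelse(x < th["CR"], 4L,
                           ifelse(x < th["EN"], 3L,
                           ifelse(x < th["VU"], 2L, 1L)))
  lv <- c("LC", "VU", "EN", "CR")
  b1 <- grade(eoo, thresholds$eoo)
  b2 <- grade(aoo, thresholds$aoo)
  final <- pmax(b1, b2)
  basis <- ifelse(final == 1L, NA_character_,
           ifelse(b1 == final & b2 == final, "B1+B2",
           ifelse(b1 == final, "B1", "B2")))
  tibble::tibble(category = factor(lv[final], levels = lv, ordered = TRUE),
                 basis = basis)
}

#' Assess all species
#'
#' One preliminary criterion-B assessment per species: EOO from the convex
#' hull, AOO from the fixed 2-km grid, EOO reconciled to be >= AOO, category
#' and basis from the thresholds.
#'
#' @param records Cleaned full-range records with `accepted_name`,
#'   `longitude`, `latitude`.
#' @param thresholds See [threshold_config()].
#' @return Tibble with one row per species: `accepted_name`, `n_records`,
#'   `n_unique_points`, `eoo_km2` (reconciled), `aoo_km2`, `category`,
#'   `basis`. Summarise with [category_summary()].
#' @export
assess_all <- function(records, thresholds = threshold_config()) {
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  rec <- records[ok, , drop = FALSE]
  if (nrow(rec) == 0) stop_data("no assessable records")
  split_idx <- split(seq_len(nrow(rec)), rec$accepted_name)
  rows <- lapply(names(split_idx), function(sp) {
    i <- split_idx[[sp]]
    pts <- rec[i, c("longitude", "latitude")]
    e <- as.numeric(eoo(pts))
    a <- aoo(pts, cell_edge_km = thresholds$aoo_cell_km)
    tibble::tibble(accepted_name = sp, n_records = length(i),
                   n_unique_points = nrow(unique(pts)),
                   eoo_km2 = reconcile_eoo(e, a), aoo_km2 = a)
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(out, assign_category(out$eoo_km2, out$aoo_km2,
                                               thresholds))
  out
}

#' Category histogram
#'
#' @param assessments Tibble from [assess_all()].
#' @return Named integer vector of species counts per category (LC..CR).
#' @export
category_summary <- function(assessments) {
  tab <- table(factor(assessments$category, levels = c("LC", "VU", "EN", "CR")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Join a legal-protection table
#'
#' Left join of a statutory protection list (e.g. a national norm's
#' categories) onto the assessments by accepted name; species absent from
#' the table get `NA`.
#'
#' @param assessments Tibble from [assess_all()].
#' @param legal_table Tibble with `accepted_name` (or `name`) and
#'   `legal_status` (or `category`).
#' @return `assessments` with a `legal_status` column.
#' @export
join_legal_status <- function(assessments, legal_table) {
  nm <- if ("accepted_name" %in% names(legal_table)) "accepted_name" else "name"
  st <- if ("legal_status" %in% names(legal_table)) "legal_status" else "category"
  assessments$legal_status <-
    legal_table[[st]][match(assessments$accepted_name, legal_table[[nm]])]
  assessments
}
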