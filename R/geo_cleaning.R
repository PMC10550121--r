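#' Coordinate-validity flags
#'
#' Each `flag_*` function returns a logical vector over the input records
#' (`TRUE` = flagged as suspect). They implement the standard battery of
#' geographic filters applied to occurrence datasets before analysis:
#' non-numeric/out-of-range coordinates, zero coordinates, points off the
#' reference landmass, points near country/province centroids, capitals and
#' biodiversity institutions, points inside urban areas, and exact
#' (name, lat, lon) duplicates. Records with missing coordinates are only
#' flagged by [flag_invalid_coords()]; the geometric filters ignore them.
#'
#' @param records Occurrence tibble with `latitude`, `longitude` (and
#'   `accepted_name` for the duplicate filter).
#' @return Logical vector of flags.
#' @name geo_flags
NULL

#' @rdname geo_flags
#' @export
flag_invalid_coords <- function(records) {
  !is.finite(records$latitude) | !is.finite(records$longitude) |
    records$latitude < -90 | records$latitude > 90 |
    records$longitude < -180 | records$longitude > 180
}

#' @rdname geo_flags
#' @param tolerance Absolute degrees within which an ordinate counts as zero.
#' @export
flag_zero_coords <- function(records, tolerance = 1e-9) {
  out <- abs(records$latitude) <= tolerance | abs(records$longitude) <= tolerance
  out & !is.na(out)
}

#' @rdname geo_flags
#' @param landmass Landmass polygons ([karst_polygons()]); boundary points
#'   count as on land.
#' @export
flag_outside_landmass <- function(records, landmass) {
  if (length(landmass) == 0) stop_config("landmass polygon set is empty")
  ok <- is.finite(records$latitude) & is.finite(records$longitude)
  out <- !points_in_polygons(records$longitude, records$latitude, landmass)
  out & ok
}

#' @rdname geo_flags
#' @param points Tibble of gazetteer points with `longitude`, `latitude`
#'   (centroids, capitals or institutions).
#' @param radius_km Flagging radius; records at great-circle distance
#'   `<= radius_km` of any point are flagged (haversine, sphere radius
#'   6371 km).
#' @export
flag_near_points <- function(records, points, radius_km) {
  if (!is.numeric(radius_km) || radius_km <= 0)
    stop_config("radius_km must be > 0")
  n <- nrow(records)
  if (is.null(points) || nrow(points) == 0) return(logical(n))
  ok <- is.finite(records$latitude) & is.finite(records$longitude)
  out <- logical(n)
  if (!any(ok)) return(out)
  d <- geosphere::distm(
    cbind(records$longitude[ok], records$latitude[ok]),
    cbind(points$longitude, points$latitude),
    fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)
  )
  out[ok] <- apply(d, 1, min) <= radius_km * 1000
  out
}

#' @rdname geo_flags
#' @param polygons Urban-area polygons; points inside (boundary inclusive)
#'   are flagged. An empty set flags nothing.
#' @export
flag_in_polygons <- function(records, polygons) {
  if (is.null(polygons) || length(polygons) == 0)
    return(logical(nrow(records)))
  ok <- is.finite(records$latitude) & is.finite(records$longitude)
  points_in_polygons(records$longitude, records$latitude, polygons) & ok
}

#' @rdname geo_flags
#' @export
flag_geo_duplicates <- function(records) {
  key <- paste(records$accepted_name, format(records$latitude, digits = 15),
               format(records$longitude, digits = 15), sep = "|")
  duplicated(key) & !is.na(records$accepted_name)
}

#' Cleaning configuration
#'
#' Radii follow the defaults of the reference coordinate-cleaning tools:
#' 1 km around country/province centroids, 10 km around capitals, 0.1 km
#' around biodiversity institutions.
#'
#' @param centroid_km,capital_km,institution_km Proximity radii in km.
#' @param zero_tolerance Degrees within which an ordinate counts as zero.
#' @return A named list.
#' @export
cleaning_config <- function(centroid_km = 1, capital_km = 10,
                            institution_km = 0.1, zero_tolerance = 1e-9) {
  list(centroid_km = centroid_km, capital_km = capital_km,
       institution_km = institution_km, zero_tolerance = zero_tolerance)
}

#' Run the geographic cleaning pipeline
#'
#' Applies the eight validity filters in the conventional order — (a)
#' non-numeric coordinates, (b) zero coordinates, (c) off-landmass, (d)
#' centroid vicinity, (e) capital vicinity, (f) urban areas, (g) institution
#' vicinity, (h) exact duplicates — each on the survivors of the previous
#' step. The survivor set is order-independent; only the attribution of a
#' record to a step depends on the order.
#'
#' @param records Name-resolved occurrence tibble.
#' @param gazetteer List with elements `centroids`, `capitals`,
#'   `institutions` (point tibbles with `longitude`, `latitude`), `urban`
#'   ([karst_polygons()]) and `landmass` ([karst_polygons()]). Missing
#'   elements disable the corresponding filter (landmass excepted: omitting
#'   it skips the landmass step).
#' @param config See [cleaning_config()].
#' @return List with `records` (survivors), `report` (per-step audit,
#'   [cleaning_report()]) and `flagged` (tibble `record_id`, `step`).
#' @export
clean_pipeline <- function(records, gazetteer = list(),
                           config = cleaning_config()) {
  rep <- cleaning_report(nrow(records))
  flagged <- tibble::tibble(record_id = character(), step = character())
  cur <- records

  run_step <- function(label, flags) {
    flags[is.na(flags)] <- FALSE
    rep <<- add_step(rep, label, nrow(cur), sum(flags))
    if (any(flags))
      flagged <<- dplyr::bind_rows(flagged, tibble::tibble(
        record_id = cur$record_id[flags], step = label))
    cur <<- cur[!flags, , drop = FALSE]
  }

  run_step("invalid_coords", flag_invalid_coords(cur))
  run_step("zero_coord", flag_zero_coords(cur, config$zero_tolerance))
  if (!is.null(gazetteer$landmass))
    run_step("off_landmass", flag_outside_landmass(cur, gazetteer$landmass))
  if (!is.null(gazetteer$centroids))
    run_step("centroid", flag_near_points(cur, gazetteer$centroids,
                                          config$centroid_km))
  if (!is.null(gazetteer$capitals))
    run_step("capital", flag_near_points(cur, gazetteer$capitals,
                                         config$capital_km))
  if (!is.null(gazetteer$urban))
    run_step("urban", flag_in_polygons(cur, gazetteer$urban))
  if (!is.null(gazetteer$institutions))
    run_step("institution", flag_near_points(cur, gazetteer$institutions,
                                             config$institution_km))
  run_step("duplicate", flag_geo_duplicates(cur))

  list(records = cur, report = rep, flagged = flagged)
}

#' Collection-level deduplication
#'
#' Collapses duplicate collection events: among records sharing the same
#' grid cell (default 0.08 degrees), year, month, day and accepted name,
#' only the first in stable input order is retained. Missing date fields
#' compare equal to missing (a conservative choice: two undated records of
#' one species in one cell are treated as the same collection).
#'
#' @param records Cleaned occurrence tibble with valid coordinates.
#' @param cell_size Deduplication cell edge in degrees.
#' @return The deduplicated records, in input order.
#' @export
dedup_collections <- function(records, cell_size = 0.08) {
  if (nrow(records) == 0) return(records)
  cells <- cell_of(records$longitude, records$latitude,
                   grid_spec(cell_size = cell_size))
  key <- paste(cells$cell, records$year, records$month, records$day,
               records$accepted_name, sep = "|")
  records[!duplicated(key), , drop = FALSE]
}

#' Read a gazetteer point table
#'
#' @param path Delimited text with columns `name`, `longitude`, `latitude`.
#' @param delim Field delimiter.
#' @return A tibble of points.
#' @export
read_gazetteer_points <- function(path, delim = ",") {
  if (!file.exists(path)) stop_config(paste0("gazetteer file not found: ", path))
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    name = readr::col_character(), longitude = readr::col_double(),
    latitude = readr::col_double()
  ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
  tibble::as_tibble(tab)
}
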