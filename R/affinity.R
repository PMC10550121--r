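#' Build per-species occupied-cell profiles
#'
#' Counts, for each species, the distinct analysis-grid cells it occupies in
#' each biome class over its *entire* range (pass the full cleaned dataset,
#' not the biome-clipped subset). Sampling effort is homogenised to one
#' record per cell per category, and a `MIXED` cell (partly karst, partly
#' not) contributes one occupied cell to *both* categories.
#'
#' @param records Cleaned, name-resolved occurrence tibble.
#' @param mask Biome mask from [classify_cells()]. Cells occupied by records
#'   but absent from the mask are treated as `NON_KARST` (the mask is
#'   usually built only over karst-adjacent cells).
#' @param grid Analysis grid, default 0.5 degrees.
#' @return A tibble with `accepted_name`, `karst_cells`, `nonkarst_cells`
#'   and `karst_fraction` = karst / (karst + nonkarst). Species with zero
#'   locatable records are omitted with a warning.
#' @export
build_profiles <- function(records, mask, grid = grid_spec(0.5)) {
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  dropped <- setdiff(unique(records$accepted_name),
                     unique(records$accepted_name[ok]))
  dropped <- dropped[!is.na(dropped)]
  if (length(dropped) > 0)
    warning(length(dropped), " species omitted: no valid records")
  rec <- records[ok, , drop = FALSE]
  cells <- cell_of(rec$longitude, rec$latitude, grid)
  occ <- dplyr::distinct(tibble::tibble(
    accepted_name = rec$accepted_name, cell = cells$cell))
  cls <- mask$class[match(occ$cell, mask$cell)]
  cls[is.na(cls)] <- "NON_KARST"
  occ$karst <- as.integer(cls %in% c("KARST", "MIXED"))
  occ$nonkarst <- as.integer(cls %in% c("NON_KARST", "MIXED"))
  prof <- dplyr::summarise(dplyr::group_by(occ, .data$accepted_name),
                           karst_cells = sum(.data$karst),
                           nonkarst_cells = sum(.data$nonkarst),
                           .groups = "drop")
  prof$karst_fraction <- prof$karst_cells /
    (prof$karst_cells + prof$nonkarst_cells)
  prof
}

#' Classify species affinity to the karst biome
#'
#' Three exhaustive, mutually exclusive classes from occupied-cell counts:
#' `KARST_ENDEMIC` when every occupied cell is karstic
#' (`nonkarst_cells == 0`); `KARST_ASSOCIATED` when strictly more than half
#' of the occupied cells are karstic; `NON_KARST` otherwise. An exact half
#' split is assigned to `NON_KARST` by default — "more than half inside" and
#' "more than half outside" both fail at a tie, and the conservative reading
#' does not claim karst affinity; set `tie = "KARST_ASSOCIATED"` for the
#' opposite convention.
#'
#' @param profiles Tibble from [build_profiles()] (or any tibble with
#'   `karst_cells`, `nonkarst_cells`).
#' @param tie Class assigned when exactly half the occupied cells are
#'   karstic.
#' @return `profiles` with a `class` factor added (levels `KARST_ENDEMIC`,
#'   `KARST_ASSOCIATED`, `NON_KARST`).
#' @export
classify_affinity <- function(profiles,
                              tie = c("NON_KARST", "KARST_ASSOCIATED")) {
  tie <- match.arg(tie)
  k <- profiles$karst_cells
  n <- profiles$nonkarst_cells
  total <- k + n
  if (any(total < 1)) stop_data("species with zero occupied cells")
  frac <- k / total
  cls <- ifelse(n == 0, "KARST_ENDEMIC",
         ifelse(frac > 0.5, "KARST_ASSOCIATED",
         ifelse(frac == 0.5, tie, "NON_KARST")))
  profiles$class <- factor(cls, levels = affinity_levels())
  profiles
}

affinity_levels <- function() c("KARST_ENDEMIC", "KARST_ASSOCIATED", "NON_KARST")

#' Record-based endemism
#'
#' The record-based definition used for endemism mapping: a species is
#' endemic to the biome when *all* of its georeferenced records fall inside
#' the biome polygons (boundary inclusive). This is distinct from the
#' cell-based `KARST_ENDEMIC` class of [classify_affinity()]; choose the
#' definition explicitly, never infer it.
#'
#' @param records Full-range cleaned records.
#' @param polys Biome polygons.
#' @return Character vector of endemic species names.
#' @export
endemic_by_records <- function(records, polys) {
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  rec <- records[ok, , drop = FALSE]
  inside <- points_in_polygons(rec$longitude, rec$latitude, polys)
  tab <- dplyr::summarise(dplyr::group_by(
    tibble::tibble(accepted_name = rec$accepted_name, inside = inside),
    .data$accepted_name), all_in = all(.data$inside), .groups = "drop")
  sort(tab$accepted_name[tab$all_in])
}

#' Tabulate affinity classes
#'
#' @param classes Factor or character vector of affinity classes (e.g.
#'   column `class` of [classify_affinity()] output).
#' @return Named integer vector over the three classes (sums to the number
#'   of species).
#' @export
affinity_histogram <- function(classes) {
  tab <- table(factor(classes, levels = affinity_levels()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-species share of records inside the biome
#'
#' Secondary, record-proportion view of karst affinity (the cell-based
#' classifier is canonical): the fraction of each species' records falling
#' inside the biome polygons, with a banding at 50% and 90%.
#'
#' @param records Full-range cleaned records.
#' @param polys Biome polygons.
#' @return Tibble with `accepted_name`, `n_records`, `fraction_inside` and
#'   `band` (`"exclusive"` = 100%, `"mostly_karst"` = (50%, 100%),
#'   `"mostly_outside"` = <= 50%).
#' @export
record_proportion_summary <- function(records, polys) {
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  rec <- records[ok, , drop = FALSE]
  inside <- points_in_polygons(rec$longitude, rec$latitude, polys)
  out <- dplyr::summarise(dplyr::group_by(
    tibble::tibble(accepted_name = rec$accepted_name, inside = inside),
    .data$accepted_name),
    n_records = dplyr::n(),
    fraction_inside = mean(.data$inside), .groups = "drop")
  out$band <- ifelse(out$fraction_inside == 1, "exclusive",
              ifelse(out$fraction_inside > 0.5, "mostly_karst",
                     "mostly_outside"))
  out
}
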