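#' Per-cell species richness and sampling effort
#'
#' @param records Cleaned (and, for a biome map, clipped) occurrence tibble.
#' @param grid Analysis grid ([grid_spec()]).
#' @return Tibble with `cell`, `col`, `row`, `richness` (distinct accepted
#'   names) and `effort` (record count). Empty cells do not appear.
#' @export
richness_per_cell <- function(records, grid = grid_spec(0.5)) {
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  rec <- records[ok, , drop = FALSE]
  cells <- cell_of(rec$longitude, rec$latitude, grid)
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(cell = cells$cell, col = cells$col,
                                   row = cells$row,
                                   accepted_name = rec$accepted_name),
                    .data$cell, .data$col, .data$row),
    richness = dplyr::n_distinct(.data$accepted_name),
    effort = dplyr::n(), .groups = "drop")
}

#' Weighted endemism per cell
#'
#' Range-size rarity: for each cell *j*, `WE_j = sum_i 1/C_i` over the
#' species *i* present in *j*, where `C_i` is the number of cells species
#' *i* occupies *within the analysis extent* (the cell set being scored).
#' Summed over all cells, WE equals the total species count — an identity
#' used as a self-check throughout the test-suite.
#'
#' @param occupancy Either a tibble with columns `cell` and `accepted_name`
#'   (one row per species presence; duplicates collapsed), or a
#'   cells-by-species matrix (rownames = cell ids) whose nonzero entries
#'   mark presence.
#' @return Tibble with `cell` and `we`.
#' @export
weighted_endemism <- function(occupancy) {
  if (is.matrix(occupancy)) {
    pres <- occupancy > 0
    if (is.null(rownames(pres)))
      rownames(pres) <- as.character(seq_len(nrow(pres)))
    ci <- colSums(pres)
    keep <- ci > 0
    we <- as.numeric(pres[, keep, drop = FALSE] %*% (1 / ci[keep]))
    return(tibble::tibble(cell = rownames(pres), we = we))
  }
  occ <- dplyr::distinct(tibble::as_tibble(
    occupancy[c("cell", "accepted_name")]))
  range_size <- dplyr::summarise(dplyr::group_by(occ, .data$accepted_name),
                                 ci = dplyr::n(), .groups = "drop")
  occ <- dplyr::left_join(occ, range_size, by = "accepted_name")
  dplyr::summarise(dplyr::group_by(occ, .data$cell),
                   we = sum(1 / .data$ci), .groups = "drop")
}

#' Corrected weighted endemism
#'
#' `CWE_j = WE_j / S_j`, in (0, 1]: the mean range restriction of the
#' species in a cell, independent of how rich the cell is. Cells with zero
#' richness are skipped.
#'
#' @param we,richness Numeric vectors of per-cell WE and richness, aligned.
#' @return Numeric vector of CWE (NA where richness is 0).
#' @export
corrected_weighted_endemism <- function(we, richness) {
  stopifnot(length(we) == length(richness))
  out <- ifelse(richness > 0, we / richness, NA_real_)
  out
}

#' Taxonomic biodiversity index
#'
#' `IB = E / ln(A)`: species count scaled by the natural logarithm of area
#' (km^2), used to compare the richness of regions of very different size.
#' Printed values are conventionally rounded to the nearest integer; use
#' [round_half_away()] for that presentation.
#'
#' @param E Species count (>= 0).
#' @param A Area in km^2 (> 1, so that ln(A) is positive).
#' @return Numeric, full precision.
#' @export
taxonomic_biodiversity_index <- function(E, A) {
  if (any(!is.finite(A)) || any(A <= 1))
    stop_data("area must be > 1 km^2 for IB = E/ln(A)")
  if (any(E < 0)) stop_data("species count must be non-negative")
  E / log(A)
}

#' Species density (species per km^2)
#'
#' @param E Species count.
#' @param A Area in km^2 (> 0).
#' @return `E / A`, full precision (tables conventionally print 4 decimals).
#' @export
species_area_ratio <- function(E, A) {
  if (any(!is.finite(A)) || any(A <= 0)) stop_data("area must be > 0")
  E / A
}

#' Round half away from zero
#'
#' Presentation helper matching how printed index tables round (R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Richness-effort correlation
#'
#' Diagnoses collection bias: the squared Pearson correlation between
#' per-cell richness and per-cell record count, with the two-sided p-value
#' from the t transform. With fewer than 3 cells or zero variance in either
#' variable the correlation is undefined: a warning is raised and `NA`s are
#' returned.
#'
#' @param cells Tibble with `richness` and `effort` columns
#'   ([richness_per_cell()]).
#' @return List with `r_squared` and `p_value`.
#' @export
richness_effort_correlation <- function(cells) {
  s <- cells$richness
  n <- cells$effort
  if (length(s) < 3 || stats::sd(s) == 0 || stats::sd(n) == 0) {
    warning("richness-effort correlation undefined: ",
            "need >= 3 cells with variance in both variables")
    return(list(r_squared = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(n, s, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value)
}

#' Assemble the per-cell diversity table
#'
#' Combines richness, effort, WE, CWE and (optionally) endemic and
#' threatened species counts into one table per analysis cell.
#'
#' @param records Cleaned, biome-clipped records.
#' @param grid Analysis grid.
#' @param endemic_species Character vector of endemic species names
#'   (e.g. [endemic_by_records()]); `NULL` for zero counts.
#' @param threatened_species Character vector of threatened species names;
#'   `NULL` for zero counts.
#' @return Tibble with `cell`, `col`, `row`, `richness`, `effort`, `we`,
#'   `cwe`, `endemic_count`, `threatened_count`, sorted by (col, row).
#' @export
cell_diversity <- function(records, grid = grid_spec(0.5),
                           endemic_species = NULL,
                           threatened_species = NULL) {
  base <- richness_per_cell(records, grid)
  ok <- is.finite(records$longitude) & is.finite(records$latitude) &
    !is.na(records$accepted_name)
  rec <- records[ok, , drop = FALSE]
  cells <- cell_of(rec$longitude, rec$latitude, grid)
  occ <- dplyr::distinct(tibble::tibble(cell = cells$cell,
                                        accepted_name = rec$accepted_name))
  we <- weighted_endemism(occ)
  out <- dplyr::left_join(base, we, by = "cell")
  out$cwe <- corrected_weighted_endemism(out$we, out$richness)
  count_in <- function(species) {
    if (is.null(species)) return(rep(0L, nrow(out)))
    sub <- occ[occ$accepted_name %in% species, , drop = FALSE]
    cnt <- table(sub$cell)
    as.integer(ifelse(out$cell %in% names(cnt), cnt[out$cell], 0L))
  }
  out$endemic_count <- count_in(endemic_species)
  out$threatened_count <- count_in(threatened_species)
  dplyr::arrange(out, .data$col, .data$row)
}
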