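#' Run configuration
#'
#' Assembles (or reads from YAML) the single configuration object driving
#' [run_all()]. File paths may be replaced by in-memory objects (tibbles /
#' [karst_polygons()]), which is how the test-suite runs the pipeline on
#' generated data.
#'
#' @param records Occurrence table (path or tibble). Required.
#' @param karst_polygons Biome polygons (path or [karst_polygons()]).
#'   Required.
#' @param name_table Name-resolution table (path or tibble); `NULL` accepts
#'   raw names as-is.
#' @param landmass,centroids,capitals,institutions,urban Gazetteer inputs
#'   (paths or objects); `NULL` disables the corresponding filter.
#' @param legal_table Legal-protection table (path or tibble); optional.
#' @param dedup_cell_deg Collection-dedup cell size (degrees).
#' @param analysis_cell_deg Analysis grid cell size (degrees).
#' @param cleaning Radii and tolerances ([cleaning_config()]).
#' @param thresholds Red-list thresholds ([threshold_config()]).
#' @param synonyms Synonym handling for [resolve_names()].
#' @param top_k Top-k used by [overlay_priority()].
#' @param out_dir Output directory; `NULL` for in-memory results only.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(records, karst_polygons, name_table = NULL,
                       landmass = NULL, centroids = NULL, capitals = NULL,
                       institutions = NULL, urban = NULL, legal_table = NULL,
                       dedup_cell_deg = 0.08, analysis_cell_deg = 0.5,
                       cleaning = cleaning_config(),
                       thresholds = threshold_config(),
                       synonyms = "remap", top_k = 5, out_dir = NULL) {
  if (missing(records) || is.null(records))
    stop_config("config requires 'records'")
  if (missing(karst_polygons) || is.null(karst_polygons))
    stop_config("config requires 'karst_polygons'")
  structure(list(records = records, karst_polygons = karst_polygons,
                 name_table = name_table, landmass = landmass,
                 centroids = centroids, capitals = capitals,
                 institutions = institutions, urban = urban,
                 legal_table = legal_table, dedup_cell_deg = dedup_cell_deg,
                 analysis_cell_deg = analysis_cell_deg, cleaning = cleaning,
                 thresholds = thresholds, synonyms = synonyms,
                 top_k = top_k, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `cleaning` and
#' `thresholds` may be nested mappings overriding individual defaults.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rp <- function(p) if (is.null(p)) NULL else
    (if (file.exists(p)) p else file.path(base, p))
  cl <- do.call(cleaning_config, as.list(y$cleaning %||% list()))
  th <- do.call(threshold_config, as.list(y$thresholds %||% list()))
  run_config(
    records = rp(y$records), karst_polygons = rp(y$karst_polygons),
    name_table = rp(y$name_table), landmass = rp(y$landmass),
    centroids = rp(y$centroids), capitals = rp(y$capitals),
    institutions = rp(y$institutions), urban = rp(y$urban),
    legal_table = rp(y$legal_table),
    dedup_cell_deg = y$dedup_cell_deg %||% 0.08,
    analysis_cell_deg = y$analysis_cell_deg %||% 0.5,
    cleaning = cl, thresholds = th,
    synonyms = y$synonyms %||% "remap",
    top_k = y$top_k %||% 5,
    out_dir = y$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_input <- function(x, loader) {
  if (is.null(x) || !is.character(x)) return(x)
  loader(x)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their canonical order: ingest, name resolution,
#' geographic cleaning, collection-level deduplication, biome clip and
#' gridding, affinity classification, per-cell diversity and endemism,
#' preliminary red-list assessment with legal-status join, and the
#' richness/endemism/threat priority overlay. Every stage appends a
#' machine-readable audit line; with `out_dir` set, all result tables, the
#' audit log (JSON per line, no timestamps — reruns are byte-identical) and
#' the cleaning report are written as delimited text.
#'
#' @param config A [run_config()] (or path to a YAML file).
#' @return A list of class `karst_run`: `records_clean` (full range, after
#'   dedup), `records_karst` (biome-clipped), `report` (cleaning report),
#'   `mask` (biome mask over occupied cells), `profiles` (affinity
#'   classification), `affinity_counts`, `endemics` (record-based),
#'   `cell_table`, `correlation` (richness vs effort), `assessments`,
#'   `category_counts`, `overlay`, `log`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(list(stage = stage), list(...))
  }

  karst <- load_input(config$karst_polygons, read_polygons)
  records <- load_input(config$records, read_occurrences)
  note("ingest", records_in = nrow(records))

  if (!is.null(config$name_table)) {
    tab <- load_input(config$name_table, read_name_table)
    res <- resolve_names(records, tab, synonyms = config$synonyms)
    records <- res$records
    name_report <- res$report
  } else {
    records$accepted_name <- records$raw_name
    name_report <- cleaning_report(nrow(records))
  }
  note("resolve", records_out = nrow(records))

  gazetteer <- list(
    landmass = load_input(config$landmass, read_polygons),
    centroids = load_input(config$centroids, read_gazetteer_points),
    capitals = load_input(config$capitals, read_gazetteer_points),
    institutions = load_input(config$institutions, read_gazetteer_points),
    urban = load_input(config$urban, read_polygons)
  )
  cl <- clean_pipeline(records, gazetteer, config$cleaning)
  records <- cl$records
  report <- merge_reports(name_report, cl$report)
  note("clean", records_out = nrow(records),
       flagged = nrow(cl$flagged))

  records <- dedup_collections(records, cell_size = config$dedup_cell_deg)
  note("dedup_collections", records_out = nrow(records))

  grid <- grid_spec(config$analysis_cell_deg)
  records_karst <- clip_records(records, karst)
  note("clip", records_karst = nrow(records_karst),
       species_karst = dplyr::n_distinct(records_karst$accepted_name))

  cells <- cell_of(records$longitude, records$latitude, grid)
  mask <- classify_cells(karst, grid, cells)
  note("grid", cells_total = nrow(mask),
       cells_karst = sum(mask$class != "NON_KARST"))

  profiles <- classify_affinity(build_profiles(records, mask, grid))
  counts <- affinity_histogram(profiles$class)
  note("affinity", n_species = nrow(profiles),
       endemic = counts[["KARST_ENDEMIC"]],
       associated = counts[["KARST_ASSOCIATED"]],
       non_karst = counts[["NON_KARST"]])

  karst_species <- unique(records_karst$accepted_name)
  assess_rec <- records[records$accepted_name %in% karst_species, ,
                        drop = FALSE]
  assessments <- assess_all(assess_rec, config$thresholds)
  if (!is.null(config$legal_table)) {
    lt <- load_input(config$legal_table, function(p)
      readr::read_csv(p, col_types = readr::cols(
        .default = readr::col_character()), progress = FALSE))
    assessments <- join_legal_status(assessments, lt)
  }
  cat_counts <- category_summary(assessments)
  threatened <- assessments$accepted_name[
    assessments$category %in% c("VU", "EN", "CR")]
  note("assess", n_species = nrow(assessments),
       threatened = length(threatened))

  endemics <- endemic_by_records(records, karst)
  cell_table <- cell_diversity(records_karst, grid,
                               endemic_species = endemics,
                               threatened_species = threatened)
  corr <- suppressWarnings(richness_effort_correlation(cell_table))
  note("diversity", cells = nrow(cell_table),
       endemics = length(endemics),
       we_total = sum(cell_table$we))

  overlay <- overlay_priority(cell_table, k = config$top_k)
  note("overlay", priority_cells = sum(overlay$priority))

  out <- structure(list(
    records_clean = records, records_karst = records_karst,
    report = report, mask = mask, profiles = profiles,
    affinity_counts = counts, endemics = endemics,
    cell_table = cell_table, correlation = corr,
    assessments = assessments, category_counts = cat_counts,
    overlay = overlay, log = log
  ), class = "karst_run")

  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(run$records_clean, file.path(dir, "records_clean.csv"))
  write_table(run$records_karst, file.path(dir, "records_karst.csv"))
  readr::write_csv(run$report, file.path(dir, "cleaning_report.csv"))
  readr::write_csv(run$mask, file.path(dir, "biome_mask.csv"))
  readr::write_csv(run$profiles, file.path(dir, "affinity.csv"))
  readr::write_csv(run$cell_table, file.path(dir, "cell_diversity.csv"))
  readr::write_csv(run$assessments, file.path(dir, "assessments.csv"))
  readr::write_csv(run$overlay, file.path(dir, "overlay.csv"))
  lines <- vapply(run$log, function(x)
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)), "")
  writeLines(lines, file.path(dir, "run_log.jsonl"), useBytes = TRUE)
  invisible(dir)
}

#' @export
print.karst_run <- function(x, ...) {
  cat("<karst_run>\n")
  cat("  records (clean, full range): ", nrow(x$records_clean), "\n", sep = "")
  cat("  records in biome:            ", nrow(x$records_karst), "\n", sep = "")
  cat("  species profiled:            ", nrow(x$profiles), "\n", sep = "")
  cat("  affinity: ", paste(names(x$affinity_counts), x$affinity_counts,
                            sep = "=", collapse = " "), "\n", sep = "")
  cat("  analysis cells:              ", nrow(x$cell_table), "\n", sep = "")
  cat("  preliminary categories: ",
      paste(names(x$category_counts), x$category_counts, sep = "=",
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Priority overlay of richness, endemism and threat
#'
#' Ranks cells separately by species richness, endemic-species count and
#' threatened-species count (descending; ties broken deterministically by
#' cell index) and flags the cells appearing in the top `k` of all three —
#' the candidate conservation-priority areas.
#'
#' @param cell_table Per-cell table from [cell_diversity()].
#' @param k Top-k cutoff per metric.
#' @return `cell_table` columns `cell`, `col`, `row` with the three ranks
#'   and a logical `priority`.
#' @export
overlay_priority <- function(cell_table, k = 5) {
  rank_by <- function(metric) {
    ord <- order(-metric, cell_table$col, cell_table$row)
    r <- integer(length(ord)); r[ord] <- seq_along(ord)
    r
  }
  out <- tibble::tibble(
    cell = cell_table$cell, col = cell_table$col, row = cell_table$row,
    rank_richness = rank_by(cell_table$richness),
    rank_endemic = rank_by(cell_table$endemic_count),
    rank_threatened = rank_by(cell_table$threatened_count)
  )
  out$priority <- out$rank_richness <= k & out$rank_endemic <= k &
    out$rank_threatened <= k
  out
}

#' Write a full synthetic input bundle
#'
#' Materialises a seeded synthetic study — landscape, occurrences with
#' injected contamination, identity name table (plus a rank-filter and an
#' unmatched decoy entry), a small legal-protection table, truth tables and
#' a ready-to-run YAML configuration — in the exact file formats the
#' pipeline ingests. This is the `simulate` entry point of the command-line
#' interface.
#'
#' @param dir Output directory (created).
#' @param seed Integer seed controlling everything.
#' @param n_species,placement Passed to [generate_occurrences()].
#' @return `dir`, invisibly; side effect: files written.
#' @export
write_synthetic_inputs <- function(dir, seed = 1,
                                   n_species = c(endemic = 20,
                                                 associated = 40,
                                                 non_karst = 140),
                                   placement = "cells") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ls <- generate_landscape(landscape_spec(seed = seed))
  occ <- generate_occurrences(ls, n_species = n_species,
                              placement = placement, seed = seed + 1)
  cont <- inject_contamination(occ$records, ls, seed = seed + 2)

  write_table(cont$records, file.path(dir, "records.csv"))
  write_polygons(ls$karst, file.path(dir, "karst.geojson"))
  write_polygons(ls$landmass, file.path(dir, "landmass.geojson"))
  write_polygons(ls$gazetteer$urban, file.path(dir, "urban.geojson"))
  readr::write_csv(ls$gazetteer$centroids, file.path(dir, "centroids.csv"))
  readr::write_csv(ls$gazetteer$capitals, file.path(dir, "capitals.csv"))
  readr::write_csv(ls$gazetteer$institutions,
                   file.path(dir, "institutions.csv"))

  sp <- occ$truth$species$accepted_name
  name_table <- tibble::tibble(
    raw_name = c(sp, "Synthgenus sp.", "Ghostia absentia"),
    accepted_name = c(sp, NA, NA),
    status = c(rep("accepted", length(sp)), "above_species_rank", "unmatched"))
  readr::write_csv(name_table, file.path(dir, "name_table.csv"), na = "")

  set.seed(seed + 3)
  legal <- tibble::tibble(
    accepted_name = sort(sample(sp, max(1, length(sp) %/% 10))),
    legal_status = "protected")
  readr::write_csv(legal, file.path(dir, "legal_table.csv"))
  readr::write_csv(occ$truth$species, file.path(dir, "truth_species.csv"))
  readr::write_csv(cont$truth, file.path(dir, "truth_records.csv"))

  cfg <- list(records = "records.csv", karst_polygons = "karst.geojson",
              name_table = "name_table.csv", landmass = "landmass.geojson",
              centroids = "centroids.csv", capitals = "capitals.csv",
              institutions = "institutions.csv", urban = "urban.geojson",
              legal_table = "legal_table.csv")
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}
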