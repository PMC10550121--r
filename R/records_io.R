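#' Default Darwin Core column mapping
#'
#' Maps the canonical record fields onto the Darwin Core-style headers
#' expected in input files. Override entries to ingest files with other
#' header spellings, e.g. `column_map = default_column_map(latitude = "lat")`.
#'
#' @param scientific_name,latitude,longitude,year,month,day,source Header
#'   names in the input file.
#' @return Named character vector (canonical field -> file header).
#' @export
default_column_map <- function(scientific_name = "scientificName",
                               latitude = "decimalLatitude",
                               longitude = "decimalLongitude",
                               year = "year", month = "month", day = "day",
                               source = "source") {
  c(scientific_name = scientific_name, latitude = latitude,
    longitude = longitude, year = year, month = month, day = day,
    source = source)
}

#' Read occurrence records from delimited text
#'
#' Performs the semantic alignment of attribute names onto a fixed internal
#' schema. Coordinates that do not parse as numbers (e.g. `"n/a"`) are kept
#' as missing values — they are flagged later by the non-numeric coordinate
#' filter, never silently dropped at ingestion. Parsed coordinate values are
#' never rounded or otherwise altered.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Mapping from canonical fields to file headers; see
#'   [default_column_map()]. `scientific_name`, `latitude` and `longitude`
#'   are mandatory; date and source columns are optional in the file.
#' @param delim Field delimiter, default comma.
#' @return A tibble of records with columns `record_id`, `raw_name`,
#'   `accepted_name` (all `NA` until [resolve_names()]), `latitude`,
#'   `longitude`, `year`, `month`, `day`, `source`.
#' @export
read_occurrences <- function(path, column_map = default_column_map(),
                             delim = ",") {
  if (!file.exists(path)) stop_config(paste0("records file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
  need <- c("scientific_name", "latitude", "longitude")
  for (f in need) {
    col <- column_map[[f]]
    if (is.null(col) || !col %in% names(raw))
      stop_config(paste0("mandatory column missing from ", path, ": ",
                         if (is.null(col)) f else col))
  }
  pick <- function(f) {
    col <- column_map[[f]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  id <- if ("recordId" %in% names(raw)) raw[["recordId"]] else
    sprintf("r%06d", seq_len(nrow(raw)))
  tibble::tibble(
    record_id = id,
    raw_name = pick("scientific_name"),
    accepted_name = if ("acceptedName" %in% names(raw)) raw[["acceptedName"]]
      else rep(NA_character_, nrow(raw)),
    latitude = suppressWarnings(as.numeric(pick("latitude"))),
    longitude = suppressWarnings(as.numeric(pick("longitude"))),
    year = suppressWarnings(as.integer(pick("year"))),
    month = suppressWarnings(as.integer(pick("month"))),
    day = suppressWarnings(as.integer(pick("day"))),
    source = pick("source")
  )
}

#' Read a name-resolution table
#'
#' The table replaces a live taxonomic backbone query: one row per distinct
#' raw name with its accepted name and status (`accepted`, `synonym`,
#' `unmatched`, or `above_species_rank`).
#'
#' @param path Delimited text with columns `raw_name`, `accepted_name`,
#'   `status`.
#' @param delim Field delimiter.
#' @return A tibble with those three columns.
#' @export
read_name_table <- function(path, delim = ",") {
  if (!file.exists(path)) stop_config(paste0("name table not found: ", path))
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
  for (col in c("raw_name", "status"))
    if (!col %in% names(tab))
      stop_config(paste0("name table missing column: ", col))
  if (!"accepted_name" %in% names(tab)) tab$accepted_name <- NA_character_
  if (anyDuplicated(tab$raw_name))
    stop_config("name table has duplicated raw_name entries")
  bad <- !tab$status %in% c("accepted", "synonym", "unmatched", "above_species_rank")
  if (any(bad))
    stop_config(paste0("unknown name status: ", tab$status[which(bad)[1]]))
  tibble::as_tibble(tab[c("raw_name", "accepted_name", "status")])
}

#' Resolve raw names against an accepted-names table
#'
#' Drops records whose raw name is missing, not matched in the table, or
#' identified above species rank, and counts every drop. Records carrying a
#' synonym are by default remapped to the accepted species name (they are
#' genuine observations of that species); set `synonyms = "drop"` to discard
#' them instead, mimicking pipelines that discard synonym-labelled rows
#' outright.
#'
#' @param records Tibble from [read_occurrences()].
#' @param table Name-resolution table ([read_name_table()]).
#' @param synonyms `"remap"` (default) or `"drop"`.
#' @return A list with `records` (survivors, `accepted_name` filled) and
#'   `report` (a cleaning report, see [cleaning_report()]).
#' @export
resolve_names <- function(records, table, synonyms = c("remap", "drop")) {
  synonyms <- match.arg(synonyms)
  idx <- match(records$raw_name, table$raw_name)
  status <- ifelse(is.na(records$raw_name) | records$raw_name == "",
                   "missing", table$status[idx])
  status[is.na(status)] <- "unmatched"
  accepted <- table$accepted_name[idx]

  rep <- cleaning_report(nrow(records))
  keep <- rep(TRUE, nrow(records))

  flag_missing <- status == "missing"
  rep <- add_step(rep, "missing_name", sum(keep), sum(flag_missing & keep))
  keep <- keep & !flag_missing

  flag_rank <- status == "above_species_rank"
  rep <- add_step(rep, "above_species_rank", sum(keep), sum(flag_rank & keep))
  keep <- keep & !flag_rank

  flag_unmatched <- status == "unmatched"
  rep <- add_step(rep, "unmatched_name", sum(keep), sum(flag_unmatched & keep))
  keep <- keep & !flag_unmatched

  if (synonyms == "drop") {
    flag_syn <- status == "synonym"
    rep <- add_step(rep, "synonym_name", sum(keep), sum(flag_syn & keep))
    keep <- keep & !flag_syn
  }

  out <- records[keep, , drop = FALSE]
  out$accepted_name <- accepted[keep]
  list(records = out, report = rep)
}

#' Write a table as delimited text
#'
#' UTF-8, lossless round-trip for occurrence records through
#' [read_occurrences()]. An empty collection yields a header-only file.
#'
#' @param x A tibble or data frame. Occurrence records are written with
#'   Darwin Core-style headers (plus `recordId`/`acceptedName`); any other
#'   table is written with its own column names.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = ",") {
  if (is.null(x)) stop_config("nothing to write: collection is NULL")
  if (all(c("record_id", "raw_name", "latitude", "longitude") %in% names(x))) {
    x <- tibble::tibble(
      recordId = x$record_id,
      scientificName = x$raw_name,
      acceptedName = x$accepted_name,
      decimalLatitude = x$latitude,
      decimalLongitude = x$longitude,
      year = x$year, month = x$month, day = x$day,
      source = x$source
    )
  }
  readr::write_delim(x, path, delim = delim, na = "")
  invisible(path)
}

#' Cleaning reports
#'
#' A cleaning report is an audit trail of filtering: one row per step with
#' records in, records flagged, records out, and the flagged share expressed
#' both relative to the step's input and to the original total (the
#' convention used when pipelines print per-filter percentages). Steps
#' chain: the output of step *k* is the input of step *k + 1*.
#'
#' @param total Number of records entering the first step.
#' @return An empty report tibble with attribute `total`.
#' @export
cleaning_report <- function(total) {
  structure(
    tibble::tibble(step = character(), records_in = integer(),
                   records_flagged = integer(), records_out = integer(),
                   pct_of_step = numeric(), pct_of_total = numeric()),
    total = as.integer(total)
  )
}

#' @rdname cleaning_report
#' @param report An existing report.
#' @param step Step label.
#' @param records_in,records_flagged Counts for the step.
#' @export
add_step <- function(report, step, records_in, records_flagged) {
  total <- attr(report, "total")
  if (nrow(report) > 0 && records_in != report$records_out[nrow(report)])
    stop_data("cleaning report steps do not chain")
  row <- tibble::tibble(
    step = step,
    records_in = as.integer(records_in),
    records_flagged = as.integer(records_flagged),
    records_out = as.integer(records_in - records_flagged),
    pct_of_step = if (records_in > 0) 100 * records_flagged / records_in else 0,
    pct_of_total = if (total > 0) 100 * records_flagged / total else 0
  )
  out <- dplyr::bind_rows(report, row)
  attr(out, "total") <- total
  out
}

# concatenate two reports that chain (second starts where first ended)
merge_reports <- function(a, b) {
  out <- dplyr::bind_rows(a, b)
  attr(out, "total") <- attr(a, "total")
  tot <- attr(a, "total")
  if (tot > 0) out$pct_of_total <- 100 * out$records_flagged / tot
  out
}
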