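test_that("ingestion aligns headers, keeps unparseable coordinates as NA", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,decimalLatitude,decimalLongitude,year,month,day,source",
    "Piper amalago,19.1,-99.2,1990,5,2,HERB",
    "Quercus insignis Martínez,n/a,-96.5,,,,HERB",
    "Salvia fulgens,17.0001,-92.3002,2001,11,30,GBIF"
  ), path, useBytes = TRUE)
  rec <- read_occurrences(path)
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$latitude[2]))
  expect_identical(rec$raw_name[2], "Quercus insignis Martínez")
  # no rounding at read time
  expect_identical(rec$latitude[3], 17.0001)
  expect_identical(rec$longitude[3], -92.3002)
})

test_that("column_map aliases ingest identically to canonical headers", {
  canon <- withr::local_tempfile(fileext = ".csv")
  alias <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scientificName,decimalLatitude,decimalLongitude",
               "Aa bb,10.5,-70.25", "Cc dd,-3.125,40"), canon)
  writeLines(c("species,lat,lon",
               "Aa bb,10.5,-70.25", "Cc dd,-3.125,40"), alias)
  a <- read_occurrences(canon)
  b <- read_occurrences(alias, column_map = default_column_map(
    scientific_name = "species", latitude = "lat", longitude = "lon"))
  expect_equal(a[c("raw_name", "latitude", "longitude")],
               b[c("raw_name", "latitude", "longitude")])
})

test_that("missing mandatory column raises a configuration error naming it", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scientificName,decimalLatitude", "Aa bb,1"), path)
  expect_error(read_occurrences(path), "decimalLongitude",
               class = "karstflora_config_error")
})

test_that("resolve_names drops missing/unmatched/rank records and remaps synonyms", {
  tab <- tibble::tibble(
    raw_name = c("Piper amalago", "Piper sanctum", "Piper sp."),
    accepted_name = c("Piper amalago", "Piper auritum", NA),
    status = c("accepted", "synonym", "above_species_rank"))
  rec <- make_records(seq(-99, -98.4, length.out = 7), rep(19, 7),
                      accepted = FALSE)
  rec$raw_name <- c("Piper amalago", "Piper sanctum", "Piper sp.",
                    "Nonexistens ficta", NA, "Piper amalago",
                    "Alia incognita")
  res <- resolve_names(rec, tab)
  expect_equal(nrow(res$records), 3)   # 2 accepted + 1 remapped synonym
  expect_equal(res$records$accepted_name[res$records$raw_name == "Piper sanctum"],
               "Piper auritum")
  rep <- res$report
  expect_equal(rep$records_flagged[rep$step == "missing_name"], 1)
  expect_equal(rep$records_flagged[rep$step == "above_species_rank"], 1)
  expect_equal(rep$records_flagged[rep$step == "unmatched_name"], 2)
  # strict mode drops synonym records too
  strict <- resolve_names(rec, tab, synonyms = "drop")
  expect_equal(nrow(strict$records), 2)
  expect_equal(
    strict$report$records_flagged[strict$report$step == "synonym_name"], 1)
})

test_that("resolve_names is idempotent and report percentages reconstruct retention", {
  tab <- tibble::tibble(raw_name = c("Aa bb", "Cc dd"),
                        accepted_name = c("Aa bb", "Cc dd"),
                        status = c("accepted", "accepted"))
  rec <- make_records(c(-99, -98, -97, -96), c(19, 18, 17, 16),
                      accepted = FALSE)
  rec$raw_name <- c("Aa bb", "Cc dd", "Zz zz", "Aa bb")
  once <- resolve_names(rec, tab)
  twice <- resolve_names(once$records, tab)
  expect_identical(once$records, twice$records)
  # chained step-wise retention equals the overall retained fraction
  rep <- once$report
  stepwise <- prod(1 - rep$records_flagged / rep$records_in)
  expect_equal(stepwise, nrow(once$records) / nrow(rec))
  expect_equal(rep$records_out, rep$records_in - rep$records_flagged)
})

test_that("write_table round-trips records losslessly, including unicode", {
  path <- withr::local_tempfile(fileext = ".csv")
  rec <- make_records(c(-99.123456, -96.5, 100, -70, 0),
                      c(19.654321, NA, 45.25, -33.5, 7),
                      name = "Quercus insignis Martínez",
                      year = 1987L, month = 3L, day = 12L)
  write_table(rec, path)
  back <- read_occurrences(path)
  for (col in c("raw_name", "accepted_name", "latitude", "longitude",
                "year", "month", "day", "source"))
    expect_equal(back[[col]], rec[[col]], label = col)
  # empty collection -> header-only file
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table(rec[0, ], p2)
  expect_equal(length(readLines(p2)), 1)
  expect_equal(nrow(read_occurrences(p2)), 0)
})
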