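test_that("validity and zero-coordinate flags follow their conventions", {
  rec <- make_records(
    longitude = c(-99.2, 10, 0, -99.2, 0.5, NA),
    latitude = c(19.1, 91, 5, 0, 0.5, 12))
  expect_equal(flag_invalid_coords(rec),
               c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE))
  valid <- rec[!flag_invalid_coords(rec), ]
  expect_equal(flag_zero_coords(valid), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(flag_zero_coords(make_records(0.5, 0.5))))
})

test_that("landmass and urban polygon flags are boundary-inclusive complements", {
  land <- unit_square()
  inside <- make_records(0.5, 0.5)
  outside <- make_records(10, 10)
  edge <- make_records(1, 0.5)     # exactly on the eastern edge
  expect_false(flag_outside_landmass(inside, land))
  expect_true(flag_outside_landmass(outside, land))
  expect_false(flag_outside_landmass(edge, land))
  expect_true(flag_in_polygons(inside, land))
  expect_false(flag_in_polygons(outside, land))
  expect_equal(flag_in_polygons(inside, karst_polygons()), FALSE)
})

test_that("proximity flags use great-circle distance with <= radius convention", {
  pts <- tibble::tibble(name = "c", longitude = -99, latitude = 19)
  near <- make_records(-99, 19.0027)       # ~0.30 km north
  far <- make_records(-99, 19.135)         # ~15 km north
  expect_true(flag_near_points(near, pts, radius_km = 1))
  expect_false(flag_near_points(far, pts, radius_km = 10))
  # a record at exactly the radius is flagged
  d_km <- geosphere::distHaversine(c(-99, 19), c(-99, 19.135),
                                   r = 6371000) / 1000
  expect_true(flag_near_points(far, pts, radius_km = d_km))
  expect_error(flag_near_points(near, pts, radius_km = 0),
               class = "karstflora_config_error")
})

test_that("exact geographic duplicates keep the first record in input order", {
  rec <- make_records(c(-99.123456, -99.123456, -99.123456, -99.123457),
                      c(19.1, 19.1, 19.1, 19.1))
  rec$accepted_name <- c("Aa bb", "Aa bb", "Cc dd", "Aa bb")
  expect_equal(flag_geo_duplicates(rec), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("clean_pipeline flags exactly the injected contamination, by the right filter", {
  ls <- generate_landscape(landscape_spec(seed = 7))
  occ <- generate_occurrences(ls, n_species = c(endemic = 5, associated = 10,
                                                non_karst = 35), seed = 8)
  cont <- inject_contamination(occ$records, ls, seed = 9)
  rec <- cont$records
  rec$accepted_name <- rec$raw_name
  out <- clean_pipeline(rec, ls$gazetteer)
  truth <- cont$truth[cont$truth$label != "clean", ]
  expect_setequal(out$flagged$record_id, truth$record_id)
  m <- merge(out$flagged, truth, by = "record_id")
  expect_true(all(m$step == m$label))
  # all-clean input: nothing flagged at any step
  clean_only <- rec[!rec$record_id %in% truth$record_id, ]
  out2 <- clean_pipeline(clean_only, ls$gazetteer)
  expect_equal(sum(out2$report$records_flagged), 0)
})

test_that("the survivor set is invariant to filter order", {
  ls <- generate_landscape(landscape_spec(seed = 10))
  occ <- generate_occurrences(ls, n_species = c(endemic = 5, associated = 5,
                                                non_karst = 20), seed = 11)
  cont <- inject_contamination(occ$records, ls, seed = 12)
  rec <- cont$records
  rec$accepted_name <- rec$raw_name
  full <- clean_pipeline(rec, ls$gazetteer)
  # run duplicates first by pre-flagging them, then the rest of the battery
  dup_first <- rec[!flag_geo_duplicates(rec), ]
  rest <- clean_pipeline(dup_first, ls$gazetteer)
  expect_setequal(full$records$record_id, rest$records$record_id)
})

test_that("dedup_collections collapses same cell/date/species and is idempotent", {
  # two records 0.01 degrees apart inside one 0.08-degree cell, same day
  rec <- make_records(c(-99.201, -99.211, -99.201, -99.201),
                      c(19.101, 19.111, 19.101, 19.101),
                      year = 1990L, month = 5L, day = 2L)
  rec$day <- c(2L, 2L, 3L, 2L)
  dd <- dedup_collections(rec)
  expect_equal(dd$record_id, c("t001", "t003"))
  expect_identical(dedup_collections(dd), dd)
  # absent dates compare equal to absent
  rec2 <- make_records(c(-99.201, -99.205), c(19.101, 19.103))
  expect_equal(nrow(dedup_collections(rec2)), 1)
  # different species in the same cell both survive
  rec3 <- make_records(c(-99.201, -99.205), c(19.101, 19.103))
  rec3$accepted_name <- c("Aa bb", "Cc dd")
  expect_equal(nrow(dedup_collections(rec3)), 2)
})
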