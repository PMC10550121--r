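test_that("EOO handles degenerate inputs and matches a planar shoelace oracle", {
  expect_equal(as.numeric(eoo(data.frame(longitude = -92, latitude = 17))), 0)
  expect_equal(as.numeric(eoo(make_records(c(-92, -92.01), c(17, 17.01)))), 0)
  # small right triangle with ~1 km legs near (17 N, -92 E)
  dlat <- 1 / 110.574
  dlon <- 1 / (111.320 * cos(17 * pi / 180))
  lon <- c(-92, -92 + dlon, -92)
  lat <- c(17, 17, 17 + dlat)
  a <- as.numeric(eoo(data.frame(longitude = lon, latitude = lat)))
  expect_equal(a, eoo_oracle(lon, lat), tolerance = 0.02)
  expect_equal(a, 0.5, tolerance = 0.02)
  # interior points do not change the hull
  lon2 <- c(lon, -92 + dlon / 4)
  lat2 <- c(lat, 17 + dlat / 4)
  expect_equal(as.numeric(eoo(data.frame(longitude = lon2, latitude = lat2))),
               a, tolerance = 1e-9)
  # larger extents (<= 50 km) also agree with the oracle within 2%
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    lon <- -92 + runif(n, 0, 0.4)
    lat <- 17 + runif(n, 0, 0.4)
    expect_equal(as.numeric(eoo(data.frame(longitude = lon, latitude = lat))),
                 eoo_oracle(lon, lat), tolerance = 0.02)
  }
})

test_that("AOO counts occupied 2-km cells times cell area", {
  # base point and two neighbours a few metres away: same cell
  p1 <- data.frame(longitude = -92.0001234, latitude = 17.0004321)
  p3 <- data.frame(longitude = p1$longitude + c(0, 1e-6, -1e-6),
                   latitude = p1$latitude + c(0, 1e-6, 1e-6))
  expect_equal(aoo(p3), 4)
  # two points 10 km apart occupy distinct cells
  p2 <- data.frame(longitude = c(-92, -92), latitude = c(17, 17 + 10 / 110.574))
  expect_equal(aoo(p2), 8)
  # n points far apart -> 4n
  pn <- data.frame(longitude = -92 + (0:9) * 0.5, latitude = rep(17, 10))
  expect_equal(aoo(pn), 40)
  # multiplicity invariance
  expect_equal(aoo(rbind(pn, pn, pn)), 40)
})

test_that("EOO reconciliation and category assignment follow the thresholds", {
  expect_equal(reconcile_eoo(0, 4), 4)
  expect_equal(reconcile_eoo(5000, 4), 5000)
  expect_equal(reconcile_eoo(3, 8), 8)
  out <- assign_category(c(50, 15000, 25000), c(8, 3000, 2500))
  expect_equal(as.character(out$category), c("CR", "VU", "LC"))
  expect_equal(out$basis, c("B1+B2", "B1", NA))
  # step function: values within a threshold interval share the category
  set.seed(31)
  eoo_v <- runif(50, 5000 + 1, 20000 - 1)
  aoo_v <- runif(50, 2000 + 1, 1e5)
  expect_true(all(assign_category(eoo_v, aoo_v)$category == "VU"))
  expect_error(assign_category(-1, 4), class = "karstflora_data_error")
})

test_that("adding points never shrinks EOO/AOO nor raises the threat category", {
  set.seed(22)
  sev <- c(LC = 1, VU = 2, EN = 3, CR = 4)
  for (i in 1:40) {
    n <- sample(4:25, 1)
    lon <- -95 + runif(n, 0, 1.5)
    lat <- 16 + runif(n, 0, 1.5)
    base <- data.frame(longitude = lon[-n], latitude = lat[-n])
    ext <- data.frame(longitude = lon, latitude = lat)
    e0 <- as.numeric(eoo(base)); e1 <- as.numeric(eoo(ext))
    a0 <- aoo(base); a1 <- aoo(ext)
    expect_gte(e1, e0 - 1e-9)
    expect_gte(a1, a0)
    c0 <- assign_category(reconcile_eoo(e0, a0), a0)$category
    c1 <- assign_category(reconcile_eoo(e1, a1), a1)$category
    expect_lte(sev[as.character(c1)], sev[as.character(c0)])
  }
})

test_that("single-point species are CR and widespread species LC", {
  one <- make_records(-92, 17)
  res <- assess_all(one)
  expect_equal(res$eoo_km2, 4)   # reconciled up to the AOO of one cell
  expect_equal(res$aoo_km2, 4)
  expect_equal(as.character(res$category), "CR")
  wide <- generate_assessment_cohort(n_per_category = c(LC = 1), seed = 5)
  res2 <- assess_all(wide$records)
  expect_equal(as.character(res2$category), "LC")
})

test_that("planted red-list categories are recovered exactly", {
  co <- generate_assessment_cohort(seed = 17)
  res <- assess_all(co$records)
  m <- merge(res, co$truth, by = "accepted_name")
  expect_equal(as.character(m$category), m$category_truth)
  # planted disc areas are also recovered by the EOO estimate
  expect_equal(m$eoo_km2, m$disc_area_km2, tolerance = 0.05)
})

test_that("legal status joins on the accepted name, including via synonyms", {
  tab <- tibble::tibble(raw_name = c("Piper lapathifolium", "Piper amalago"),
                        accepted_name = c("Piper amalago", "Piper amalago"),
                        status = c("synonym", "accepted"))
  rec <- make_records(c(-92, -92.3), c(17, 17.2), accepted = FALSE)
  rec$raw_name <- c("Piper lapathifolium", "Piper amalago")
  resolved <- resolve_names(rec, tab)$records
  ass <- assess_all(resolved)
  legal <- tibble::tibble(accepted_name = "Piper amalago",
                          legal_status = "protected")
  out <- join_legal_status(ass, legal)
  expect_equal(out$legal_status, "protected")
  # unmatched name -> NA
  out2 <- join_legal_status(ass, tibble::tibble(accepted_name = "Alia species",
                                                legal_status = "protected"))
  expect_true(is.na(out2$legal_status))
})
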