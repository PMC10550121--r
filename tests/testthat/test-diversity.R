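test_that("richness and effort are counted per cell", {
  g <- grid_spec(0.5)
  rec <- make_records(c(0.1, 0.2, 0.3), c(0.2, 0.2, 0.2))
  rec$accepted_name <- c("Aa bb", "Aa bb", "Cc dd")
  out <- richness_per_cell(rec, g)
  expect_equal(nrow(out), 1)
  expect_equal(out$richness, 2)
  expect_equal(out$effort, 3)
})

test_that("weighted endemism matches the hand-computed two-cell example", {
  occ <- tibble::tibble(cell = c("c1", "c1", "c2"),
                        accepted_name = c("X", "Y", "X"))
  we <- weighted_endemism(occ)
  expect_equal(we$we[we$cell == "c1"], 1.5)   # 1/2 (X) + 1 (Y)
  expect_equal(we$we[we$cell == "c2"], 0.5)
  expect_equal(corrected_weighted_endemism(1.5, 2), 0.75)
  # single-cell dataset: WE = richness
  one <- tibble::tibble(cell = "c1", accepted_name = c("X", "Y", "Z"))
  expect_equal(weighted_endemism(one)$we, 3)
})

test_that("WE conserves total species count and equals the brute-force oracle", {
  set.seed(101)
  for (i in 1:20) {
    m <- random_occupancy(20, 50)
    we <- weighted_endemism(m)
    expect_equal(sum(we$we), 50, tolerance = 1e-12)
    expect_equal(we$we[match(rownames(m), we$cell)], we_oracle(m),
                 tolerance = 1e-12)
  }
  # matrix and long-table interfaces agree
  m <- random_occupancy(12, 9)
  long <- tibble::tibble(
    cell = rownames(m)[row(m)[m > 0]],
    accepted_name = paste0("s", col(m)[m > 0]))
  a <- weighted_endemism(m)
  b <- weighted_endemism(long)
  occupied <- rownames(m)[rowSums(m) > 0]  # empty cells absent from long form
  expect_equal(b$we[match(occupied, b$cell)],
               a$we[match(occupied, a$cell)], tolerance = 1e-12)
})

test_that("all-single-cell species give CWE = 1 everywhere", {
  occ <- tibble::tibble(cell = c("c1", "c1", "c2"),
                        accepted_name = c("X", "Y", "Z"))
  we <- weighted_endemism(occ)
  s <- c(c1 = 2, c2 = 1)
  expect_equal(corrected_weighted_endemism(we$we, s[we$cell]),
               c(c1 = 1, c2 = 1)[we$cell], ignore_attr = TRUE)
})

test_that("the taxonomic biodiversity index reproduces published worked examples", {
  expect_equal(round_half_away(taxonomic_biodiversity_index(9592, 318126)), 757)
  expect_equal(round_half_away(taxonomic_biodiversity_index(7505, 170000)), 623)
  expect_equal(round_half_away(taxonomic_biodiversity_index(1216, 260)), 219)
  expect_equal(taxonomic_biodiversity_index(42, exp(1)), 42)
  expect_error(taxonomic_biodiversity_index(10, 1),
               class = "karstflora_data_error")
})

test_that("species density reproduces published worked examples and monotonicity", {
  expect_equal(round_half_away(species_area_ratio(1216, 260), 4), 4.6769)
  expect_equal(round_half_away(species_area_ratio(9592, 318126), 4), 0.0302)
  expect_equal(species_area_ratio(0, 100), 0)
  # IB and density increase in E at fixed A; IB decreases in A at fixed E
  E <- seq(100, 1000, by = 100)
  expect_true(all(diff(taxonomic_biodiversity_index(E, 5000)) > 0))
  expect_true(all(diff(species_area_ratio(E, 5000)) > 0))
  A <- seq(1000, 100000, by = 1000)
  expect_true(all(diff(taxonomic_biodiversity_index(500, A)) < 0))
})

test_that("richness-effort correlation matches the textbook formula", {
  set.seed(7)
  cells <- tibble::tibble(effort = rpois(40, 30))
  cells$richness <- round(cells$effort * 0.6 + rnorm(40, 0, 2))
  out <- richness_effort_correlation(cells)
  x <- cells$effort; y <- cells$richness
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((40 - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), 40 - 2)
  expect_equal(out$r_squared, r^2, tolerance = 1e-12)
  expect_equal(out$p_value, p, tolerance = 1e-12)
  # exact proportionality gives r^2 = 1
  prop <- tibble::tibble(effort = 1:10, richness = 2 * (1:10))
  expect_equal(richness_effort_correlation(prop)$r_squared, 1)
  # independence: r^2 near zero under the null
  set.seed(8)
  null <- tibble::tibble(effort = rpois(1000, 50), richness = rpois(1000, 20))
  expect_lt(richness_effort_correlation(null)$r_squared, 0.02)
  # degenerate input warns and returns NA
  flat <- tibble::tibble(effort = 1:5, richness = rep(3, 5))
  expect_warning(res <- richness_effort_correlation(flat), "undefined")
  expect_true(is.na(res$r_squared))
})

test_that("cell_diversity assembles WE, CWE and per-cell special counts", {
  g <- grid_spec(0.5)
  rec <- make_records(c(0.1, 0.6, 0.1, 0.1), c(0.2, 0.2, 0.2, 0.3))
  rec$accepted_name <- c("X", "X", "Y", "Z")
  out <- cell_diversity(rec, g, endemic_species = "Y",
                        threatened_species = c("X", "Y"))
  c1 <- out[out$cell == "360_180", ]
  expect_equal(c1$richness, 3)
  expect_equal(c1$we, 1 / 2 + 1 + 1)   # X in two cells, Y and Z in one
  expect_equal(c1$cwe, c1$we / 3)
  expect_equal(c1$endemic_count, 1L)
  expect_equal(c1$threatened_count, 2L)
})
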