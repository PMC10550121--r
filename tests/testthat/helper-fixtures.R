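# Small fixture builders shared across the suite. Everything is generated in
# code; no data files.

make_records <- function(longitude, latitude, name = "Aa bb",
                         year = NA_integer_, month = NA_integer_,
                         day = NA_integer_, accepted = TRUE) {
  n <- length(longitude)
  tibble::tibble(
    record_id = sprintf("t%03d", seq_len(n)),
    raw_name = rep_len(name, n),
    accepted_name = if (accepted) rep_len(name, n) else NA_character_,
    latitude = latitude, longitude = longitude,
    year = rep_len(year, n), month = rep_len(month, n),
    day = rep_len(day, n),
    source = "test"
  )
}

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  karst_polygons(list(rect_ring(x0, y0, x0 + side, y0 + side)))
}

# independent brute-force weighted-endemism oracle: double loop over a
# cells x species presence matrix
we_oracle <- function(m) {
  pres <- m > 0
  we <- numeric(nrow(pres))
  for (j in seq_len(nrow(pres))) {
    for (i in seq_len(ncol(pres))) {
      if (pres[j, i]) {
        ci <- 0
        for (jj in seq_len(nrow(pres))) if (pres[jj, i]) ci <- ci + 1
        we[j] <- we[j] + 1 / ci
      }
    }
  }
  we
}

# independent planar EOO oracle: local equirectangular scaling around the
# centroid, convex hull, shoelace
eoo_oracle <- function(lon, lat) {
  lat0 <- mean(lat)
  x <- (lon - mean(lon)) * 111.320 * cos(lat0 * pi / 180)
  y <- (lat - lat0) * 110.574
  h <- grDevices::chull(x, y)
  xx <- x[h]; yy <- y[h]
  n <- length(xx)
  j <- c(n, seq_len(n - 1))
  abs(sum(xx[j] * yy - xx * yy[j]) / 2)
}

# random occupancy matrix with every species present somewhere
random_occupancy <- function(n_cells, n_species, p = 0.15) {
  m <- matrix(stats::rbinom(n_cells * n_species, 1, p), n_cells, n_species)
  empty <- colSums(m) == 0
  m[sample.int(n_cells, sum(empty), replace = TRUE) +
      (which(empty) - 1) * n_cells] <- 1
  rownames(m) <- paste0("c", seq_len(n_cells))
  m
}
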