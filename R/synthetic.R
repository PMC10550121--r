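#' Synthetic landscape specification
#'
#' Describes a virtual study region emulating an archipelago of karst
#' forest remnants: a bounding box, a number of rectangular karst patches
#' sized in analysis-grid cells, a surrounding landmass, and a gazetteer
#' strip (centroids, capitals, institutions, urban areas) kept far from any
#' species range so that proximity filters have unambiguous truth.
#'
#' Patches are placed on the analysis grid. With `align = TRUE` (default)
#' patch edges coincide with cell edges, so every patch cell is fully
#' karstic and every other cell has zero overlap — the margin-respecting
#' regime where affinity classes are recoverable exactly. With
#' `align = FALSE` patches are offset by `offset_deg`, producing a ring of
#' `MIXED` cells around each patch core.
#'
#' @param bbox `c(lon0, lat0, lon1, lat1)` in degrees.
#' @param n_patches Number of karst patches.
#' @param patch_cells Integer range `c(min, max)` of patch width/height in
#'   analysis cells.
#' @param cell_size Analysis cell size (degrees).
#' @param align Snap patches to the analysis grid?
#' @param offset_deg Patch offset when `align = FALSE`.
#' @param seed Integer seed; the whole landscape is deterministic given it.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(bbox = c(-105, 12, -95, 22), n_patches = 10,
                           patch_cells = c(2, 3), cell_size = 0.5,
                           align = TRUE, offset_deg = 0.2, seed = 1) {
  if (n_patches < 1) stop_config("need at least one patch")
  structure(list(bbox = bbox, n_patches = n_patches,
                 patch_cells = patch_cells, cell_size = cell_size,
                 align = align, offset_deg = offset_deg, seed = seed),
            class = "landscape_spec")
}

#' Generate a synthetic landscape
#'
#' Deterministic given `spec$seed`: karst patches inside an analysis region
#' occupying the eastern ~2/3 of the bounding box, a landmass rectangle
#' generously larger than the box (so that a zero-latitude point is still
#' on land and violates only the zero-coordinate filter), and gazetteer
#' features in a western strip more than 100 km from the analysis region —
#' far beyond three times the largest proximity radius.
#'
#' @param spec A [landscape_spec()].
#' @return List with `karst` ([karst_polygons()]), `landmass`, `gazetteer`
#'   (list `centroids`, `capitals`, `institutions` point tibbles and
#'   `urban` polygons), `patches` (tibble of patch cell origins/sizes) and
#'   `spec`.
#' @export
generate_landscape <- function(spec = landscape_spec()) {
  set.seed(spec$seed)
  s <- spec$cell_size
  b <- spec$bbox
  # analysis region: keep 2.5 deg of clearance from the gazetteer strip
  ar <- c(b[1] + 3, b[2] + 1, b[3] - 0.5, b[4] - 1)
  col_range <- floor((c(ar[1], ar[3]) + 180) / s)
  row_range <- floor((c(ar[2], ar[4]) + 90) / s)

  max_wh <- spec$patch_cells[2]
  patches <- tibble::tibble(col = integer(), row = integer(),
                            w = integer(), h = integer())
  tries <- 0
  while (nrow(patches) < spec$n_patches && tries < 5000) {
    tries <- tries + 1
    w <- sample(spec$patch_cells[1]:spec$patch_cells[2], 1)
    h <- sample(spec$patch_cells[1]:spec$patch_cells[2], 1)
    col <- sample(col_range[1]:(col_range[2] - w), 1)
    row <- sample(row_range[1]:(row_range[2] - h), 1)
    # require a >= 1-cell gap to every accepted patch
    clash <- any(
      patches$col - 1 - w < col & col < patches$col + patches$w + 1 &
      patches$row - 1 - h < row & row < patches$row + patches$h + 1
    )
    if (!clash)
      patches <- dplyr::bind_rows(patches, tibble::tibble(
        col = col, row = row, w = w, h = h))
  }
  if (nrow(patches) < spec$n_patches)
    stop_data("could not place the requested number of disjoint patches")

  dx <- if (spec$align) 0 else spec$offset_deg
  rings <- lapply(seq_len(nrow(patches)), function(i) {
    x0 <- -180 + patches$col[i] * s + dx
    y0 <- -90 + patches$row[i] * s + dx
    rect_ring(x0, y0, x0 + patches$w[i] * s, y0 + patches$h[i] * s)
  })

  gx <- b[1] + 0.5  # gazetteer strip longitude
  gazetteer <- list(
    centroids = tibble::tibble(
      name = c("centroid_country", "centroid_province"),
      longitude = c(gx, gx), latitude = b[2] + c(2, 4)),
    capitals = tibble::tibble(
      name = c("capital_1", "capital_2"),
      longitude = c(gx, gx), latitude = b[2] + c(6, 8)),
    institutions = tibble::tibble(
      name = c("herbarium_1", "herbarium_2", "herbarium_3"),
      longitude = gx + 0.2, latitude = b[2] + c(3, 5, 7)),
    urban = karst_polygons(list(
      rect_ring(gx - 0.3, b[2] + 0.9, gx - 0.1, b[2] + 1.1),
      rect_ring(gx - 0.3, b[4] - 1.1, gx - 0.1, b[4] - 0.9)
    ))
  )

  landmass <- karst_polygons(list(
    rect_ring(b[1] - 5, -5, b[3] + 10, b[4] + 8)))
  gazetteer$landmass <- landmass
  list(
    karst = karst_polygons(rings),
    landmass = landmass,
    gazetteer = gazetteer,
    patches = patches,
    spec = spec
  )
}

# cells fully covered by patch i (all of them when aligned)
patch_full_cells <- function(landscape, i) {
  p <- landscape$patches[i, ]
  s <- landscape$spec$cell_size
  if (landscape$spec$align) {
    expand.grid(col = p$col:(p$col + p$w - 1), row = p$row:(p$row + p$h - 1))
  } else {
    # offset by offset_deg: interior full cells are shifted one in from the
    # low edge; the high edge loses the partly covered band
    off <- landscape$spec$offset_deg
    stopifnot(off > 0, off < s)
    expand.grid(col = (p$col + 1):(p$col + p$w - 1),
                row = (p$row + 1):(p$row + p$h - 1))
  }
}

# sample a point uniformly in a cell, inset by margin on all sides
runif_in_cell <- function(n, col, row, s, margin = 0.1) {
  x0 <- -180 + col * s + margin
  y0 <- -90 + row * s + margin
  w <- s - 2 * margin
  tibble::tibble(longitude = x0 + stats::runif(n) * w,
                 latitude = y0 + stats::runif(n) * w)
}

#' Generate synthetic occurrence records with class truth
#'
#' Builds a cohort of virtual species of three archetypes — karst endemics
#' (occupied cells strictly karstic), karst-associated (more than half of
#' occupied cells karstic) and non-karst — with heavy-tailed per-species
#' record counts (lognormal, median `exp(records_meanlog)`), and returns the
#' records together with a truth table.
#'
#' Two placement regimes:
#' * `"cells"` (margin-respecting): each species is assigned an explicit
#'   cell set consistent with its class; records are laid out round-robin
#'   over those cells, at least one per cell, each at least 0.1 degrees from
#'   any cell or patch edge. Class recovery from the clean records is exact.
#' * `"range"`: records are drawn uniformly from rectangular ranges that
#'   straddle patch edges (use an `align = FALSE` landscape so edge cells
#'   are `MIXED`); occupancy is then stochastic and class recovery is high
#'   but not guaranteed.
#'
#' @param landscape From [generate_landscape()].
#' @param n_species Named integer vector
#'   `c(endemic = , associated = , non_karst = )`.
#' @param records_meanlog,records_sdlog Lognormal parameters of per-species
#'   record counts (defaults: median 5 records per species).
#' @param placement `"cells"` or `"range"`.
#' @param seed Integer seed.
#' @return List with `records` (standard occurrence tibble, `accepted_name`
#'   unset) and `truth` — `species` (tibble `accepted_name`, `class_truth`)
#'   and `records` (tibble `record_id`, `label`, all `"clean"`).
#' @export
generate_occurrences <- function(landscape,
                                 n_species = c(endemic = 20, associated = 40,
                                               non_karst = 140),
                                 records_meanlog = log(5),
                                 records_sdlog = 0.8,
                                 placement = c("cells", "range"),
                                 seed = 1) {
  placement <- match.arg(placement)
  set.seed(seed)
  s <- landscape$spec$cell_size
  npatch <- nrow(landscape$patches)

  # pool of non-karst cells: analysis-region cells >= 1 cell away from any
  # patch (so even unaligned patches cannot leak into them)
  b <- landscape$spec$bbox
  ar_cols <- floor((b[1] + 3 + 180) / s):floor((b[3] - 0.5 + 180) / s)
  ar_rows <- floor((b[2] + 1 + 90) / s):floor((b[4] - 1 + 90) / s)
  all_cells <- expand.grid(col = ar_cols, row = ar_rows)
  near_patch <- rep(FALSE, nrow(all_cells))
  for (i in seq_len(npatch)) {
    p <- landscape$patches[i, ]
    near_patch <- near_patch |
      (all_cells$col >= p$col - 1 & all_cells$col <= p$col + p$w &
       all_cells$row >= p$row - 1 & all_cells$row <= p$row + p$h)
  }
  outside_cells <- all_cells[!near_patch, , drop = FALSE]

  classes <- rep(c("KARST_ENDEMIC", "KARST_ASSOCIATED", "NON_KARST"),
                 times = c(n_species[["endemic"]], n_species[["associated"]],
                           n_species[["non_karst"]]))
  n_sp <- length(classes)
  names_sp <- sprintf("Synthspecies %03d", seq_len(n_sp))

  # patches whose fully-karst core can dominate an associated species' apron
  big_core <- which((landscape$patches$w - 1) * (landscape$patches$h - 1) >= 4)
  if (length(big_core) == 0)
    big_core <- which.max((landscape$patches$w - 1) *
                          (landscape$patches$h - 1))

  rec_list <- vector("list", n_sp)
  for (i in seq_len(n_sp)) {
    cls <- classes[i]
    patch_i <- if (placement == "range" && cls == "KARST_ASSOCIATED")
      big_core[sample.int(length(big_core), 1)] else sample.int(npatch, 1)
    karst_pool <- patch_full_cells(landscape, patch_i)
    n_rec <- max(1L, round(stats::rlnorm(1, records_meanlog, records_sdlog)))

    if (placement == "cells") {
      if (cls == "KARST_ENDEMIC") {
        kk <- sample(1:min(3, nrow(karst_pool)), 1); kn <- 0
      } else if (cls == "KARST_ASSOCIATED") {
        kk <- sample(2:min(3, nrow(karst_pool)), 1); kn <- 1
      } else {
        kk <- sample(0:1, 1); kn <- sample(max(1, kk):4, 1)
      }
      chosen <- dplyr::bind_rows(
        karst_pool[sample.int(nrow(karst_pool), kk), , drop = FALSE],
        outside_cells[sample.int(nrow(outside_cells), kn), , drop = FALSE])
      n_rec <- max(n_rec, nrow(chosen))
      idx <- rep(seq_len(nrow(chosen)), length.out = n_rec)
      pts <- dplyr::bind_rows(lapply(seq_len(n_rec), function(k)
        runif_in_cell(1, chosen$col[idx[k]], chosen$row[idx[k]], s)))
    } else {
      p <- landscape$patches[patch_i, ]
      off <- if (landscape$spec$align) 0 else landscape$spec$offset_deg
      x1 <- -180 + p$col * s + off + p$w * s
      n_rec <- max(n_rec, 6L)
      core <- patch_full_cells(landscape, patch_i)
      cx0 <- -180 + min(core$col) * s; cx1 <- -180 + (max(core$col) + 1) * s
      cy0 <- -90 + min(core$row) * s; cy1 <- -90 + (max(core$row) + 1) * s
      if (cls == "KARST_ENDEMIC") {
        # the endemic archetype occupies exclusively karstic cells, so its
        # range sits in the fully-karst core (with margin)
        pts <- tibble::tibble(
          longitude = stats::runif(n_rec, cx0 + 0.1, cx1 - 0.1),
          latitude = stats::runif(n_rec, cy0 + 0.1, cy1 - 0.1))
      } else if (cls == "KARST_ASSOCIATED") {
        # ~20% of records (always at least one — occurring beyond the karst
        # is what defines the archetype) in an eastern apron crossing the
        # MIXED edge column into the neighbouring outside cell; the rest in
        # the karst core
        n_apron <- min(max(1L, stats::rbinom(1, n_rec, 0.2)), n_rec - 1L)
        in_apron <- seq_len(n_rec) <= n_apron
        pts <- tibble::tibble(
          longitude = ifelse(in_apron,
                             stats::runif(n_rec, cx1 + 0.05, x1 + 0.55),
                             stats::runif(n_rec, cx0 + 0.05, cx1 - 0.05)),
          latitude = stats::runif(n_rec, cy0 + 0.05, cy1 - 0.05))
      } else {
        # most records in cells far from every patch, ~20% in a strip
        # inside the patch's MIXED edge column (the straddle)
        n_strip <- min(stats::rbinom(1, n_rec, 0.2), n_rec - 1L)
        in_strip <- seq_len(n_rec) <= n_strip
        far <- outside_cells[sample.int(nrow(outside_cells), 3), , drop = FALSE]
        k <- rep(seq_len(nrow(far)), length.out = n_rec)
        far_pts <- dplyr::bind_rows(lapply(seq_len(n_rec), function(j)
          runif_in_cell(1, far$col[k[j]], far$row[k[j]], s)))
        pts <- tibble::tibble(
          longitude = ifelse(in_strip,
                             stats::runif(n_rec, cx1 + 0.05, cx1 + 0.45),
                             far_pts$longitude),
          latitude = ifelse(in_strip,
                            stats::runif(n_rec, cy0 + 0.05, cy1 - 0.05),
                            far_pts$latitude))
      }
    }

    rec_list[[i]] <- tibble::tibble(
      record_id = sprintf("s%03d_%04d", i, seq_len(nrow(pts))),
      raw_name = names_sp[i],
      accepted_name = NA_character_,
      latitude = pts$latitude, longitude = pts$longitude,
      year = sample(1950:2020, nrow(pts), replace = TRUE),
      month = sample(1:12, nrow(pts), replace = TRUE),
      day = sample(1:28, nrow(pts), replace = TRUE),
      source = "synthetic")
  }
  records <- dplyr::bind_rows(rec_list)
  list(
    records = records,
    truth = list(
      species = tibble::tibble(accepted_name = names_sp,
                               class_truth = classes),
      records = tibble::tibble(record_id = records$record_id,
                               label = "clean")
    )
  )
}

#' Inject coordinate contamination with known truth
#'
#' Replaces (or, for duplicates, copies) a sampled subset of clean records
#' so that each contaminated record violates exactly one geographic filter:
#' zero latitude (still on the landmass), placement within a fraction of the
#' flagging radius of a centroid/capital/institution, placement inside an
#' urban polygon, placement off the landmass, or an exact (name, lat, lon)
#' copy appended after its source record. Rates are relative to the input
#' record count; sampled sets are disjoint.
#'
#' Only records that are redundant for analysis-cell occupancy (not the
#' first record of their species in their analysis cell) are eligible for
#' coordinate replacement, so the species' occupied-cell truth survives the
#' removal of every contaminated record — class recovery downstream is not
#' degraded by the contamination itself.
#'
#' @param records Clean records (e.g. from [generate_occurrences()]).
#' @param landscape The landscape the records live in.
#' @param rates Named list of per-label rates in \[0, 1) summing to < 1,
#'   over `zero_coord`, `centroid`, `capital`, `institution`, `urban`,
#'   `off_landmass`, `duplicate`.
#' @param config Cleaning radii ([cleaning_config()]); contaminated points
#'   are placed well inside the corresponding radius.
#' @param cell_size_deg Analysis cell size used to decide which records are
#'   redundant for occupancy.
#' @param seed Integer seed.
#' @return List with `records` (contaminated table; duplicates appended at
#'   the end) and `truth` (tibble `record_id`, `label`).
#' @export
inject_contamination <- function(records, landscape,
                                 rates = list(zero_coord = 0.02,
                                              centroid = 0.01, capital = 0.01,
                                              institution = 0.01, urban = 0.01,
                                              off_landmass = 0.02,
                                              duplicate = 0.02),
                                 config = cleaning_config(),
                                 cell_size_deg = 0.5, seed = 1) {
  stopifnot(all(unlist(rates) >= 0), sum(unlist(rates)) < 1)
  set.seed(seed)
  n <- nrow(records)
  labels <- c("zero_coord", "centroid", "capital", "institution", "urban",
              "off_landmass", "duplicate")
  counts <- vapply(labels, function(l)
    if (is.null(rates[[l]])) 0L else as.integer(round(rates[[l]] * n)), 0L)
  occ_cell <- cell_of(records$longitude, records$latitude,
                      grid_spec(cell_size_deg))
  eligible <- which(duplicated(paste(records$raw_name, occ_cell$cell)))
  if (length(eligible) < sum(counts))
    stop_data("not enough occupancy-redundant records to contaminate at these rates")
  take <- eligible[sample.int(length(eligible), sum(counts))]
  idx <- split(take, rep(labels, counts))
  label_of <- rep("clean", n)

  out <- records
  gz <- landscape$gazetteer

  place_near <- function(rows, points, radius_km) {
    m <- length(rows)
    for (k in seq_len(m)) {
      tgt <- points[((k - 1) %% nrow(points)) + 1, ]
      ang <- 2 * pi * k / (m + 1)
      d <- radius_km * 0.25 * k / (m + 1)  # strictly inside the radius
      out$latitude[rows[k]] <<- tgt$latitude + d * sin(ang) / 110.574
      out$longitude[rows[k]] <<- tgt$longitude +
        d * cos(ang) / (111.320 * cos(tgt$latitude * pi / 180))
    }
  }

  if (length(idx$zero_coord)) {
    out$latitude[idx$zero_coord] <- 0
    label_of[idx$zero_coord] <- "zero_coord"
  }
  if (length(idx$centroid)) {
    place_near(idx$centroid, gz$centroids, config$centroid_km)
    label_of[idx$centroid] <- "centroid"
  }
  if (length(idx$capital)) {
    place_near(idx$capital, gz$capitals, config$capital_km)
    label_of[idx$capital] <- "capital"
  }
  if (length(idx$institution)) {
    place_near(idx$institution, gz$institutions, config$institution_km)
    label_of[idx$institution] <- "institution"
  }
  if (length(idx$urban)) {
    rows <- idx$urban
    for (k in seq_along(rows)) {
      ring <- gz$urban[[((k - 1) %% length(gz$urban)) + 1]]
      out$longitude[rows[k]] <- mean(range(ring$x)) +
        stats::runif(1, -0.02, 0.02)
      out$latitude[rows[k]] <- mean(range(ring$y)) +
        stats::runif(1, -0.02, 0.02)
    }
    label_of[rows] <- "urban"
  }
  if (length(idx$off_landmass)) {
    b <- landscape$spec$bbox
    rows <- idx$off_landmass
    # east of the landmass rectangle, still in the valid coordinate domain
    out$longitude[rows] <- b[3] + 12 + stats::runif(length(rows), 0, 3)
    out$latitude[rows] <- stats::runif(length(rows), 5, 20)
    label_of[rows] <- "off_landmass"
  }
  truth <- tibble::tibble(record_id = out$record_id, label = label_of)
  if (length(idx$duplicate)) {
    dup <- records[idx$duplicate, , drop = FALSE]
    dup$record_id <- paste0(dup$record_id, "_dup")
    out <- dplyr::bind_rows(out, dup)
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      record_id = dup$record_id, label = "duplicate"))
    label_of <- c(label_of, rep("duplicate", nrow(dup)))
  }
  list(records = out, truth = truth)
}

#' Generate a cohort with planted red-list categories
#'
#' Virtual species whose records tile a disc of known area: a 4-km interior
#' lattice plus evenly spaced boundary points, converted to degrees by the
#' exact inverse of the package's equal-area projection. Disc area plants
#' the B1 (EOO) band and the lattice point count the B2 (AOO) band, both
#' with a wide margin from the category thresholds, so the expected category
#' is known by construction: CR discs of 50 km^2, EN of 2,500 km^2, VU of
#' 13,000 km^2 and LC of 32,000 km^2.
#'
#' @param n_per_category Named integer vector `c(CR=, EN=, VU=, LC=)`.
#' @param center `c(lon, lat)` of the cohort.
#' @param seed Integer seed (random disc centres and rotations).
#' @return List with `records` (occurrence tibble, `accepted_name` set) and
#'   `truth` (tibble `accepted_name`, `category_truth`, `disc_area_km2`).
#' @export
generate_assessment_cohort <- function(n_per_category = c(CR = 5, EN = 5,
                                                          VU = 5, LC = 3),
                                       center = c(-98.5, 17), seed = 1) {
  set.seed(seed)
  areas <- c(CR = 50, EN = 2500, VU = 13000, LC = 32000)
  R <- 6371
  c0 <- cos(center[2] * pi / 180)
  unproject <- function(x, y) {
    # inverse of project_cea with lon0/lat0 = cohort center
    tibble::tibble(
      longitude = center[1] + x / (R * c0 * pi / 180),
      latitude = asin(pmin(1, pmax(-1, y * c0 / R))) * 180 / pi)
  }
  cats <- rep(names(n_per_category), n_per_category)
  rec_list <- list(); truth_list <- list()
  for (i in seq_along(cats)) {
    cat_i <- cats[i]
    r <- sqrt(areas[[cat_i]] / pi)
    # species centres spread so discs never interact
    ctr_x <- ((i - 1) %% 5 - 2) * 450
    ctr_y <- (floor((i - 1) / 5) - 2) * 450
    m <- max(24, ceiling(2 * pi * r / 4))
    rot <- stats::runif(1, 0, 2 * pi / m)
    ang <- rot + 2 * pi * seq_len(m) / m
    bx <- ctr_x + r * cos(ang); by <- ctr_y + r * sin(ang)
    g <- seq(-floor(r / 4) * 4, floor(r / 4) * 4, by = 4)
    lat_grid <- expand.grid(x = g, y = g)
    keep <- lat_grid$x^2 + lat_grid$y^2 < r^2
    px <- c(bx, ctr_x + lat_grid$x[keep])
    py <- c(by, ctr_y + lat_grid$y[keep])
    pts <- unproject(px, py)
    name <- sprintf("Plantedspecies %s %02d", cat_i, i)
    rec_list[[i]] <- tibble::tibble(
      record_id = sprintf("a%02d_%05d", i, seq_along(px)),
      raw_name = name, accepted_name = name,
      latitude = pts$latitude, longitude = pts$longitude,
      year = 2000L, month = 1L, day = 1L, source = "synthetic")
    truth_list[[i]] <- tibble::tibble(
      accepted_name = name, category_truth = cat_i,
      disc_area_km2 = areas[[cat_i]])
  }
  list(records = dplyr::bind_rows(rec_list),
       truth = dplyr::bind_rows(truth_list))
}
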