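Package: karstflora
Title: Occurrence-Record Cleaning, Karst-Affinity Classification, Gridded
    Endemism and Preliminary Red-List Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling and analysing herbarium-style occurrence
    datasets of biome-restricted floras, motivated by the mountain karst
    forests of Mexico. Provides Darwin Core-style ingestion and taxonomic
    name resolution, the standard battery of coordinate-validity filters
    (zero coordinates, landmass containment, gazetteer proximity, urban
    areas, duplicates), collection-level deduplication on a 0.08 degree
    grid, half-degree gridding with karst/non-karst/mixed cell
    classification, species affinity classes from occupied-cell counts,
    per-cell richness, weighted and corrected weighted endemism, the
    taxonomic biodiversity index E/ln(A), preliminary IUCN criterion-B
    assessment (EOO, AOO, category thresholds), and a deterministic
    synthetic-landscape generator with truth labels so every stage is
    testable without database downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    geosphere,
    grDevices,
    jsonlite,
    polyclip,
    readr,
    rlang,
    sp,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
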