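---
title: "karstflora: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{karstflora: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karstflora)
```

karstflora implements an occurrence-record workflow for biomes defined by a
polygon layer — motivated by the archipelago-like mountain karst forests of
Mexico — from raw Darwin Core-style tables to per-cell diversity metrics
and per-species preliminary red-list categories. This vignette explains the
underlying models and the decisions taken where the methodology left the
design open. It states no empirical result beyond what the package's own
tests and acceptance script compute.

## Record ingestion and name resolution

Input files are delimited text with Darwin Core-style headers; a column map
aliases other spellings. Coordinates are parsed but never altered: a value
like `"n/a"` becomes a missing coordinate and is *flagged later* by the
validity filter rather than silently dropped at read time, so the audit
trail accounts for every record.

Name resolution uses a user-supplied table (raw name → accepted name +
status) standing in for a live taxonomic backbone. Records that are
unidentifiable (missing name, above species rank, unmatched) are dropped
and counted. For records carrying a **synonym**, two behaviours exist in
the wild: discard them together with the invalid names, or remap them to
the accepted species. We default to **remapping**, because a record
labelled with a synonym is a genuine observation of the accepted species —
discarding it throws away occupancy information; `synonyms = "drop"`
reproduces the stricter behaviour. `resolve_names()` is idempotent either
way.

The cleaning report gives, per step, records in/flagged/out and the flagged
share on two bases — of the step's input and of the original total — since
published pipelines typically print the latter while the former is what
chains multiplicatively to the final retained fraction.

## Geographic cleaning

The eight validity filters run in the conventional order (non-numeric, zero
coordinates, off-landmass, centroid, capital, urban, institution,
duplicate), each on the survivors of the previous step. The survivor set is
provably order-independent (each filter is a pointwise predicate; only the
*attribution* of a record to a step depends on order), and the suite tests
that property.

Numerical choices:

* Proximity radii default to 1 km (centroids), 10 km (capitals) and 0.1 km
  (institutions) — the defaults of the reference coordinate-cleaning tools;
  all configurable.
* Distances are haversine on a sphere of radius 6371 km; at the radii
  involved (≤ 10 km) the spherical error is irrelevant, and the model is
  simple enough to oracle in tests.
* A record at exactly the radius is flagged (`≤` convention); a point
  exactly on a polygon boundary counts as *inside* that polygon everywhere
  in the package (landmass, urban areas, biome clip).
* Zero-coordinate detection uses an absolute tolerance (default 1e-9°)
  rather than exact equality.

Collection-level deduplication collapses records sharing a 0.08° grid cell,
year, month, day and accepted name, keeping the first in stable input
order. **Missing date fields compare equal to missing**: two undated
records of a species in one cell are treated as one collection. This is the
conservative choice (it can only remove records, never invent them) and is
documented here because equally defensible pipelines keep undated records
apart.

## Gridding and biome classification

All gridding is on unprojected WGS84 degrees, anchored at (−180, −90) with
half-open cells `[lower, upper)` — every coordinate maps to exactly one
cell, with no double assignment on edges. The analysis grid defaults to
0.5°; the deduplication grid to 0.08°.

Cells are classified against the biome polygons by *full geometric
coverage* (polygon clipping, not centroid sampling): `KARST` when the cell
rectangle is entirely covered, `NON_KARST` at zero intersection, `MIXED`
otherwise, with a relative area tolerance of 1e-6 absorbing clipping noise.
Centroid sampling would be cheaper but cannot express the `MIXED` state
that the affinity rule depends on.

A note on cell areas: a 0.5° cell at these latitudes spans roughly
2,800–3,000 km², not a fixed area; richness maps on degree grids carry that
latitudinal distortion. We keep degree cells because the affinity and
endemism definitions are formulated on them; no equal-area analysis grid is
provided.

## Species affinity to the biome

Per species, over its entire range (the full cleaned dataset, not the
clipped subset), occupied cells are counted once per biome category — a
`MIXED` cell contributes one occupied cell to *both* categories. The three
classes are: `KARST_ENDEMIC` (no non-karst cells), `KARST_ASSOCIATED`
(karst fraction strictly > 0.5) and `NON_KARST` (otherwise).

Two open points and how we resolved them:

* **Ties.** "More than half inside" and "more than half outside" both fail
  when exactly half the occupied cells are karstic. We assign ties to
  `NON_KARST` — claiming karst affinity requires positive evidence — and
  expose `tie = "KARST_ASSOCIATED"` for the complementary convention.
* **Species occupying only MIXED cells.** A MIXED cell contributes to both
  counts, so such a species has equal counts — the tie rule applies and it
  is classed `NON_KARST` by default; with any fully-karst cell added it
  becomes `KARST_ASSOCIATED`. Either way, a species genuinely restricted
  to the biome but living entirely in partially-karst cells can never be
  classed endemic by the cell-based rule — an acknowledged resolution
  limit of the method, not a bug (the record-based definition below does
  recognise it).

The cell-based classifier is canonical. A second, record-based definition —
endemic = every georeferenced record inside the polygons — is used for
endemism *mapping* (`endemic_by_records()`), and a record-proportion
banding (`record_proportion_summary()`) is provided as a secondary report.
The definition in use is always an explicit argument, never inferred.

## Diversity and endemism indices

Weighted endemism per cell *j* is range-size rarity,
`WE_j = Σ_i 1/C_i`, summing over species present in *j*; `C_i` is the
number of cells species *i* occupies **within the analysis extent**. The
extent restriction matters: scoring a clipped dataset against global range
sizes would deflate WE, and the reference implementations score the dataset
they are given. It also yields the conservation law `Σ_j WE_j = S` (total
species), which the test-suite asserts to 1e-9 on random occupancy matrices
and against a brute-force double-loop oracle to 1e-12. Corrected weighted
endemism divides by richness, `CWE_j = WE_j/S_j ∈ (0, 1]`.

For cross-region comparison the package computes the taxonomic biodiversity
index `IB = E/ln(A)` (area in km², natural log, defined for `A > 1`) and
the species density `E/A`. Printed tables conventionally round IB to an
integer and density to 4 decimals; `round_half_away()` reproduces that
presentation (R's own `round()` rounds half to even). One published
worked-example table that the tests reproduce has three internally
consistent rows; its fourth row (Mexico: IB 993 and density 0.2586 against
E = 11,771 and A = 40,759) is inconsistent with the stated formulas, which
imply E ≈ 10,540 for both printed values. The package reproduces the three
consistent rows and sets no expectation on the fourth.

The richness–effort diagnostic is a squared Pearson correlation between
per-cell richness and record count with the usual t-transform p-value;
p-values are reported, never used as acceptance quantities. With fewer than
3 cells or zero variance the correlation is undefined and returned as `NA`
with a warning.

## Preliminary criterion-B assessment

EOO is the convex-hull area of a species' unique points, computed on a
cylindrical equal-area projection whose standard parallel and central
meridian sit at the point cloud's centroid (identity recorded in an
attribute). Fewer than three unique points, or a collinear hull, give 0,
after which EOO is reconciled to `max(EOO, AOO)` — the extent may not be
smaller than the occupancy. AOO counts occupied 2×2 km cells on a fixed
equal-area grid anchored at the projection origin (no origin optimisation —
deterministic; an optional origin shift exposes the sensitivity for
diagnostics) and multiplies by the cell area.

Categories follow criterion B thresholds — B1 on EOO (CR < 100,
EN < 5,000, VU < 20,000 km²), B2 on AOO (10 / 500 / 2,000 km²) — taking
the more severe, with the driving subcriterion recorded. Two deliberate
simplifications, prominent in the output's framing: the criterion-B
subconditions (severe fragmentation, number of locations, continuing
decline) are **assumed to hold**, as in reference preliminary-assessment
tools, so categories are triage signals, not Red List assessments; and NT
is never assigned — the bottom category is LC.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with truth labels at every stage:

* **Landscape**: 10 rectangular karst patches (2–3 analysis cells a side)
  on a 10°×10° bounding box, pairwise separated by at least one cell; a
  landmass rectangle generously larger than the box (so a zero-latitude
  point is still on land and violates only the zero-coordinate filter);
  and a gazetteer strip (centroids, capitals, institutions, urban
  polygons) placed > 100 km from the analysis region — beyond three times
  the largest proximity radius, so proximity truth is unambiguous.
* **Species**: three archetypes (endemic / associated / non-karst) in
  1:2:7 proportions by default (200 species), with per-species record
  counts lognormal with median 5 — the heavy-tailed effort distribution
  real collections show. In the default `"cells"` placement each species
  receives an explicit cell set consistent with its class and at least one
  record per cell, each ≥ 0.1° from any cell or patch edge; recovery of
  the class truth is then exact, which is what makes it a usable oracle.
  The `"range"` placement draws records uniformly from ranges that
  straddle patch edges (with `align = FALSE` landscapes producing `MIXED`
  edge cells); occupancy is then stochastic and recovery high but not
  guaranteed. Associated species always place at least one record beyond
  the karst core — occurring outside is what the archetype means.
* **Contamination**: seven labels (zero coordinate, centroid, capital,
  institution, urban, off-landmass, exact duplicate), each record
  violating exactly one filter, sampled only from records redundant for
  cell occupancy so that cleaning truth and affinity truth compose. Real
  contaminated records often violate several filters at once; the
  exclusivity here is a deliberate divergence that makes per-filter
  attribution testable.
* **Red-list truth** lives in a separate generator
  (`generate_assessment_cohort()`): species are discs of known area — a
  4-km interior lattice plus boundary circle points, converted to degrees
  by the exact inverse of the package's equal-area projection — so the B1
  band is planted by the disc area (50 / 2,500 / 13,000 / 32,000 km² for
  CR / EN / VU / LC) and the B2 band by the lattice point count, all with
  > 5% margins from the thresholds. Keeping this cohort separate from the
  landscape generator keeps each truth independent of the machinery it
  checks.

What passing these tests does *not* show about real data: the generator has
no misidentifications, no spatially autocorrelated collection bias beyond
per-cell effort, no fuzzy duplicates (transcription jitter), and its
contamination is filter-exclusive. Results on real aggregator downloads
will be noisier in all four respects.

## Problem sizes and determinism

The default synthetic study (200 species, ~1,400–2,000 records, 10 patches)
runs the full pipeline in a few seconds; the test-suite's property
batteries use 100 random occupancy matrices, 1,000 random point sets and
200-species cohorts, sizes chosen so the whole suite stays fast while still
exercising every code path. All randomness is seed-parameterised;
`run_all()` itself contains no randomness, and its outputs are written
without timestamps so reruns of the same configuration are byte-identical.

## Known limitations

* Polygon support is outer-rings-only (no holes); supply pre-dissolved
  layers.
* Degree-based analysis cells are not equal-area (see above).
* The preliminary categories deliberately overstate risk relative to full
  criterion-B logic; they are a prioritisation signal.
* No rarefaction or richness extrapolation; the richness–effort correlation
  is the only sampling-bias diagnostic.
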