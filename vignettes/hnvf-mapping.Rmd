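---
title: "Mapping High Nature Value farmland at administrative-unit level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping High Nature Value farmland at administrative-unit level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnvfmap)
```

## The problem

High Nature Value farmland (HNVf) is agricultural land whose conservation
value depends on the continuation of low-intensity farming. Three types are
distinguished: farmland with a high share of semi-natural vegetation
(type 1), low-intensity mosaics with abundant small-scale features (type 2),
and farmland supporting species of conservation concern, often within
otherwise intensively managed landscapes (type 3). EU rural-development
monitoring requires member states to assess the extent of HNVf, but coarse
land-cover products systematically miss the local features that carry its
value. hnvfmap implements a bottom-up alternative: all indicators are
computed per local administrative unit (here called a parish), from the
finest land-cover, natural-constraint and agrarian-census data available for
that unit, and combined through an explicit threshold cascade into per-unit
HNVf maps and area accounts.

## The four-step procedure

**Step 1 — eligibility and candidate envelopes.** The utilized agricultural
area (UAA) of each parish is the union of farmland-role land-cover classes
and off-farm grazing classes (heathland commons and similar), the latter
restricted to land with no or only moderate natural constraints to
agriculture (`compute_uaa()`). Parishes where the UAA share of the territory
reaches the dominance threshold (default 40 %) proceed; the rest are flagged
not applicable (`dominance_screen()`). Within eligible parishes, land-cover
classes are scored by HNVf likelihood: *minimum* classes (semi-natural
pastures, hay meadows, eligible grazed heathland) are almost certainly HNV;
*maximum-only* classes (arable mosaics, vineyards, orchards) are potentially
HNV depending on intensity. Their areas delimit the candidate envelope
pHNVf~m~ ⊆ pHNVf~M~ (`min_max_candidates()`).

**Step 2 — intensity and structure cascades.** A parish is HNVf-1 when its
livestock density (LSI, livestock units per hectare of UAA) and irrigation
share both stay at or below their cuts; its type-1 extent is its minimum
candidate area. A parish is HNVf-2 when the Shannon evenness of its
land-cover mosaic and its edge density both reach their cuts; its type-2
extent is the maximum-minus-minimum candidate area. Crop-diversity
indicators act as confirmation by default: parishes in the bottom tercile of
crop Shannon diversity are flagged, not excluded (a strict-filter mode is
available via `cd_strict`).

**Step 3 — species overlay.** Occurrences of indicator plant species
(recorded as grid squares) and Important Bird and Biodiversity Areas are
intersected with the mapped extent (`species_coincidence()`), and
species-supported UAA not already covered by types 1 or 2 is designated
HNVf-3 (`designate_hnvf3()`). Because the framework's original use of
species data was a sensitivity check without an explicit construction rule,
the set-algebra definition used here — (occurrences ∪ IBAs) ∩ UAA minus the
type-1/2 extent — is a package design choice; `designate_type3 = FALSE`
restricts Step 3 to coincidence reporting.

**Step 4 — assembly.** Per-parish areas are summed to municipality totals
(reported to 0.01 ha) and each parish receives a trend label comparing the
refined type area with its candidate envelope (decrease / unchanged /
increase at the 0.01-ha reporting tolerance).

## Indicators and thresholds

| Indicator | Meaning | Unit | Cascade role | Default cut |
|---|---|---|---|---|
| P.UAA | farmland share of parish area | % | eligibility | ≥ 40 |
| LSI | livestock units per ha UAA | LSU/ha | type 1 | ≤ 0.2 |
| Irrig | irrigated share of UAA | % | type 1 | ≤ 15 |
| SDI / SEI | Shannon diversity / evenness of the mosaic | – | type 2 | SEI ≥ 0.60 |
| NP / MSI | patch number, mean shape index | – | descriptive | – |
| ED | edge length per parish area | m/ha | type 2 | ≥ 300 |
| SDI~c~ / SEI~c~ / SCrop | crop diversity, evenness, richness | – | confirmation | bottom tercile flagged |

All cuts retain at equality: the framework phrases exclusions as strictly
above/below the cut, so the cut itself stays in. Edge density is thresholded
in m/ha (its defining unit), and livestock density uses the Eurostat
standard LSU coefficients (`eurostat_lsu_coefficients()`), overridable where
a census uses different categories.

Before the cascade, the indicator set is screened for redundancy with
Kendall's τ-b (tie-corrected, suitable for small administrative tables):
for any pair with |τ| ≥ 0.7 the indicator later in a declared ecological
priority order (intensity before structure before crop diversity) is
dropped from the reported set. Anti-correlated pairs are treated as equally
redundant. Constant columns, whose rank correlation is undefined, are
reported as missing and retained with a warning.

## Geometry on a lattice

All spatial computation runs on a regular lattice in a projected metric
coordinate system. Vector inputs (GeoJSON polygons) are discretized on load
by the cell-centre rule at a configurable resolution (default 10 m) using an
even-odd point-in-polygon test; masks are polygonized on write by tracing
boundary edges into exterior rings (counter-clockwise) and holes
(clockwise), so write-then-read round-trips are exact. Consequences worth
knowing:

* Areas equal planar m²/10,000 and are exact for any mosaic aligned to the
  lattice, accurate to one cell otherwise.
* A patch is a maximal edge-connected (4-neighbour) same-class region:
  polygons sharing a boundary segment merge, corner contact does not —
  the vector-dissolve adjacency convention.
* The mean shape index uses the circle-normalized vector form
  p/(2√(πa)) (1 for a circle); a raster-normalized form 0.25·p/√a
  (1 for a square) is available via `shape_index = "raster"`. On a lattice,
  perimeters of non-rectilinear shapes are staircase lengths, so MSI should
  be compared between units computed at the same resolution, not against
  vector-GIS output.
* Edge density divides the summed patch perimeters by the parish area;
  internal class borders are therefore counted from both sides, and
  segments on the parish boundary are included by default
  (`exclude_unit_boundary = TRUE` removes them; the choice is recorded in
  the run manifest).
* Landscape metrics can be computed over all classes or over farmland only
  (`metric_scope`); diversity uses area shares of the classes present in
  the chosen scope after clipping, dropping shares below 1e-12. A
  single-class parish has SEI defined as 0 (no evenness information).
* Geographic (degree-unit) coordinate systems are rejected at load time;
  all layers must share one projected CRS.

## The worked example

`melgaco_table_fixture()` ships the reference per-parish indicator values
and candidate/refined areas for the 18 civil parishes of Melgaço (northern
Portugal), the mountain municipality for which this framework was developed;
`run_table_cascade()` drives the Step-2 cascade from those tables alone.
Six parishes fail the 40 % dominance screen. For type 1 the fixture cascade
runs with the livestock cut non-binding (`lsi_max = Inf`): that is the
reference decision path, where livestock density was assessed first, found
uninformative at parish level, and only the irrigation cut applied, removing
three parishes. For type 2, the evenness cut removes four parishes and the
edge-density cut three more, leaving five. Refined type-2 areas are carried
as fixture data because the spatial mask behind them is not derivable from
the published tables; the cascade reproduces the retained sets, the per-type
totals (9478.17 ha, 618.17 ha) and the overall extent (10096.34 ha).
Reference tables of this kind contain rounding and occasional internal
inconsistencies; the fixture keeps the printed values as data and the tests
compare totals at the table's own precision (0.02 ha).

## The synthetic generator

`generate_municipality()` builds complete, seeded municipalities so every
stage is testable without external GIS data. Parishes tile a rectangle
(default 3 × 6 parishes of 800 m × 800 m at 10 m cells — a deliberately
compact municipality that keeps full-pipeline experiments cheap while
preserving realistic patch-size/edge-density gradients). Each parish
follows one of four profiles emulating the structure of a mountain
agro-pastoral municipality with a west-to-east intensity gradient:

* `extensive_seminatural` — meadow/pasture/heath dominated, LSI drawn in
  0.02–0.15 LSU/ha, irrigation 0–8 % (planted label: type 1);
* `mosaic_diverse` — eight evenly shared classes in small (≈0.8 ha)
  patches, irrigation 25–50 % (planted label: type 2);
* `intensive` — arable-dominated low-evenness cover in coarse patches,
  irrigation 25–50 % (planted label: none);
* `forest_dominated` — ≈64 % forest, farmed share well under the dominance
  cut (planted label: not applicable).

Mosaics are grown by seeded region growing: class seeds are allocated to
the profile's target shares by largest remainder (avoiding multinomial
noise), scattered uniformly, and cells join the seed minimizing a
noise-perturbed squared distance, yielding irregular contiguous patches at
the requested mean size. Constraint blobs are generated the same way at
4-cell granularity. Agrarian statistics are back-computed from each
profile's intensity draws and the realized UAA, so the planted labels are
consistent with the data the pipeline actually sees. Species occurrences
(200 m squares — scaled to the synthetic extent; real grid-square records
are typically 1 km on parishes an order of magnitude larger) are placed in
extensive parishes with probability 0.8, plus one IBA polygon over an
extensive parish. Profile parameter ranges sit on the far sides of the
default thresholds by design, so planted labels are recoverable; the
recovery experiment (`recovery_experiment()`, 100 municipalities of 18
parishes in the shipped configuration) measures exactly that separability.

What the generator does **not** emulate: irregular parish boundaries,
topographic gradients and spatially autocorrelated constraint structure,
census noise and reporting error, and mixed-profile parishes. Passing the
recovery experiment therefore shows that the pipeline implements the
cascade faithfully under separable conditions — not that the default
thresholds discriminate real municipalities, where threshold choice remains
a substantive decision.

## Numerical choices and limitations

* Lattice resolution trades accuracy for cost quadratically; 10 m resolves
  0.01-ha features, matching fine-scale municipal land-cover maps.
* Rasterization is last-feature-wins for overlapping polygons; degenerate
  rings (under four coordinates) are rejected with the feature index.
* Where the constraint layer has no coverage, the limitation defaults to
  `none` (configurable via `missing=` in `load_constraints()`).
* Missing numeric cells in agrarian tables read as 0 with a warning;
  negative values and duplicated unit ids are errors.
* Irrigated area above the UAA is capped at 100 % with a warning (census
  tables occasionally report irrigable rather than irrigated area).
* The municipality totals are reported to 0.01 ha; trend labels use the
  same tolerance.
* Exact numeric reproduction of externally computed metric tables (SDI,
  MSI, ED) is not attempted: those values depend on unpublished tool
  options (boundary inclusion, shape-index normalization, dissolve rules).
  The package instead fixes each convention explicitly, records it in the
  run manifest, and validates the metric engine against exhaustive
  raster-counting oracles.
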