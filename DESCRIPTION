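Package: hnvfmap
Title: Mapping High Nature Value Farmland from Land Cover and Agrarian Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit four-step pipeline to map the extent of High
    Nature Value farmland (HNVf types 1, 2 and 3) at the level of local
    administrative units (parishes). From a classed land-cover map, parish
    boundaries, natural-constraint data and per-parish agrarian statistics it
    computes landscape-pattern metrics (Shannon diversity and evenness, patch
    number, mean shape index, edge density), farming-intensity indicators
    (livestock density, irrigation share) and crop-diversity indicators,
    screens indicator redundancy with Kendall's tau, applies a threshold
    cascade to delimit minimum-maximum HNVf candidate envelopes and refined
    type 1/2 extents, overlays indicator-species occurrences to designate
    complementary type-3 areas, and reports per-unit and municipality area
    accounts. Includes a seeded synthetic-municipality generator with planted
    ground truth so every stage is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
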