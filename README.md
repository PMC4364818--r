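# hnvfmap

Mapping the extent of High Nature Value farmland (HNVf) at
local-administrative-unit level, from a classed land-cover map,
natural-constraint data and per-unit agrarian statistics.

## What it does

High Nature Value farmland is agricultural land whose conservation value
depends on the continuation of low-intensity farming: farmland rich in
semi-natural vegetation (type 1), fine-grained low-intensity mosaics
(type 2), and farmland supporting species of conservation concern (type 3).
`hnvfmap` implements a spatially explicit four-step pipeline over the civil
parishes (LAUs) of a municipality:

1. **Eligibility and candidate envelopes.** The utilized agricultural area
   (UAA) per parish combines farmland classes with off-farm grazing land
   under no or moderate natural constraints; parishes with UAA share
   ≥ 40 % proceed. Land-cover classes scored by HNVf likelihood delimit the
   candidate envelope pHNVf_m ⊆ pHNVf_M per parish.
2. **Threshold cascades.** Type 1: livestock density LSI = Σ(heads × LSU
   coefficient)/UAA ≤ 0.2 LSU/ha and irrigation share ≤ 15 % of UAA.
   Type 2: land-cover Shannon evenness SEI = (−Σ pᵢ ln pᵢ)/ln m ≥ 0.60 and
   edge density ED ≥ 300 m/ha, with crop-diversity confirmation. Indicator
   redundancy is screened beforehand with Kendall's τ-b at |τ| ≥ 0.7.
3. **Species overlay.** Indicator-species occurrences and Important Bird
   Areas are intersected with the mapped extent; species-supported UAA not
   already mapped is designated type 3.
4. **Assembly.** Per-parish and municipality area accounts with trend
   labels against the candidate envelope.

Because no vector-GIS stack is required, all geometry runs on a regular
lattice (default 10 m) with GeoJSON in/out; patches are edge-connected
same-class regions, and all metric conventions are explicit and recorded in
the run manifest. A seeded synthetic-municipality generator with planted
ground truth makes every stage testable end to end. See the vignette
`vignettes/hnvf-mapping.Rmd` for the model, parameter and design details.

## Worked example

The package ships the reference per-parish tables of the 18-parish
municipality of Melgaço (northern Portugal) as a fixture and can drive the
threshold cascade from them directly:

```r
library(hnvfmap)
fx  <- melgaco_table_fixture()
cas <- run_table_cascade(fx)   # livestock cut non-binding, irrigation at 15 %
str(cas$totals)
#> List of 7
#>  $ hnvf1_ha     : num 9478
#>  $ hnvf2_ha     : num 618
#>  $ hnvf_total_ha: num 10096
#>  $ n_eligible   : int 12
#>  $ n_na         : int 6
#>  $ n_hnvf1      : int 9
#>  $ n_hnvf2      : int 5
```

Twelve of the eighteen parishes are farmland-dominant; the irrigation cut
removes three of them from type 1 (9 parishes, 9478.17 ha of minimum
candidate area retained), and the evenness and edge-density cuts leave five
type-2 parishes (618.17 ha), for a total HNVf extent of 10096.34 ha.

A full geometric run on synthetic data:

```r
gen <- generate_municipality(hnvf_scenario(seed = 7))
run <- run_pipeline(gen$landcover, gen$zones, gen$registry, gen$agrarian,
                    constraints = gen$constraints, species = gen$species)
run
#> <hnvf_run> 18 units, 15 farmland-dominant
#>   candidate envelope: 354.15 - 753.61 ha
#>   HNVf-1 266.43 ha | HNVf-2 222.36 ha | HNVf-3 16.02 ha | total 504.81 ha
predict_labels(run)          # compare with gen$truth
write_result(run, "out/")    # CSV tables, GeoJSON extents, manifest
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/hnvf.R synth --seed 1 --out data/
Rscript inst/cli/hnvf.R run --config config.yaml --out out/
Rscript inst/cli/hnvf.R fixture-check
```

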