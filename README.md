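# floragrid

Tools for analysing the diversity and distribution of a national
useful-plant flora from a species checklist and georeferenced occurrence
records — the workflow behind edible-plant diversity assessments such as
the one carried out for Colombia (3805 edible species across 33
departments and 13 bioregions). It is aimed at biodiversity informaticians
and ethnobotanists who need the full chain from raw Darwin-Core tables to
per-cell endemism maps to be reproducible, audited and testable offline.

The pipeline has four stages:

1. **Checklist curation** — reconcile verbatim names against a taxonomic
   backbone (exact match after conservative normalisation; no fuzzy
   matching), flag neglected and underutilized species (NUS = catalogued
   species absent from a crop-census list), and compute catalogue summary
   statistics with one-decimal percentage shares (round half away from
   zero).
2. **Occurrence cleaning** — the standard coordinate filter battery for
   herbarium data: unparseable and out-of-range coordinates, zero or equal
   latitude/longitude, fewer than 3 decimals of recorded precision
   (counted on the verbatim text), country-centroid proximity, sea, urban
   centres, institutions; then exact-duplicate collapse on
   (taxon, lat, lon). Every removal is attributed to the first failing
   filter, and the report satisfies
   `n_input = n_output + Σ removals + duplicates` exactly.
3. **Grid metrics** — on a 0.1° lattice anchored at (−180, −90), with
   `C_s` the number of cells occupied by species `s`:
   `SR = #{species in cell}`, `WE = Σ_s 1/C_s` (inverse range-size
   rarity), `CWE = WE/SR ∈ (0, 1]`. Summed over all cells, WE equals the
   number of gridded species — a conservation law the tests assert to
   1e−9.
4. **Regional aggregation** — point-in-polygon assignment to department
   and bioregion GeoJSON polygons (alphabetical boundary tie-break),
   per-region record/species/genus/family counts, species breadth
   distributions, and an OLS regression of richness on record count to
   expose sampling-effort bias.

A seeded synthetic-data generator (`simulate_scenario()`) produces
checklists, backbones, occurrence tables, toy geometry and contamination
with ground-truth answer keys, so the whole pipeline is testable without
any external download.

## Worked example

```r
library(floragrid)

cfg  <- scenario_config(seed = 42)       # 300-species demo scenario
scen <- simulate_scenario(cfg)

chk <- flag_nus(scen$checklist, scen$crops$accepted_name)
summarize_catalogue(chk)
#> Edible-species catalogue summary
#>   species: 300  families: 19  genera: 75
#>   native                  220  (73.3%)
#>   endemic                  20  (6.7%)
#>   naturalised              34  (11.3%)
#>   cultivated               63  (21.0%)
#>   locally_reported        168  (56.0%)
#>   nus                     291  (97.0%)

fc  <- filter_config(centroid = scen$geometry$centroid,
                     institution_points = scen$geometry$institutions,
                     urban_polygons = scen$geometry$urban,
                     land_polygon = scen$geometry$land)
cln <- clean_pipeline(scen$occurrences, fc)
cln
#> Occurrence cleaning: 2940 records in, 2698 out
#>   removed (zero_coordinate): 27
#>   removed (equal_coordinates): 27
#>   removed (low_precision): 54
#>   removed (centroid): 13
#>   removed (sea): 27
#>   removed (urban): 27
#>   removed (institution): 13
#>   duplicates collapsed: 54
```

The scenario injected exactly those contaminant counts (1%/1%/2%/0.5%/1%/
1%/0.5%/2% of 2698 clean records), so the per-filter removals recover the
ground truth exactly. Gridding the survivors:

```r
m <- compute_grid_metrics(cln$records, scen$grid)
head(m[order(-m$SR), c("cell_i", "cell_j", "SR", "WE", "CWE")], 3)
#>   cell_i cell_j    SR    WE   CWE
#> 1   1818    906     5  4.5  0.9
#> 2   1821    927     5  2.83 0.567
#> 3   1817    902     4  2.75 0.688
sum(m$WE)   # = 300, the number of gridded species (conservation law)
```

The richest cell holds five species of which most are narrow-ranged
(CWE = 0.9): a rarity hotspot, not merely a sampling hotspot. Regional
aggregation and the effort regression:

```r
dep <- region_set(scen$geometry$departments)
s <- summarize_regions(cln$records, chk, dep)
richness_records_regression(s)
#> Richness ~ records OLS (n = 5): slope = 0.1287, intercept = -7.067,
#>   r = 0.988, p = 0.00152
```

Apparent per-department richness tracks record count closely — the same
effort artefact the national analyses report, here visible by
construction because hotspot departments attract both ranges and records.

`run_pipeline(out_dir, cfg)` runs all stages, writes every output (CSV,
GeoJSON, JSON reports) plus a hash manifest, and is byte-reproducible for
a fixed seed. A thin command-line wrapper lives at
`inst/cli/floragrid.R`.

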