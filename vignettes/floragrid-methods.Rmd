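---
title: "Methods: checklist curation, occurrence cleaning, and gridded endemism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: checklist curation, occurrence cleaning, and gridded endemism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floragrid)
```

## What this package computes

floragrid is a pipeline for national-scale analyses of useful-plant
diversity of the kind carried out for the Colombian edible flora: a curated
species checklist with status flags and neglected-and-underutilized-species
(NUS) categorisation; coordinate-level cleaning of herbarium occurrence
records; species richness (SR), weighted endemism (WE) and corrected
weighted endemism (CWE) on a 0.1° grid; and aggregation of records over
administrative departments and ecological bioregions, including species
breadth distributions and a regression of apparent richness on sampling
effort. Because the compiled national datasets behind such studies are not
redistributable, the package carries a first-class synthetic-data generator
with ground-truth answer keys; every stage is tested against those keys and
against independent oracles.

## Checklist curation

Verbatim taxon names are reconciled against a locally supplied backbone
table (the offline stand-in for a names service) by exact matching after a
conservative normalisation: outer trim, internal whitespace collapse, and
case folding with genus re-capitalisation. Fuzzy or phonetic matching is
deliberately absent — at national scale it silently merges distinct taxa,
which is a worse failure mode than leaving a misspelling unmatched. Two
verbatim names resolving to the same accepted name collapse to one taxon;
backbone rows with conflicting accepted names for one input key are a hard
error rather than a silent first-wins choice.

A species is NUS exactly when its accepted name is absent from the supplied
crop-census list, so NUS and census species partition the catalogue. All
reported percentages use one rounding convention: round half away from
zero to one decimal (`compute_share()`). Published catalogues are not
always consistent with any single convention — e.g. a printed 47.4% whose
numerator/denominator give 47.46% can only arise from truncation — and the
test suite documents such discrepancies rather than mimicking them
case by case.

The growth-habit vocabulary is fixed to five values (tree, shrub, herb,
climber, other); unknown strings map to "other" with a warning, and a
species listed under several habits counts once under each, so habit
tables overlap by design.

## Occurrence cleaning

The cleaning pipeline applies the standard battery of coordinate filters
for herbarium data, in a fixed order: parse, out-of-range, zero
coordinate, equal latitude/longitude, decimal precision, country centroid,
sea, urban centres, institutions; then exact-duplicate collapse. Each
removed record is attributed to the *first* filter it fails, which makes
the per-filter counts exclusive and the report exactly additive:

> n_input = n_output + sum(removals) + n_duplicates_collapsed

Every filter is a pure per-record predicate, so the surviving *set* is
independent of the order; only attribution depends on it. The order itself
is a convention (cheap textual checks before spatial ones) and is asserted
only through attribution tests.

Decisions worth making explicit:

* **Precision is counted on the verbatim coordinate string**, trailing
  zeros included, because occurrence archives ship coordinates as text and
  "4.50" genuinely records two decimals. When only a parsed number is
  available, the shortest round-trip decimal rendering stands in
  (`format_coordinate()`), which is documented as a fallback rather than
  an equivalent. Scientific notation is routed to the unparseable branch.
* **Boundary conventions are asymmetric on purpose**: a point on the
  land-polygon boundary is retained (coastal specimens are legitimate),
  while points on urban-polygon boundaries or exactly at the institution
  buffer distance are removed — conservative toward data quality in both
  directions.
* **Distances are haversine on a sphere of radius 6371.0088 km.** The
  centroid radius (5 km) and institution buffer (100 m) are configuration
  values with defaults, since the filters are standard but published radii
  rarely are. Projection-based buffering is out of scope.
* **The duplicate key is (taxon, latitude, longitude)** — the "unique
  georeferenced record" unit — deliberately excluding collector and date.

## Grid metrics

Cleaned records are binned into a regular lattice (default 0.1°, roughly
10 × 10 km at the equator) anchored at (−180, −90), so cell identities are
stable across datasets rather than dependent on each dataset's extent.
Cells are half-open `[edge, edge + cell)`; because 0.1° is not exactly
representable in binary floating point, the cell index applies a relative
1e−7 epsilon bump so points lying exactly on an edge land in the
higher-index cell as the convention requires. Presence is binary per
(species, cell), making all metrics invariant under record duplication.

With `C_s` the number of occupied cells of species `s` (its range size on
this same grid):

* `SR(cell) = #{s present}`
* `WE(cell) = Σ_{s present} 1 / C_s`
* `CWE(cell) = WE / SR ∈ (0, 1]`

The inverse-range weighting is the standard rarity weighting of the
SDMtoolbox lineage: a single-cell endemic contributes 1 to its cell, a
species spread over 40 cells contributes 0.025 to each. Descriptions of WE
in the applied literature are sometimes garbled into "the sum of the number
of cells each species occupies", which is the reciprocal-free quantity and
contradicts the stated purpose of emphasising restricted ranges; this
package implements the inverse-range form. Two consequences are used as
self-checks everywhere: summed over cells, WE equals the number of gridded
species exactly (each species contributes `C_s · 1/C_s = 1`), and
`WE = SR` in a cell iff all its species are single-cell endemics.

The test suite verifies the whole metric table against a brute-force
oracle in exact rational arithmetic (integer numerators/denominators over
the lcm of range sizes, exact in doubles because range sizes are kept ≤ 40
cells, and lcm(1..40) < 2^53). No equal-area projection is applied; the
0.1° ≈ 10 km equivalence degrades away from the equator and is accepted as
a documented approximation of the cited tooling.

## Regional aggregation

Departments and bioregions are supplied as GeoJSON polygon sets. They must
tile: overlapping interiors are rejected at load. Containment uses an
even-odd ray-casting test with explicit boundary detection; a point on a
shared boundary goes to the alphabetically first containing region — an
arbitrary but stable, documented tie-break. Points in no region are
counted and reported, never silently dropped.

Per-region summaries count records and distinct species, genera and
families; regions with zero records are emitted with zeros, mirroring
published per-department tables where under-collected departments appear
with near-empty rows. Species breadth is the number of distinct regions
holding at least one record, with headline cuts (>20, >30, all regions,
exactly 1, ≤5) as threshold parameters matching the customary reporting
cuts.

The richness-versus-records regression is ordinary least squares of
species count on record count across regions, with the two-sided slope
t-test on n − 2 degrees of freedom. Raw counts are the default — the
published analyses state only "linear regressions" — and a log10 option is
available behind a flag. Tests pin the implementation to a
normal-equations closed form at 1e−10.

## The synthetic-data generator

The generator defines the study conditions for every test; it is not a
tuning knob. Its defaults encode the stylised facts of a national
edible-flora dataset:

* **Status-flag frequencies** default to the reported shares of the
  Colombian catalogue: 73.8% native, 3.8% endemic (drawn only among
  natives, preserving endemic ⇒ native), 11.9% naturalised, 17.4%
  cultivated, 64.6% with local use reports, 3.1% in the global crop
  census.
* **Heavy-tailed record counts**: per-species record counts follow a
  truncated power law (exponent 1.6, max 400), reproducing the situation
  where ten species contribute on the order of a quarter of all records
  while half the flora has ≤20 records. The exponent is configuration,
  since only the stylised fact, not a fitted law, is available.
* **Range-size heterogeneity**: range sizes follow a truncated power law
  (exponent 1.8, max 40 cells) from single-cell endemics to widespread
  species, seeded near a configurable number of hotspot centres with
  probability 0.6 and grown as contiguous patches.
* **Geometry** is an abstract 4° × 4° territory (40 × 40 cells) tiled by
  five department strips and three bioregion strips, with two small urban
  squares, three institution points and a central centroid. Urban squares
  are kept narrower than one grid cell and offset from the lattice so no
  cell is entirely urban and clean in-cell placement always succeeds.
* **Contamination** is injected so each contaminant violates exactly one
  filter (zero coordinate, equal coordinates, two-decimal truncation,
  centroid, sea, urban, institution, exact duplicate), which makes
  per-filter attribution exactly recoverable against the answer key.
  Mixed-violation records are real in GBIF data but would make exact
  attribution untestable, so they are deliberately out of the default
  scenario.

Clean records are rejection-sampled so they pass every filter and remain
in their assigned cell after 5-decimal serialization; coordinates are
emitted as text with five decimals, satisfying the ≥3-decimal precision
rule by construction. Identical seed and configuration produce
byte-identical files (the run manifest records hashes but no timestamps
for the same reason).

What the generator does **not** emulate: climatic/niche structure in
ranges, spatial autocorrelation of sampling effort beyond hotspots,
country-shaped coastlines, mixed-violation contaminants, and taxonomic
error modes other than exact synonyms. Passing tests therefore demonstrate
the correctness of the computations and the audit identities, not the
ecological realism of any particular national dataset.

## Problem sizes and runtime choices

The default scenario uses 300 species (~3000 records) and runs end to end
in a few seconds. Conservation and oracle tests use 200-species 40 × 40
landscapes (50 replicates) and 50-species 100-cell landscapes
respectively; the regression null-calibration check uses 100 seeds at
n = 200. These sizes give the invariants room to fail while keeping the
full suite under a minute of compute for the heavy blocks.

## Known limitations

* Point-in-polygon is planar even-odd on longitude/latitude; polygons
  spanning the antimeridian or poles are unsupported (irrelevant for a
  single-country analysis, fatal for a global one).
* Range size is defined on the analysis grid itself; there is no
  independent range estimate, so WE inherits the grid's sampling biases.
* No sampling-effort correction (rarefaction) of SR is attempted; the
  records-vs-richness regression is the package's way of making that bias
  visible instead of correcting it.
* The overlap check for region sets tests polygon vertices, which is
  sufficient for polygonal tilings of the kind used here but can miss
  pathological overlaps whose intersection contains no vertex of either
  polygon.
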