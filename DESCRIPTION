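Package: floragrid
Title: Checklist Curation, Occurrence Cleaning and Gridded Endemism Metrics
    for Edible-Plant Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the diversity and distribution of a national
    edible-plant flora: curation of a species checklist against a taxonomic
    backbone with neglected-and-underutilized-species (NUS) flagging and
    catalogue summary statistics; coordinate-level cleaning of Darwin-Core
    occurrence records (precision, zero and equal coordinates, country
    centroid, sea, urban-centre and institution filters) with an auditable
    per-filter report; species richness, weighted endemism and corrected
    weighted endemism on a 0.1-degree grid; aggregation of records over
    department and bioregion polygons with breadth distributions and a
    richness-versus-sampling regression; and a seeded synthetic-data
    generator with ground-truth answer keys for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
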