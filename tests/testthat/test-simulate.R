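test_that("checklist generator hits configured frequencies within binomial bounds", {
  cfg <- scenario_config(seed = 31, n_species = 2000)
  sim <- simulate_checklist(cfg)
  n <- 2000
  for (flag in c("native", "naturalised", "cultivated",
                 "locally_reported")) {
    p <- cfg$flag_freqs[[flag]]
    got <- sum(sim$checklist[[flag]])
    expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
  p_end <- cfg$flag_freqs[["endemic"]]
  expect_lt(abs(sum(sim$checklist$endemic) - n * p_end),
            3 * sqrt(n * p_end * (1 - p_end)) + 1)
  expect_true(all(!sim$checklist$endemic | sim$checklist$native))
  # crop_census_fraction = 0: everything NUS, and no synonyms -> no unmatched
  cfg0 <- scenario_config(seed = 32, n_species = 100,
                          crop_census_fraction = 0, synonym_rate = 0)
  sim0 <- simulate_checklist(cfg0)
  expect_true(all(sim0$checklist$is_nus))
  expect_length(reconcile_names(sim0$verbatim_names,
                                sim0$backbone)$unmatched, 0)
  expect_error(scenario_config(n_species = 0))
})

test_that("occurrence generator produces heavy-tailed record counts and honours fixed ranges", {
  cfg <- scenario_config(seed = 41, n_species = 500)
  g <- grid_spec(0.1, origin = c(0, 0), extent = cfg$extent)
  occ <- simulate_occurrences(simulate_checklist(cfg)$checklist, g, cfg)
  counts <- table(occ$occurrences$taxon_id)
  top10 <- sum(sort(counts, decreasing = TRUE)[1:10])
  # top-10 share exceeds the uniform share 10/500
  expect_gt(top10 / sum(counts), 10 / 500)
  # every emitted record passes every record-level filter
  o <- occ$occurrences
  expect_true(all(passes_precision(o$lat_text, o$lon_text, 3)))
  expect_true(all(passes_nonzero(o$lat, o$lon)))
  expect_true(all(passes_equal_coords(o$lat, o$lon)))
})

test_that("realised ranges in the answer key are recovered by the grid", {
  cfg <- scenario_config(seed = 43, n_species = 80)
  g <- grid_spec(0.1, origin = c(0, 0), extent = cfg$extent)
  occ <- simulate_occurrences(simulate_checklist(cfg)$checklist, g, cfg)
  pt <- build_presence(occ$occurrences, g)
  key <- occ$answer_key$range_cells
  for (tid in pt$range_size$taxon_id) {
    expect_equal(
      pt$range_size$range_cells[pt$range_size$taxon_id == tid],
      key[[tid]])
  }
  # occupied cell identities match too
  cells_of <- split(sprintf("%d,%d", pt$presence$cell_i,
                            pt$presence$cell_j), pt$presence$taxon_id)
  for (tid in names(cells_of)) {
    expect_setequal(cells_of[[tid]], occ$answer_key$occupied_cells[[tid]])
  }
})

test_that("one species with a single-cell range places all records in that cell", {
  cfg <- scenario_config(seed = 44, n_species = 1, range_max_cells = 1,
                         records_max = 10, records_exponent = 0.0001,
                         hotspot_share = 0)
  g <- grid_spec(0.1, origin = c(0, 0), extent = cfg$extent)
  occ <- simulate_occurrences(simulate_checklist(cfg)$checklist, g, cfg)
  pt <- build_presence(occ$occurrences, g)
  expect_equal(nrow(pt$range_size), 1)
  expect_equal(pt$range_size$range_cells, 1L)
})

test_that("toy geometry tiles the land exactly and keeps features disjoint", {
  geom <- make_toy_geometry(c(0, 0, 4, 4), n_regions = 5, n_bioregions = 3)
  area <- function(rings) {
    bb <- vapply(rings, function(r) {
      c((max(r[, 1]) - min(r[, 1])) * (max(r[, 2]) - min(r[, 2])))
    }, 0)
    sum(bb)
  }
  dep_area <- sum(vapply(geom$departments$rings, area, 0))
  expect_equal(dep_area, 16)   # area sum equals the land rectangle
  expect_equal(sum(vapply(geom$bioregions$rings, area, 0)), 16)
  # single-region degenerate case: land equals the region
  g1 <- make_toy_geometry(c(0, 0, 2, 2), n_regions = 1, n_bioregions = 1)
  expect_equal(g1$departments$rings[[1]], list(rect_ring(0, 0, 2, 2)))
  # random points never fall in two departments (strict interiors)
  set.seed(5)
  lon <- runif(300, 0.001, 3.999); lat <- runif(300, 0.001, 3.999)
  for (k in seq_len(300)) {
    n_in <- sum(vapply(geom$departments$rings, function(rr)
      point_in_rings(lon[k], lat[k], rr) == "inside", logical(1)))
    expect_lte(n_in, 1)
  }
  # institutions outside urban squares and away from the centroid
  expect_true(all(passes_urban(geom$institutions[, 2],
                               geom$institutions[, 1], geom$urban)))
  expect_true(all(passes_centroid(geom$institutions[, 2],
                                  geom$institutions[, 1],
                                  geom$centroid, 5)))
})

test_that("contamination injection violates exactly one filter per record", {
  cfg <- scenario_config(seed = 51, n_species = 60)
  scen <- simulate_scenario(cfg)
  geom <- scen$geometry
  base <- scen$clean_occurrences
  counts <- c(zero = 20L, equal = 20L, precision = 20L, centroid = 10L,
              sea = 20L, urban = 20L, institution = 10L, duplicate = 15L)
  cont <- inject_contamination(base, geom, cfg, counts = counts)
  expect_equal(nrow(cont$records), nrow(base) + sum(counts))
  # all rates zero leaves the input untouched
  cfg0 <- cfg; cfg0$contamination_rates[] <- 0
  cont0 <- inject_contamination(base, geom, cfg0)
  expect_equal(nrow(cont0$records), nrow(base))
  # run the cleaner: per-filter removals equal the injected counts exactly
  fc <- filter_config(centroid = geom$centroid,
                      institution_points = geom$institutions,
                      urban_polygons = geom$urban,
                      land_polygon = geom$land)
  out <- clean_pipeline(cont$records, fc)
  rem <- out$report$removals
  expect_equal(rem$zero_coordinate, 20)
  expect_equal(rem$equal_coordinates, 20)
  expect_equal(rem$low_precision, 20)
  expect_equal(rem$centroid, 10)
  expect_equal(rem$sea, 20)
  expect_equal(rem$urban, 20)
  expect_equal(rem$institution, 10)
  expect_equal(out$report$n_duplicates_collapsed, 15)
  expect_equal(out$report$n_output, nrow(base))
})

test_that("identical seed and config give byte-identical fixture files", {
  cfg <- scenario_config(seed = 61, n_species = 40)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_scenario(cfg, out_dir = d1)
  simulate_scenario(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_equal(h1, h2)
  # a different seed changes at least the occurrences
  d3 <- withr::local_tempdir()
  simulate_scenario(scenario_config(seed = 62, n_species = 40),
                    out_dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d3, "occurrences.csv"))),
    unname(tools::md5sum(file.path(d1, "occurrences.csv")))))
})
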