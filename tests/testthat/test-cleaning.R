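test_that("decimal places are counted on the verbatim string, trailing zeros included", {
  expect_equal(decimal_places(c("4.523", "4.50", "-74", "0.000", ".52")),
               c(3L, 2L, 0L, 3L, 2L))
  expect_true(is.na(decimal_places("1e-3")))
  expect_true(is.na(decimal_places("four")))
  expect_true(is.na(decimal_places("4.5.2")))
})

test_that("shortest round-trip rendering backs the float-only precision fallback", {
  expect_equal(format_coordinate(c(4.523, -74, 0.5)),
               c("4.523", "-74", "0.5"))
  x <- c(4.123456, -73.25)
  expect_equal(as.numeric(format_coordinate(x)), x)
})

test_that("record-level predicates implement the stated retention rules", {
  expect_true(passes_precision("4.523", "-74.107"))
  expect_false(passes_precision("4.52", "-74.107"))
  expect_true(passes_precision("4.5", "-74", min_decimals = 0))
  expect_false(passes_equal_coords(4.444, 4.444))
  expect_true(passes_equal_coords(4.444, -4.444))
  expect_false(passes_equal_coords(0, 0))
  expect_false(passes_nonzero(0, -73.25))
  expect_false(passes_nonzero(4.6, 0))
  expect_true(passes_nonzero(0.001, -73.25))
})

test_that("centroid filter removes at the haversine radius, verified against an independent haversine", {
  ctr <- c(-73.0, 4.0)
  expect_false(passes_centroid(ctr[2], ctr[1], ctr, 5))
  # 100 km north
  expect_true(passes_centroid(ctr[2] + 0.9, ctr[1], ctr, 5))
  # construct points at ~4.9 and ~5.1 km due north: 1 deg lat = R*pi/180 km
  km_per_deg <- 6371.0088 * pi / 180
  p49 <- ctr[2] + 4.9 / km_per_deg
  p51 <- ctr[2] + 5.1 / km_per_deg
  expect_equal(oracle_haversine_km(ctr[1], p49, ctr[1], ctr[2]), 4.9,
               tolerance = 1e-9)
  expect_false(passes_centroid(p49, ctr[1], ctr, 5))
  expect_true(passes_centroid(p51, ctr[1], ctr, 5))
  # package distance agrees with the oracle on random pairs
  set.seed(1)
  lon <- runif(50, -80, -70); lat <- runif(50, -5, 10)
  expect_equal(haversine_km(lon, lat, ctr[1], ctr[2]),
               vapply(seq_len(50), function(i)
                 oracle_haversine_km(lon[i], lat[i], ctr[1], ctr[2]), 0),
               tolerance = 1e-9)
})

test_that("spatial predicates agree with an even-odd ray-casting oracle and honour boundary rules", {
  land <- list(rect_ring(0, 0, 2, 2))
  set.seed(42)
  lon <- runif(1000, -0.5, 2.5)
  lat <- runif(1000, -0.5, 2.5)
  pkg_on_land <- passes_sea(lat, lon, land)
  oracle <- vapply(seq_along(lon), function(i)
    oracle_point_in_polygon(lon[i], lat[i], land[[1]]), logical(1))
  expect_equal(pkg_on_land, oracle)   # random points never on boundary

  # boundary: retained by the sea filter, removed by the urban filter
  expect_true(passes_sea(0, 1, land))          # on the lat=0 edge
  expect_false(passes_urban(0, 1, land))
  expect_true(passes_urban(5, 5, land))

  # a polygon with a hole: even-odd handles the ring pair
  holed <- list(rect_ring(0, 0, 2, 2), rect_ring(0.5, 0.5, 1.5, 1.5))
  expect_false(passes_sea(1, 1, holed))        # inside the hole = off land
  expect_true(passes_sea(0.25, 0.25, holed))

  # institution buffer: exact coordinates removed, 1 km away retained
  inst <- matrix(c(1.0, 1.0), ncol = 2)
  expect_false(passes_institution(1.0, 1.0, inst, 100))
  expect_true(passes_institution(1.01, 1.0, inst, 100))
  expect_true(all(passes_institution(c(0.2, 1.9), c(0.2, 0.1), NULL, 100)))
})

test_that("invalid geometry fails at configuration, not per record", {
  expect_error(filter_config(urban_polygons = list(matrix(1:4, 2))),
               "invalid urban geometry")
  expect_error(filter_config(min_decimals = -1))
  expect_silent(filter_config(land_polygon = list(rect_ring(0, 0, 1, 1))))
})

test_that("deduplication keeps the first exact (taxon, lat, lon) triple", {
  recs <- tibble::tibble(taxon_id = c("a", "a", "b"),
                         lat = c(1.111, 1.111, 1.111),
                         lon = c(2.222, 2.222, 2.222))
  dd <- deduplicate(recs)
  expect_equal(nrow(dd$records), 2)   # same point, two species: both kept
  expect_equal(dd$n_collapsed, 1)
})

test_that("pipeline attributes each removal to the first failing filter and conserves counts", {
  land <- list(rect_ring(0, 0, 4, 4))
  urban <- list(rect_ring(1, 1, 1.2, 1.2))
  inst <- matrix(c(3, 2), ncol = 2)   # lon 3, lat 2
  cfg <- filter_config(centroid = c(2, 2), land_polygon = land,
                       urban_polygons = urban, institution_points = inst)
  # hand-built 12-row table, one violation of each kind plus survivors
  recs <- tibble::tibble(
    taxon_id = c(sprintf("s%02d", 1:10), "s01", "s12"),
    lat_text = c("0.512",    # 1 ok
                 "abc",      # 2 unparseable
                 "95.123",   # 3 out of range
                 "0.000",    # 4 zero
                 "2.512",    # 5 equal coords
                 "0.51",     # 6 low precision (lat 2 decimals)
                 "2.001",    # 7 centroid (~ at centre)
                 "0.512",    # 8 sea (lon outside land)
                 "1.105",    # 9 urban
                 "2.000",    # 10 institution (exact point)
                 "0.512",    # 11 duplicate of row 1
                 "3.512"),   # 12 ok
    lon_text = c("2.317", "1.000", "1.000", "1.317", "2.512", "1.317",
                 "2.002", "5.317", "1.107", "3.000", "2.317", "0.317"))
  out <- clean_pipeline(recs, cfg)
  rem <- out$report$removals
  expect_equal(rem$unparseable, 1)
  expect_equal(rem$out_of_range, 1)
  expect_equal(rem$zero_coordinate, 1)
  expect_equal(rem$equal_coordinates, 1)
  expect_equal(rem$low_precision, 1)
  expect_equal(rem$centroid, 1)
  expect_equal(rem$sea, 1)
  expect_equal(rem$urban, 1)
  expect_equal(rem$institution, 1)
  expect_equal(out$report$n_duplicates_collapsed, 1)
  expect_equal(out$report$n_output, 2)
  expect_equal(out$report$n_input,
               sum(unlist(rem)) + out$report$n_duplicates_collapsed +
                 out$report$n_output)
  # taxon s05 failed at equal_coordinates even though (2.512, 2.512) is
  # also > 3 decimals from nothing else: attribution is first-fail only
  expect_equal(out$removed$reason[out$removed$taxon_id == "s05"],
               "equal_coordinates")
})

test_that("clean input passes through untouched and the pipeline is idempotent", {
  cfg <- filter_config(centroid = c(2, 2),
                       land_polygon = list(rect_ring(0, 0, 4, 4)))
  recs <- tibble::tibble(taxon_id = c("a", "b"),
                         lat_text = c("0.512", "3.999"),
                         lon_text = c("2.317", "0.812"))
  out <- clean_pipeline(recs, cfg)
  expect_equal(out$report$n_output, 2)
  expect_equal(sum(unlist(out$report$removals)), 0)
  # idempotence: cleaning the cleaned records changes nothing
  again <- clean_pipeline(out$records, cfg)
  expect_equal(again$records, out$records)
  expect_equal(again$report$n_output, out$report$n_output)
  # empty input: zeroed report
  empty <- clean_pipeline(recs[0, ], cfg)
  expect_equal(empty$report$n_input, 0L)
  expect_equal(empty$report$n_output, 0L)
})

test_that("surviving set is invariant under record-level filter order", {
  # each record-level predicate is pure, so survivors must not depend on
  # application order; emulate permuted order by intersecting predicates
  set.seed(7)
  n <- 300
  lat_text <- sprintf("%.3f", runif(n, -5, 5))
  lon_text <- sprintf("%.3f", runif(n, -5, 5))
  lat_text[sample(n, 20)] <- "0.000"
  idx <- sample(n, 20)
  lon_text[idx] <- lat_text[idx]
  lat_text[sample(n, 20)] <- sprintf("%.1f", runif(20, -5, 5))
  lat <- as.numeric(lat_text); lon <- as.numeric(lon_text)
  p1 <- passes_nonzero(lat, lon)
  p2 <- passes_equal_coords(lat, lon)
  p3 <- passes_precision(lat_text, lon_text, 3)
  survivors_any_order <- p1 & p2 & p3
  out <- clean_pipeline(tibble::tibble(taxon_id = as.character(1:n),
                                       lat_text = lat_text,
                                       lon_text = lon_text),
                        filter_config())
  expect_equal(out$report$n_output + out$report$n_duplicates_collapsed,
               sum(survivors_any_order))
})
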