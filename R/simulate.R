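#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator. Defaults emulate the stylised
#' structure of a national edible-flora occurrence dataset: heavy-tailed
#' per-species record counts (a few species dominate total records),
#' range sizes from single-cell endemics to near-country-wide species
#' (truncated power law), spatially clustered hotspots, and contamination
#' of each kind the cleaning filters target. Status-flag frequencies
#' default to the shares reported for the Colombian edible flora (73.8%
#' native, 3.8% endemic, 11.9% naturalised, 17.4% cultivated, 64.6% with
#' local use reports, 3.1% in the global crop census). Coordinates live in
#' an abstract 4 x 4 degree toy territory anchored at the origin, 40 x 40
#' cells at the 0.1-degree default resolution.
#'
#' @param seed Integer seed; identical seed and config give byte-identical
#'   outputs.
#' @param n_species Number of species in the checklist.
#' @param extent Length-4 `(lon_min, lat_min, lon_max, lat_max)` of the toy
#'   territory (also the land polygon).
#' @param cell_size Grid resolution in degrees.
#' @param n_regions,n_bioregions Number of department-like vertical strips
#'   and bioregion-like horizontal strips tiling the territory.
#' @param n_urban,n_institutions Number of urban squares / institution
#'   points in the toy geometry.
#' @param n_hotspots Number of hotspot centres attracting species ranges.
#' @param hotspot_share Probability a species' range seeds near a hotspot
#'   rather than uniformly.
#' @param hotspot_sd_cells Gaussian jitter (in cells) around hotspot
#'   centres.
#' @param range_max_cells,range_exponent Truncated power law on range size:
#'   `P(C) proportional to C^-range_exponent`, `C` in 1..`range_max_cells`.
#' @param records_max,records_exponent Truncated power law on per-species
#'   record counts.
#' @param contamination_rates Named fractions of the clean record count to
#'   inject per violation type; names from `zero`, `equal`, `precision`,
#'   `centroid`, `sea`, `urban`, `institution`, `duplicate`.
#' @param flag_freqs Named frequencies for the checklist status flags.
#' @param habit_freqs Named sampling weights over the habit vocabulary.
#' @param synonym_rate Fraction of species that also get a synonym row in
#'   the backbone (and whose occurrences may cite the synonym).
#' @param crop_census_fraction Fraction of species listed in the crop
#'   census (the non-NUS share).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1,
                            n_species = 300,
                            extent = c(0, 0, 4, 4),
                            cell_size = 0.1,
                            n_regions = 5,
                            n_bioregions = 3,
                            n_urban = 2,
                            n_institutions = 3,
                            n_hotspots = 3,
                            hotspot_share = 0.6,
                            hotspot_sd_cells = 3,
                            range_max_cells = 40,
                            range_exponent = 1.8,
                            records_max = 400,
                            records_exponent = 1.6,
                            contamination_rates = c(
                              zero = 0.01, equal = 0.01, precision = 0.02,
                              centroid = 0.005, sea = 0.01, urban = 0.01,
                              institution = 0.005, duplicate = 0.02),
                            flag_freqs = c(native = 0.738, endemic = 0.038,
                                           naturalised = 0.119,
                                           cultivated = 0.174,
                                           locally_reported = 0.646),
                            habit_freqs = c(tree = 0.35, shrub = 0.2,
                                            herb = 0.3, climber = 0.1,
                                            other = 0.05),
                            synonym_rate = 0.1,
                            crop_census_fraction = 0.031) {
  stopifnot(n_species >= 1, cell_size > 0,
            extent[3] - extent[1] >= cell_size,
            extent[4] - extent[2] >= cell_size,
            all(contamination_rates >= 0), sum(contamination_rates) <= 1,
            all(flag_freqs >= 0 & flag_freqs <= 1),
            synonym_rate >= 0, synonym_rate <= 1,
            crop_census_fraction >= 0, crop_census_fraction <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

# truncated power law on 1..kmax
.rpower <- function(n, kmax, exponent) {
  sample.int(kmax, n, replace = TRUE, prob = (seq_len(kmax))^(-exponent))
}

#' Simulate a curated checklist with backbone and crop census
#'
#' Draws species names from synthetic genus/family pools, status flags at
#' the configured frequencies (endemism only among natives, preserving
#' endemic => native), growth habits, a crop-census subset, and a backbone
#' containing one accepted row per species plus synonym rows for a
#' configured fraction. The answer key records the true synonymy, census
#' membership and realised flag counts.
#'
#' @param config A [scenario_config()].
#' @return List: `checklist` (tibble), `backbone` (tibble), `crops`
#'   (tibble with `accepted_name`), `verbatim_names` (character; accepted
#'   names with synonyms substituted where they exist), `answer_key`.
#' @export
simulate_checklist <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_species
  n_fam <- max(3L, round(n / 15))
  n_gen <- max(5L, round(n / 4))
  families <- sprintf("Famaceae%03d", seq_len(n_fam))
  genera <- sprintf("Genus%03d", seq_len(n_gen))
  genus_family <- sample(families, n_gen, replace = TRUE)
  sp_genus <- sample(seq_len(n_gen), n, replace = TRUE)
  accepted <- sprintf("%s epithet%04d", genera[sp_genus], seq_len(n))
  taxon_id <- sprintf("t%05d", seq_len(n))

  ff <- config$flag_freqs
  native <- stats::runif(n) < ff[["native"]]
  endemic <- native & (stats::runif(n) < ff[["endemic"]] / ff[["native"]])
  naturalised <- !native & (stats::runif(n) <
                              ff[["naturalised"]] / (1 - ff[["native"]]))
  cultivated <- stats::runif(n) < ff[["cultivated"]]
  locally_reported <- stats::runif(n) < ff[["locally_reported"]]

  hf <- config$habit_freqs
  habit1 <- sample(names(hf), n, replace = TRUE, prob = hf)
  habit2 <- sample(names(hf), n, replace = TRUE, prob = hf)
  two <- stats::runif(n) < 0.15 & habit2 != habit1
  growth_habits <- ifelse(two, paste(habit1, habit2, sep = "|"), habit1)

  n_crops <- round(config$crop_census_fraction * n)
  crop_idx <- if (n_crops > 0) sample.int(n, n_crops) else integer()
  in_crop_census <- seq_len(n) %in% crop_idx

  checklist <- tibble::tibble(
    taxon_id = taxon_id, accepted_name = accepted,
    family = genus_family[sp_genus], genus = genera[sp_genus],
    native = native, endemic = endemic, naturalised = naturalised,
    cultivated = cultivated, locally_reported = locally_reported,
    growth_habits = growth_habits, in_crop_census = in_crop_census,
    is_nus = !in_crop_census)

  n_syn <- round(config$synonym_rate * n)
  syn_idx <- if (n_syn > 0) sort(sample.int(n, n_syn)) else integer()
  synonyms <- sprintf("%s synonymum%04d", genera[sp_genus[syn_idx]],
                      syn_idx)
  backbone <- dplyr::bind_rows(
    tibble::tibble(input_name = accepted, accepted_name = accepted,
                   taxon_id = taxon_id, match_status = "accepted"),
    tibble::tibble(input_name = synonyms,
                   accepted_name = accepted[syn_idx],
                   taxon_id = taxon_id[syn_idx],
                   match_status = "synonym"))

  verbatim <- accepted
  verbatim[syn_idx] <- synonyms

  list(
    checklist = checklist,
    backbone = backbone,
    crops = tibble::tibble(accepted_name = accepted[sort(crop_idx)]),
    verbatim_names = verbatim,
    answer_key = list(
      n_species = n,
      n_families = length(unique(genus_family[sp_genus])),
      n_genera = length(unique(sp_genus)),
      flag_counts = list(native = sum(native), endemic = sum(endemic),
                         naturalised = sum(naturalised),
                         cultivated = sum(cultivated),
                         locally_reported = sum(locally_reported)),
      n_in_census = length(crop_idx),
      n_nus = n - length(crop_idx),
      synonym_map = stats::setNames(as.list(accepted[syn_idx]), synonyms)))
}

#' Toy geometry: land, regions, urban squares, institutions, centroid
#'
#' The land polygon is the extent rectangle; departments are equal-width
#' vertical strips and bioregions equal-height horizontal strips, each
#' tiling the land exactly (no gaps or overlaps). Urban squares and
#' institution points are placed at fixed interior positions, mutually
#' disjoint and away from the centroid and the lat = lon diagonal, so every
#' cleaning filter can be violated by exactly one construction.
#'
#' @param extent Length-4 `(lon_min, lat_min, lon_max, lat_max)`.
#' @param n_regions Number of department strips (>= 1).
#' @param n_bioregions Number of bioregion strips (>= 1).
#' @param n_urban Number of urban squares (up to 4 fixed slots).
#' @param n_institutions Number of institution points (up to 4 fixed slots).
#' @return List: `land` (ring list), `departments`, `bioregions` (polygon
#'   tibbles usable with [region_set()]), `urban` (ring list),
#'   `institutions` (matrix lon/lat), `centroid` (lon, lat).
#' @export
make_toy_geometry <- function(extent, n_regions = 5, n_bioregions = 3,
                              n_urban = 2, n_institutions = 3) {
  stopifnot(n_regions >= 1, n_bioregions >= 1)
  x0 <- extent[1]; y0 <- extent[2]; x1 <- extent[3]; y1 <- extent[4]
  w <- x1 - x0; h <- y1 - y0
  land <- list(rect_ring(x0, y0, x1, y1))

  dep_edges <- x0 + w * (0:n_regions) / n_regions
  departments <- tibble::tibble(
    name = sprintf("department_%02d", seq_len(n_regions)),
    kind = "department",
    rings = lapply(seq_len(n_regions), function(i) {
      list(rect_ring(dep_edges[i], y0, dep_edges[i + 1], y1))
    }))
  bio_edges <- y0 + h * (0:n_bioregions) / n_bioregions
  bioregions <- tibble::tibble(
    name = sprintf("bioregion_%02d", seq_len(n_bioregions)),
    kind = "bioregion",
    rings = lapply(seq_len(n_bioregions), function(i) {
      list(rect_ring(x0, bio_edges[i], x1, bio_edges[i + 1]))
    }))

  urban_slots <- list(c(0.30, 0.55), c(0.70, 0.30), c(0.15, 0.80),
                      c(0.85, 0.65))
  stopifnot(n_urban <= length(urban_slots))
  # squares narrower than a 0.1-degree cell (at the default 4 x 4 extent)
  # and offset from the lattice, so no grid cell is ever fully urban and
  # clean in-cell placement always has room
  half <- 0.012 * min(w, h)
  urban <- lapply(urban_slots[seq_len(n_urban)], function(fr) {
    cx <- x0 + fr[1] * w + 0.0041 * w; cy <- y0 + fr[2] * h + 0.0043 * h
    rect_ring(cx - half, cy - half, cx + half, cy + half)
  })

  inst_slots <- list(c(0.125, 0.875), c(0.875, 0.125), c(0.80, 0.925),
                     c(0.06, 0.31))
  stopifnot(n_institutions <= length(inst_slots))
  institutions <- do.call(rbind, lapply(inst_slots[seq_len(n_institutions)],
                                        function(fr) {
    c(x0 + fr[1] * w, y0 + fr[2] * h)
  }))
  colnames(institutions) <- c("lon", "lat")

  list(land = land, departments = departments, bioregions = bioregions,
       urban = urban, institutions = institutions,
       centroid = c(x0 + w / 2, y0 + h / 2))
}

# TRUE for coordinates that are clean under every record-level and spatial
# filter and stable under 5-decimal serialization
.coord_ok <- function(lon, lat, grid, geometry = NULL, config = NULL) {
  rl <- round(lon, 5); rt <- round(lat, 5)
  cs <- grid$cell_size
  same_cell <- .cell_index(rl, grid$origin[1], cs) ==
    .cell_index(lon, grid$origin[1], cs) &
    .cell_index(rt, grid$origin[2], cs) ==
    .cell_index(lat, grid$origin[2], cs)
  on_edge <- function(v) abs(v / cs - round(v / cs)) < 1e-9
  ok <- same_cell & !on_edge(rl) & !on_edge(rt) &
    rl != 0 & rt != 0 & rl != rt
  if (!is.null(geometry)) {
    cfg_radius <- if (is.null(config)) 5 else 5
    ok <- ok &
      passes_centroid(rt, rl, geometry$centroid, cfg_radius) &
      passes_urban(rt, rl, geometry$urban) &
      passes_institution(rt, rl, geometry$institutions, 100)
  }
  ok
}

#' Simulate occurrence records with known ground truth
#'
#' Each species receives a range: a seed cell (near a hotspot with
#' probability `hotspot_share`) grown into a contiguous patch whose size is
#' drawn from the truncated power law on range size. Its record count is
#' drawn from the heavy-tailed records law; when records outnumber range
#' cells every cell receives at least one record (so realised occupancy
#' equals the assigned range), otherwise records occupy a sampled subset.
#' Record positions are uniform within their cell, rejection-sampled so
#' every emitted record passes every cleaning filter and survives
#' 5-decimal serialization in the same cell, and coordinates are serialized
#' with five decimals. The answer key stores realised occupied cells, range
#' sizes, per-record region membership and per-species breadth.
#'
#' @param checklist Output checklist of [simulate_checklist()] (or any
#'   tibble with `taxon_id`, `accepted_name`).
#' @param grid A [grid_spec()] covering the scenario extent.
#' @param config A [scenario_config()].
#' @param geometry Optional [make_toy_geometry()] output; when supplied,
#'   positions additionally avoid urban squares, institution buffers and
#'   the centroid radius.
#' @param verbatim_names Optional character vector aligned with the
#'   checklist rows; used as the emitted `scientificName` (synonym
#'   spellings exercise reconciliation downstream).
#' @return List: `occurrences` (tibble `source_id`, `scientificName`,
#'   `taxon_id`, `lon_text`, `lat_text`, `lon`, `lat`) and `answer_key`
#'   (realised cells, `range_cells`, `breadth`, `region_of_record`).
#' @export
simulate_occurrences <- function(checklist, grid, config, geometry = NULL,
                                 verbatim_names = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(grid, "grid_spec"))
  set.seed(config$seed + 10L)
  n <- nrow(checklist)
  ext <- grid$extent
  cs <- grid$cell_size
  ni <- floor((ext[3] - ext[1]) / cs + 1e-9)
  nj <- floor((ext[4] - ext[2]) / cs + 1e-9)
  i0 <- .cell_index(ext[1], grid$origin[1], cs)
  j0 <- .cell_index(ext[2], grid$origin[2], cs)
  if (ni < 1 || nj < 1) stop("extent smaller than one cell", call. = FALSE)

  hot <- cbind(sample.int(ni, config$n_hotspots, replace = TRUE) - 1L,
               sample.int(nj, config$n_hotspots, replace = TRUE) - 1L)

  range_sizes <- .rpower(n, min(config$range_max_cells, ni * nj),
                         config$range_exponent)
  rec_counts <- .rpower(n, config$records_max, config$records_exponent)

  grow_range <- function(size) {
    if (stats::runif(1) < config$hotspot_share) {
      ctr <- hot[sample.int(nrow(hot), 1), ]
      seed_cell <- c(
        min(max(ctr[1] + round(stats::rnorm(1, 0, config$hotspot_sd_cells)),
                0), ni - 1),
        min(max(ctr[2] + round(stats::rnorm(1, 0, config$hotspot_sd_cells)),
                0), nj - 1))
    } else {
      seed_cell <- c(sample.int(ni, 1) - 1L, sample.int(nj, 1) - 1L)
    }
    cells <- matrix(seed_cell, ncol = 2)
    while (nrow(cells) < size) {
      base <- cells[sample.int(nrow(cells), 1), ]
      step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[
        sample.int(4, 1), ]
      cand <- base + step
      if (cand[1] < 0 || cand[1] >= ni || cand[2] < 0 || cand[2] >= nj)
        next
      if (!any(cells[, 1] == cand[1] & cells[, 2] == cand[2])) {
        cells <- rbind(cells, cand)
      }
    }
    cells
  }

  used_keys <- new.env(hash = TRUE, parent = emptyenv())
  rows <- vector("list", n)
  key_cells <- vector("list", n)
  for (s in seq_len(n)) {
    cells <- grow_range(range_sizes[s])
    k <- rec_counts[s]
    C <- nrow(cells)
    if (k >= C) {
      pick <- c(seq_len(C), sample.int(C, k - C, replace = TRUE))
    } else {
      pick <- sample.int(C, k)
    }
    cell_of_rec <- cells[pick, , drop = FALSE]
    lon <- ext[1] + (cell_of_rec[, 1] + stats::runif(k)) * cs
    lat <- ext[2] + (cell_of_rec[, 2] + stats::runif(k)) * cs
    for (tries in 1:200) {
      ok <- .coord_ok(lon, lat, grid, geometry, config)
      if (length(ok)) {
        keys <- paste0(sprintf("%.5f", lon), "_", sprintf("%.5f", lat))
        ok <- ok & !vapply(keys, exists, logical(1), envir = used_keys)
        ok <- ok & !duplicated(keys)
      }
      if (all(ok)) break
      redo <- which(!ok)
      lon[redo] <- ext[1] +
        (cell_of_rec[redo, 1] + stats::runif(length(redo))) * cs
      lat[redo] <- ext[2] +
        (cell_of_rec[redo, 2] + stats::runif(length(redo))) * cs
    }
    if (!all(ok)) stop("could not place clean records", call. = FALSE)
    for (kk in paste0(sprintf("%.5f", lon), "_", sprintf("%.5f", lat))) {
      assign(kk, TRUE, envir = used_keys)
    }
    lon <- round(lon, 5); lat <- round(lat, 5)
    nm <- if (is.null(verbatim_names)) checklist$accepted_name[s] else
      verbatim_names[s]
    rows[[s]] <- tibble::tibble(
      scientificName = nm, taxon_id = checklist$taxon_id[s],
      lon = lon, lat = lat,
      lon_text = sprintf("%.5f", lon), lat_text = sprintf("%.5f", lat))
    occ_cells <- unique(cell_of_rec[, , drop = FALSE])
    key_cells[[s]] <- occ_cells
  }
  occ <- dplyr::bind_rows(rows)
  occ$source_id <- sprintf("r%06d", seq_len(nrow(occ)))

  realized <- lapply(key_cells, function(m) {
    m <- unique(m)
    sprintf("%d,%d", m[, 1] + i0, m[, 2] + j0)
  })
  names(realized) <- checklist$taxon_id

  region_of <- NULL
  breadth <- NULL
  if (!is.null(geometry)) {
    dep <- region_set(geometry$departments)
    region_of <- assign_region(occ$lon, occ$lat, dep)
    bt <- tibble::tibble(taxon_id = occ$taxon_id, region = region_of) |>
      dplyr::distinct() |>
      dplyr::count(.data$taxon_id, name = "breadth")
    breadth <- stats::setNames(as.list(bt$breadth), bt$taxon_id)
  }

  list(occurrences = occ,
       answer_key = list(
         range_cells = stats::setNames(
           as.list(vapply(realized, length, 0L)), names(realized)),
         occupied_cells = realized,
         n_records = nrow(occ),
         region_of_record = region_of,
         breadth = breadth))
}

#' Inject filter-violating contamination into a clean record set
#'
#' Appends records that each violate exactly one cleaning filter — zero
#' coordinate, equal coordinates, sub-threshold decimal precision, country
#' centroid, sea, urban centre, institution, or exact duplication — at the
#' configured rates (or explicit per-type counts). Violations are disjoint
#' by construction: each contaminant passes every other filter, so the
#' cleaning report's per-filter counts must equal the injected counts
#' exactly. The answer key labels every injected row.
#'
#' @param records Clean occurrence tibble from [simulate_occurrences()].
#' @param geometry [make_toy_geometry()] output used for placement.
#' @param config A [scenario_config()]; `contamination_rates` set the
#'   per-type counts as `round(rate * nrow(records))`.
#' @param counts Optional named integer vector overriding the rates with
#'   absolute per-type counts.
#' @return List: `records` (input plus injected rows appended) and
#'   `answer_key` (tibble `source_id`, `violation`; plus per-type counts).
#' @export
inject_contamination <- function(records, geometry, config,
                                 counts = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 20L)
  n0 <- nrow(records)
  if (is.null(counts)) {
    counts <- round(config$contamination_rates * n0)
  }
  types <- c("zero", "equal", "precision", "centroid", "sea", "urban",
             "institution", "duplicate")
  counts <- counts[intersect(types, names(counts))]
  ext <- c(.ring_bbox(geometry$land))
  x0 <- ext[1]; y0 <- ext[2]; x1 <- ext[3]; y1 <- ext[4]
  ctr <- geometry$centroid

  # draw interior points clean under all filters except the targeted one
  draw_clean <- function(m, avoid_diag = TRUE) {
    lon <- numeric(0); lat <- numeric(0)
    while (length(lon) < m) {
      need <- m - length(lon)
      cl <- round(stats::runif(need, x0, x1), 5)
      ct <- round(stats::runif(need, y0, y1), 5)
      ok <- cl > x0 & cl < x1 & ct > y0 & ct < y1 &
        cl != 0 & ct != 0 &
        passes_centroid(ct, cl, ctr, 5) &
        passes_urban(ct, cl, geometry$urban) &
        passes_institution(ct, cl, geometry$institutions, 100)
      if (avoid_diag) ok <- ok & (cl != ct)
      lon <- c(lon, cl[ok]); lat <- c(lat, ct[ok])
    }
    list(lon = lon[seq_len(m)], lat = lat[seq_len(m)])
  }
  fmt5 <- function(x) sprintf("%.5f", x)

  out <- list(); labels <- list()
  add <- function(type, lon_text, lat_text, lon, lat) {
    m <- length(lon_text)
    if (m == 0) return(invisible())
    tb <- tibble::tibble(
      scientificName = sample(records$scientificName, m, replace = TRUE),
      taxon_id = NA_character_,
      lon = lon, lat = lat, lon_text = lon_text, lat_text = lat_text,
      source_id = sprintf("contam_%s_%04d", type, seq_len(m)))
    tb$taxon_id <- records$taxon_id[match(tb$scientificName,
                                          records$scientificName)]
    out[[type]] <<- tb
    labels[[type]] <<- tibble::tibble(source_id = tb$source_id,
                                      violation = type)
  }

  if (!is.na(counts["zero"]) && counts["zero"] > 0) {
    p <- draw_clean(counts[["zero"]])
    add("zero", fmt5(p$lon), fmt5(rep(0, counts[["zero"]])),
        p$lon, rep(0, counts[["zero"]]))
  }
  if (!is.na(counts["equal"]) && counts["equal"] > 0) {
    lo <- max(x0, y0); hi <- min(x1, y1)
    if (hi <= lo) stop("extent does not admit equal-coordinate points",
                       call. = FALSE)
    v <- numeric(0)
    while (length(v) < counts[["equal"]]) {
      cand <- round(stats::runif(counts[["equal"]], lo, hi), 5)
      ok <- cand > lo & cand < hi & cand != 0 &
        passes_centroid(cand, cand, ctr, 5) &
        passes_urban(cand, cand, geometry$urban) &
        passes_institution(cand, cand, geometry$institutions, 100)
      v <- c(v, cand[ok])
    }
    v <- v[seq_len(counts[["equal"]])]
    add("equal", fmt5(v), fmt5(v), v, v)
  }
  if (!is.na(counts["precision"]) && counts["precision"] > 0) {
    p <- draw_clean(counts[["precision"]])
    lon2 <- round(p$lon, 2); lat2 <- round(p$lat, 2)
    # re-check cleanliness at the truncated position
    ok <- lon2 > x0 & lon2 < x1 & lat2 > y0 & lat2 < y1 &
      lon2 != 0 & lat2 != 0 & lon2 != lat2 &
      passes_centroid(lat2, lon2, ctr, 5) &
      passes_urban(lat2, lon2, geometry$urban) &
      passes_institution(lat2, lon2, geometry$institutions, 100)
    while (!all(ok)) {
      q <- draw_clean(sum(!ok))
      lon2[!ok] <- round(q$lon, 2); lat2[!ok] <- round(q$lat, 2)
      ok <- lon2 > x0 & lon2 < x1 & lat2 > y0 & lat2 < y1 &
        lon2 != 0 & lat2 != 0 & lon2 != lat2 &
        passes_centroid(lat2, lon2, ctr, 5) &
        passes_urban(lat2, lon2, geometry$urban) &
        passes_institution(lat2, lon2, geometry$institutions, 100)
    }
    add("precision", sprintf("%.2f", lon2), sprintf("%.2f", lat2),
        lon2, lat2)
  }
  if (!is.na(counts["centroid"]) && counts["centroid"] > 0) {
    m <- counts[["centroid"]]
    lon <- lat <- numeric(0)
    while (length(lon) < m) {
      need <- m - length(lon)
      ang <- stats::runif(need, 0, 2 * pi)
      rr <- stats::runif(need, 0, 0.03)   # degrees; well within 5 km
      cl <- round(ctr[1] + rr * cos(ang), 5)
      ct <- round(ctr[2] + rr * sin(ang), 5)
      ok <- !passes_centroid(ct, cl, ctr, 5) & cl != ct & cl != 0 &
        ct != 0 &
        passes_urban(ct, cl, geometry$urban) &
        passes_institution(ct, cl, geometry$institutions, 100)
      lon <- c(lon, cl[ok]); lat <- c(lat, ct[ok])
    }
    add("centroid", fmt5(lon[1:m]), fmt5(lat[1:m]), lon[1:m], lat[1:m])
  }
  if (!is.na(counts["sea"]) && counts["sea"] > 0) {
    m <- counts[["sea"]]
    lon <- round(stats::runif(m, x1 + 0.2, x1 + 1.0), 5)
    lat <- round(stats::runif(m, y0 + 0.1, y1 - 0.1), 5)
    lat[lat == 0] <- 0.123
    eq <- lon == lat
    lon[eq] <- lon[eq] + 0.011
    add("sea", fmt5(lon), fmt5(lat), lon, lat)
  }
  if (!is.na(counts["urban"]) && counts["urban"] > 0) {
    m <- counts[["urban"]]
    lon <- lat <- numeric(0)
    while (length(lon) < m) {
      need <- m - length(lon)
      ring <- geometry$urban[[sample.int(length(geometry$urban), 1)]]
      bb <- .ring_bbox(list(ring))
      cl <- round(stats::runif(need, bb[1], bb[3]), 5)
      ct <- round(stats::runif(need, bb[2], bb[4]), 5)
      ok <- !passes_urban(ct, cl, geometry$urban) & cl != ct &
        cl != 0 & ct != 0 &
        passes_centroid(ct, cl, ctr, 5) &
        passes_institution(ct, cl, geometry$institutions, 100)
      lon <- c(lon, cl[ok]); lat <- c(lat, ct[ok])
    }
    add("urban", fmt5(lon[1:m]), fmt5(lat[1:m]), lon[1:m], lat[1:m])
  }
  if (!is.na(counts["institution"]) && counts["institution"] > 0) {
    m <- counts[["institution"]]
    idx <- sample.int(nrow(geometry$institutions), m, replace = TRUE)
    lon <- round(geometry$institutions[idx, 1], 5)
    lat <- round(geometry$institutions[idx, 2], 5)
    add("institution", fmt5(lon), fmt5(lat), lon, lat)
  }
  if (!is.na(counts["duplicate"]) && counts["duplicate"] > 0) {
    m <- counts[["duplicate"]]
    src <- records[sample.int(n0, m, replace = FALSE), ]
    tb <- src
    tb$source_id <- sprintf("contam_duplicate_%04d", seq_len(m))
    out[["duplicate"]] <- tb
    labels[["duplicate"]] <- tibble::tibble(source_id = tb$source_id,
                                            violation = "duplicate")
  }

  contaminated <- dplyr::bind_rows(c(list(records), out))
  key <- dplyr::bind_rows(labels)
  list(records = contaminated,
       answer_key = list(
         labels = key,
         counts = as.list(stats::setNames(as.integer(counts),
                                          names(counts)))))
}

#' Simulate a full scenario and write its fixture files
#'
#' Orchestrates [simulate_checklist()], [make_toy_geometry()],
#' [simulate_occurrences()] and [inject_contamination()], writing
#' `checklist.csv`, `backbone.csv`, `crops.csv`, `occurrences.csv` (Darwin
#' Core columns, coordinates as text), `geometry/*.geojson` and
#' `answer_key.json` under `out_dir`. Identical seed and config give
#' byte-identical files.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return List with all in-memory pieces: `checklist`, `backbone`,
#'   `crops`, `geometry`, `occurrences` (contaminated), `clean_occurrences`,
#'   `answer_key`, `grid`.
#' @export
simulate_scenario <- function(config = scenario_config(), out_dir = NULL) {
  chk <- simulate_checklist(config)
  geom <- make_toy_geometry(config$extent, config$n_regions,
                            config$n_bioregions, config$n_urban,
                            config$n_institutions)
  grid <- grid_spec(config$cell_size, origin = c(-180, -90),
                    extent = config$extent)
  occ <- simulate_occurrences(chk$checklist, grid, config, geometry = geom,
                              verbatim_names = chk$verbatim_names)
  cont <- inject_contamination(occ$occurrences, geom, config)
  answer_key <- c(chk$answer_key, occ$answer_key,
                  list(contamination = cont$answer_key))

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "geometry"), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_csv(chk$checklist, file.path(out_dir, "checklist.csv"),
                     progress = FALSE)
    readr::write_csv(chk$backbone, file.path(out_dir, "backbone.csv"),
                     progress = FALSE)
    readr::write_csv(chk$crops, file.path(out_dir, "crops.csv"),
                     progress = FALSE)
    occ_out <- tibble::tibble(
      source_id = cont$records$source_id,
      scientificName = cont$records$scientificName,
      decimalLatitude = cont$records$lat_text,
      decimalLongitude = cont$records$lon_text)
    readr::write_csv(occ_out, file.path(out_dir, "occurrences.csv"),
                     progress = FALSE)
    gdir <- file.path(out_dir, "geometry")
    write_geojson(file.path(gdir, "land.geojson"),
                  polygons = tibble::tibble(name = "land", kind = "land",
                                            rings = list(geom$land)))
    write_geojson(file.path(gdir, "regions.geojson"),
                  polygons = dplyr::bind_rows(geom$departments,
                                              geom$bioregions))
    write_geojson(file.path(gdir, "urban.geojson"),
                  polygons = tibble::tibble(
                    name = sprintf("urban_%02d", seq_along(geom$urban)),
                    kind = "urban",
                    rings = lapply(geom$urban, list)))
    write_geojson(file.path(gdir, "institutions.geojson"),
                  points = tibble::tibble(
                    name = sprintf("institution_%02d",
                                   seq_len(nrow(geom$institutions))),
                    kind = "institution",
                    lon = geom$institutions[, 1],
                    lat = geom$institutions[, 2]))
    jsonlite::write_json(
      c(answer_key["range_cells"], answer_key["breadth"],
        list(n_records_clean = answer_key$n_records,
             contamination_counts = answer_key$contamination$counts,
             n_species = answer_key$n_species,
             n_nus = answer_key$n_nus,
             n_in_census = answer_key$n_in_census)),
      file.path(out_dir, "answer_key.json"), auto_unbox = TRUE,
      digits = NA)
  }
  list(checklist = chk$checklist, backbone = chk$backbone,
       crops = chk$crops, verbatim_names = chk$verbatim_names,
       geometry = geom, grid = grid,
       occurrences = cont$records,
       clean_occurrences = occ$occurrences,
       answer_key = answer_key)
}
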