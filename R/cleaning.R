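#' Count decimal places in a verbatim coordinate string
#'
#' Counts digits after the decimal point in the source text, trailing zeros
#' included ("4.50" has two). Occurrence archives ship coordinates as text,
#' and the recorded precision lives in that text, so precision filtering is
#' done on the verbatim string wherever available. Scientific notation and
#' non-numeric text return `NA` (unparseable; such records are removed and
#' counted separately by the pipeline).
#'
#' @param text Character vector of coordinate strings.
#' @return Integer vector: decimal digit count, or `NA` where the text does
#'   not parse as a plain decimal number.
#' @export
#' @examples
#' decimal_places(c("4.523", "4.50", "-74", "1e-3"))
decimal_places <- function(text) {
  text <- trimws(text)
  ok <- grepl("^[+-]?([0-9]+(\\.[0-9]*)?|\\.[0-9]+)$", text)
  out <- rep(NA_integer_, length(text))
  frac <- sub("^[+-]?[0-9]*", "", text[ok])   # ".523" or ""
  out[ok] <- ifelse(frac == "", 0L, nchar(frac) - 1L)
  out
}

#' Shortest round-trip decimal rendering of a parsed coordinate
#'
#' Fallback for inputs where only a numeric coordinate is available: the
#' shortest decimal string that round-trips to the same double, whose
#' decimal places then stand in for the verbatim count.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_coordinate <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    for (d in 0:17) {
      s <- formatC(v, format = "f", digits = d)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, format = "f", digits = 17)
  }, character(1))
}

#' Cleaning-filter configuration
#'
#' Bundles the tunable parameters of the occurrence-cleaning pipeline.
#' Radii and buffers must be non-negative; geometries are validated here,
#' once, rather than per record.
#'
#' @param min_decimals Minimum decimal places required of both coordinates
#'   (default 3, i.e. coordinates recorded to better than ~100 m in text).
#' @param centroid Length-2 numeric `(lon, lat)` of the country centroid,
#'   or `NULL` to disable the centroid filter.
#' @param centroid_radius_km Removal radius around the centroid, km.
#' @param institution_points Two-column matrix or data.frame `(lon, lat)` of
#'   institution locations (botanic gardens, ex-situ repositories), or
#'   `NULL`.
#' @param institution_buffer_m Removal radius around institutions, metres.
#' @param urban_polygons List of rings (see [point_in_rings()]) for urban
#'   centres, or `NULL`.
#' @param land_polygon List of rings for the land mass, or `NULL` to disable
#'   the sea filter.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_decimals = 3,
                          centroid = NULL,
                          centroid_radius_km = 5,
                          institution_points = NULL,
                          institution_buffer_m = 100,
                          urban_polygons = NULL,
                          land_polygon = NULL) {
  stopifnot(min_decimals >= 0, centroid_radius_km >= 0,
            institution_buffer_m >= 0)
  if (!is.null(centroid)) stopifnot(length(centroid) == 2)
  if (!is.null(institution_points)) {
    institution_points <- as.matrix(institution_points)
    stopifnot(ncol(institution_points) == 2)
  }
  check_rings <- function(rings, what) {
    if (is.null(rings)) return(invisible())
    if (!is.list(rings) || !length(rings) ||
        !all(vapply(rings, function(r) is.matrix(r) && ncol(r) == 2 &&
                      nrow(r) >= 4, logical(1)))) {
      stop("invalid ", what, " geometry: expected a non-empty list of ",
           "closed rings (n x 2 matrices)", call. = FALSE)
    }
  }
  check_rings(urban_polygons, "urban")
  check_rings(land_polygon, "land")
  structure(list(min_decimals = min_decimals,
                 centroid = centroid,
                 centroid_radius_km = centroid_radius_km,
                 institution_points = institution_points,
                 institution_buffer_m = institution_buffer_m,
                 urban_polygons = urban_polygons,
                 land_polygon = land_polygon),
            class = "filter_config")
}

#' Record-level cleaning predicates
#'
#' Pure per-record predicates, `TRUE` meaning the record is retained:
#' \describe{
#'   \item{`passes_precision`}{both verbatim coordinates have at least
#'     `min_decimals` decimal places;}
#'   \item{`passes_equal_coords`}{parsed latitude and longitude are not
#'     exactly equal (a classic transposition/typo signature);}
#'   \item{`passes_nonzero`}{neither coordinate is exactly zero;}
#'   \item{`passes_centroid`}{the point is farther than `radius_km` from the
#'     country centroid (haversine).}
#' }
#'
#' @param lat_text,lon_text Verbatim coordinate strings.
#' @param min_decimals Minimum required decimal places.
#' @return Logical vector.
#' @export
passes_precision <- function(lat_text, lon_text, min_decimals = 3) {
  dl <- decimal_places(lat_text)
  dn <- decimal_places(lon_text)
  !is.na(dl) & !is.na(dn) & dl >= min_decimals & dn >= min_decimals
}

#' @rdname passes_precision
#' @param lat,lon Parsed coordinates, decimal degrees.
#' @export
passes_equal_coords <- function(lat, lon) !(lat == lon)

#' @rdname passes_precision
#' @export
passes_nonzero <- function(lat, lon) !(lat == 0 | lon == 0)

#' @rdname passes_precision
#' @param centroid Length-2 `(lon, lat)`.
#' @param radius_km Removal radius, km.
#' @export
passes_centroid <- function(lat, lon, centroid, radius_km = 5) {
  haversine_km(lon, lat, centroid[1], centroid[2]) > radius_km
}

#' Spatial cleaning predicates
#'
#' `TRUE` means retained. Boundary conventions are deliberate and
#' asymmetric, conservative toward data quality in both directions:
#' a point on the land-polygon boundary counts as on land (retained by the
#' sea filter); a point on an urban-polygon boundary counts as urban
#' (removed); a point exactly at `buffer_m` from an institution is removed.
#'
#' @param lat,lon Parsed coordinates.
#' @param land_polygon,urban_polygons Ring lists (see [point_in_rings()]).
#' @param institution_points Two-column `(lon, lat)` matrix.
#' @param buffer_m Institution buffer, metres.
#' @return Logical vector.
#' @export
passes_sea <- function(lat, lon, land_polygon) {
  points_in_rings(lon, lat, land_polygon, boundary_inside = TRUE)
}

#' @rdname passes_sea
#' @export
passes_urban <- function(lat, lon, urban_polygons) {
  !points_in_rings(lon, lat, urban_polygons, boundary_inside = TRUE)
}

#' @rdname passes_sea
#' @export
passes_institution <- function(lat, lon, institution_points,
                               buffer_m = 100) {
  if (is.null(institution_points) || nrow(institution_points) == 0) {
    return(rep(TRUE, length(lat)))
  }
  mind <- rep(Inf, length(lat))
  for (i in seq_len(nrow(institution_points))) {
    d <- haversine_km(lon, lat,
                      institution_points[i, 1], institution_points[i, 2])
    mind <- pmin(mind, d)
  }
  mind * 1000 > buffer_m
}

#' Collapse exact duplicate records
#'
#' One record is kept per exact `(taxon_id, lat, lon)` triple — the
#' "unique georeferenced record" unit — keeping the first in input order.
#' Collection date and collector are deliberately not part of the key.
#'
#' @param records Tibble with columns `taxon_id`, `lat`, `lon`.
#' @return List `records` (deduplicated tibble) and `n_collapsed`.
#' @export
deduplicate <- function(records) {
  key <- paste(records$taxon_id, records$lat, records$lon, sep = "\r")
  keep <- !duplicated(key)
  list(records = records[keep, ], n_collapsed = sum(!keep))
}

.filter_names <- c("unparseable", "out_of_range", "zero_coordinate",
                   "equal_coordinates", "low_precision", "centroid", "sea",
                   "urban", "institution")

#' Run the occurrence-cleaning pipeline
#'
#' Applies the cleaning filters in a fixed order — parse, zero coordinate,
#' equal coordinates, decimal precision, country centroid, sea, urban
#' centres, institutions — then collapses exact duplicates. Each removed
#' record is attributed to the *first* filter it fails, so per-filter counts
#' in the report are exclusive and sum with the survivor and duplicate
#' counts back to the input count. Because every filter is a pure per-record
#' predicate, the surviving *set* does not depend on this order; only the
#' attribution does.
#'
#' @param records Tibble of raw occurrences with columns `taxon_id` (or
#'   `taxon_name`), `lat_text`, `lon_text` (verbatim strings; if absent they
#'   are derived from numeric `lat`/`lon` via [format_coordinate()]).
#' @param config A [filter_config()].
#' @return List of class `cleaning_result`: `records` (clean tibble with
#'   `taxon_id`, `lon`, `lat`), `report` (list: `n_input`, `removals` named
#'   by filter, `n_duplicates_collapsed`, `n_output`), and `removed`
#'   (tibble of removed rows with a `reason` column, for auditing).
#' @export
clean_pipeline <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  records <- tibble::as_tibble(records)
  if (!"taxon_id" %in% colnames(records)) {
    if ("taxon_name" %in% colnames(records)) {
      records$taxon_id <- records$taxon_name
    } else stop("records need a taxon_id or taxon_name column",
                call. = FALSE)
  }
  if (!"lat_text" %in% colnames(records)) {
    records$lat_text <- format_coordinate(records$lat)
  }
  if (!"lon_text" %in% colnames(records)) {
    records$lon_text <- format_coordinate(records$lon)
  }
  n_input <- nrow(records)
  removals <- stats::setNames(integer(length(.filter_names)), .filter_names)
  if (n_input == 0) {
    return(structure(list(
      records = tibble::tibble(taxon_id = character(), lon = numeric(),
                               lat = numeric()),
      report = list(n_input = 0L, removals = as.list(removals),
                    n_duplicates_collapsed = 0L, n_output = 0L),
      removed = tibble::tibble()), class = "cleaning_result"))
  }

  lat <- suppressWarnings(as.numeric(records$lat_text))
  lon <- suppressWarnings(as.numeric(records$lon_text))
  parseable <- !is.na(decimal_places(records$lat_text)) &
    !is.na(decimal_places(records$lon_text)) &
    !is.na(lat) & !is.na(lon)
  in_range <- !is.na(lat) & !is.na(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  records$lat <- lat
  records$lon <- lon

  reason <- rep(NA_character_, n_input)
  alive <- parseable
  reason[!alive] <- "unparseable"
  oob <- alive & !in_range
  reason[oob] <- "out_of_range"
  alive[oob] <- FALSE

  # predicates are evaluated only on still-alive rows so removed rows
  # (e.g. out-of-range latitudes) never reach the spatial backends
  apply_filter <- function(name, predicate) {
    idx <- which(alive)
    if (!length(idx)) return(invisible())
    pass <- predicate(idx)
    fail <- idx[!pass]
    reason[fail] <<- name
    alive[fail] <<- FALSE
  }
  apply_filter("zero_coordinate",
               function(i) passes_nonzero(lat[i], lon[i]))
  apply_filter("equal_coordinates",
               function(i) passes_equal_coords(lat[i], lon[i]))
  apply_filter("low_precision",
               function(i) passes_precision(records$lat_text[i],
                                            records$lon_text[i],
                                            config$min_decimals))
  if (!is.null(config$centroid)) {
    apply_filter("centroid",
                 function(i) passes_centroid(lat[i], lon[i],
                                             config$centroid,
                                             config$centroid_radius_km))
  }
  if (!is.null(config$land_polygon)) {
    apply_filter("sea",
                 function(i) passes_sea(lat[i], lon[i],
                                        config$land_polygon))
  }
  if (!is.null(config$urban_polygons)) {
    apply_filter("urban",
                 function(i) passes_urban(lat[i], lon[i],
                                          config$urban_polygons))
  }
  if (!is.null(config$institution_points)) {
    apply_filter("institution",
                 function(i) passes_institution(
                   lat[i], lon[i], config$institution_points,
                   config$institution_buffer_m))
  }

  tab <- table(factor(reason[!alive], levels = .filter_names))
  removals[] <- as.integer(tab)

  survivors <- records[alive, c("taxon_id", "lon", "lat")]
  dd <- deduplicate(survivors)
  report <- list(n_input = n_input,
                 removals = as.list(removals),
                 n_duplicates_collapsed = dd$n_collapsed,
                 n_output = nrow(dd$records))
  stopifnot(report$n_input - sum(removals) - report$n_duplicates_collapsed
            == report$n_output)
  structure(list(records = dd$records, report = report,
                 removed = cbind(records[!alive, ],
                                 reason = reason[!alive])),
            class = "cleaning_result")
}

#' @export
print.cleaning_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Occurrence cleaning: %d records in, %d out\n",
              r$n_input, r$n_output))
  for (nm in names(r$removals)) {
    if (r$removals[[nm]] > 0)
      cat(sprintf("  removed (%s): %d\n", nm, r$removals[[nm]]))
  }
  cat(sprintf("  duplicates collapsed: %d\n", r$n_duplicates_collapsed))
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param result A `cleaning_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(result, path) {
  stopifnot(inherits(result, "cleaning_result"))
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
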