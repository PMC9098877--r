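#' Load a region set from GeoJSON
#'
#' Reads a FeatureCollection of named polygons (departments or bioregions).
#' Region names must be unique; overlapping region interiors are a hard
#' error at load time, because analysis units must tile the territory. The
#' overlap check tests every polygon vertex of each region for strict
#' containment in every other bbox-overlapping region.
#'
#' @param path GeoJSON path, or a polygons tibble as returned by
#'   [read_geojson()].
#' @param kind Optional filter on the features' `kind` property
#'   (`"department"` / `"bioregion"`).
#' @return A list of class `region_set`: tibble `regions` (`name`, `kind`,
#'   list-column `rings`) sorted alphabetically by name.
#' @export
region_set <- function(path, kind = NULL) {
  polys <- if (is.character(path)) read_geojson(path)$polygons else path
  if (!is.null(kind)) polys <- polys[polys$kind %in% kind, ]
  if (nrow(polys) == 0) stop("no region polygons found", call. = FALSE)
  if (anyDuplicated(polys$name)) {
    stop("duplicate region names: ",
         paste(unique(polys$name[duplicated(polys$name)]), collapse = ", "),
         call. = FALSE)
  }
  polys <- polys[order(polys$name), ]
  .check_region_overlap(polys)
  structure(list(regions = polys), class = "region_set")
}

.ring_bbox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}

.check_region_overlap <- function(polys) {
  n <- nrow(polys)
  if (n < 2) return(invisible())
  bb <- lapply(polys$rings, .ring_bbox)
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      ba <- bb[[a]]; bbx <- bb[[b]]
      if (ba[1] >= bbx[3] || bbx[1] >= ba[3] ||
          ba[2] >= bbx[4] || bbx[2] >= ba[4]) next
      verts_b <- do.call(rbind, polys$rings[[b]])
      for (k in seq_len(nrow(verts_b))) {
        if (point_in_rings(verts_b[k, 1], verts_b[k, 2],
                           polys$rings[[a]]) == "inside") {
          stop("region interiors overlap: ", polys$name[a], " / ",
               polys$name[b], call. = FALSE)
        }
      }
      verts_a <- do.call(rbind, polys$rings[[a]])
      for (k in seq_len(nrow(verts_a))) {
        if (point_in_rings(verts_a[k, 1], verts_a[k, 2],
                           polys$rings[[b]]) == "inside") {
          stop("region interiors overlap: ", polys$name[a], " / ",
               polys$name[b], call. = FALSE)
        }
      }
    }
  }
  invisible()
}

#' Assign points to regions
#'
#' Returns, per point, the name of the containing region or `NA` when the
#' point falls in no region (such points are counted and excluded from
#' summaries, never silently dropped). A point on a shared boundary is
#' assigned to the alphabetically first region containing it — a documented
#' stable tie-break, since containment is tested in alphabetical order and
#' boundary counts as containing.
#'
#' @param lon,lat Numeric vectors.
#' @param regions A [region_set()].
#' @return Character vector of region names (`NA` = unassigned).
#' @export
assign_region <- function(lon, lat, regions) {
  stopifnot(inherits(regions, "region_set"))
  polys <- regions$regions
  bb <- lapply(polys$rings, .ring_bbox)
  out <- rep(NA_character_, length(lon))
  for (k in seq_along(lon)) {
    for (r in seq_len(nrow(polys))) {
      b <- bb[[r]]
      if (lon[k] < b[1] || lon[k] > b[3] || lat[k] < b[2] || lat[k] > b[4])
        next
      st <- point_in_rings(lon[k], lat[k], polys$rings[[r]])
      if (st != "outside") { out[k] <- polys$name[r]; break }
    }
  }
  out
}

#' Per-region record, species, genus and family counts
#'
#' The regional analogue of a per-department diversity table: for each
#' region, the number of cleaned records falling in it and the distinct
#' species, genera and families among those records. Regions with no
#' records are emitted with zeros. Records outside every region are
#' reported in the `n_unassigned` attribute.
#'
#' @param occurrences Cleaned tibble (`taxon_id`, `lon`, `lat`).
#' @param checklist Checklist tibble supplying `taxon_id`, `genus`,
#'   `family`; every occurrence `taxon_id` must be present (orphans are a
#'   hard error listing the ids).
#' @param regions A [region_set()].
#' @return Tibble `region`, `n_records`, `n_species`, `n_genera`,
#'   `n_families`, one row per region in alphabetical order, with attribute
#'   `n_unassigned`.
#' @export
summarize_regions <- function(occurrences, checklist, regions) {
  orphans <- setdiff(occurrences$taxon_id, checklist$taxon_id)
  if (length(orphans)) {
    stop("occurrence taxon_id(s) missing from checklist: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  cl <- checklist[!duplicated(checklist$taxon_id),
                  c("taxon_id", "genus", "family")]
  occ <- dplyr::left_join(tibble::as_tibble(occurrences), cl,
                          by = "taxon_id")
  occ$region <- assign_region(occ$lon, occ$lat, regions)
  n_unassigned <- sum(is.na(occ$region))
  counted <- occ[!is.na(occ$region), ] |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_records = dplyr::n(),
                     n_species = dplyr::n_distinct(.data$taxon_id),
                     n_genera = dplyr::n_distinct(.data$genus),
                     n_families = dplyr::n_distinct(.data$family),
                     .groups = "drop")
  all_regions <- tibble::tibble(region = regions$regions$name)
  out <- dplyr::left_join(all_regions, counted, by = "region")
  out[is.na(out$n_records), -1] <- 0L
  for (cc in c("n_records", "n_species", "n_genera", "n_families")) {
    out[[cc]] <- as.integer(out[[cc]])
  }
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Species breadth over regions, with headline counts
#'
#' Breadth of a species is the number of distinct regions holding at least
#' one of its records. Headline counts mirror the customary cuts of a
#' departmental breadth analysis: species found in more than `wide` and
#' more than `very_wide` regions, in every region, in exactly
#' `single` region(s), and in at most `narrow` regions.
#'
#' @param occurrences Cleaned tibble (`taxon_id`, `lon`, `lat`).
#' @param regions A [region_set()].
#' @param wide,very_wide,single,narrow Threshold parameters
#'   (defaults 20, 30, 1, 5).
#' @return List: `breadth` (tibble `taxon_id`, `breadth`), `headline`
#'   (named integers `n_wide`, `n_very_wide`, `n_all_regions`, `n_single`,
#'   `n_narrow`), `n_regions`.
#' @export
breadth_distribution <- function(occurrences, regions, wide = 20,
                                 very_wide = 30, single = 1, narrow = 5) {
  occ <- tibble::as_tibble(occurrences)
  occ$region <- assign_region(occ$lon, occ$lat, regions)
  occ <- occ[!is.na(occ$region), ]
  breadth <- occ |>
    dplyr::distinct(.data$taxon_id, .data$region) |>
    dplyr::count(.data$taxon_id, name = "breadth")
  n_regions <- nrow(regions$regions)
  headline <- c(
    n_wide = sum(breadth$breadth > wide),
    n_very_wide = sum(breadth$breadth > very_wide),
    n_all_regions = sum(breadth$breadth == n_regions),
    n_single = sum(breadth$breadth == single),
    n_narrow = sum(breadth$breadth <= narrow))
  list(breadth = breadth, headline = headline, n_regions = n_regions)
}

#' Regress species richness on record count across regions
#'
#' Ordinary least squares of `n_species` on `n_records` over the regional
#' summaries, quantifying how much apparent regional richness tracks
#' sampling effort. The slope p-value is the usual two-sided t-test with
#' n - 2 degrees of freedom. Raw counts are the default; `log10 = TRUE`
#' fits on log10 counts (regions with zero records are then dropped).
#'
#' @param summaries Output of [summarize_regions()] (or any tibble with
#'   `n_records`, `n_species`).
#' @param log10 Fit on log10-transformed counts instead of raw counts.
#' @return List of class `richness_regression`: `slope`, `intercept`, `r`
#'   (Pearson), `p_value`, `n`.
#' @export
richness_records_regression <- function(summaries, log10 = FALSE) {
  x <- summaries$n_records
  y <- summaries$n_species
  if (log10) {
    keep <- x > 0 & y > 0
    x <- base::log10(x[keep]); y <- base::log10(y[keep])
  }
  if (length(x) < 3) stop("need at least 3 regions", call. = FALSE)
  if (stats::var(x) == 0) {
    stop("record counts have zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = unname(stats::cor(x, y)),
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "richness_regression")
}

#' @export
print.richness_regression <- function(x, ...) {
  cat(sprintf(
    "Richness ~ records OLS (n = %d): slope = %.4g, intercept = %.4g, r = %.3f, p = %.3g\n",
    x$n, x$slope, x$intercept, x$r, x$p_value))
  invisible(x)
}
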