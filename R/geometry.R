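#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius 6371.0088 km, the convention
#' used by all distance-based cleaning filters in this package.
#'
#' @param lon1,lat1 Numeric vectors, decimal degrees (WGS84).
#' @param lon2,lat2 Numeric vectors, decimal degrees; recycled against the
#'   first point.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(-74.1, 4.6, -75.6, 6.2)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

# --- polygon representation ---------------------------------------------
# A polygon geometry is stored as a list of rings; each ring is an n x 2
# numeric matrix (lon, lat), closed or open (closure is implied). MultiPolygon
# geometries flatten to one list of rings: the even-odd rule then handles
# holes and multiple parts uniformly.

#' Locate a point relative to a set of polygon rings
#'
#' Even-odd (ray casting) containment with explicit boundary detection.
#' A horizontal ray is cast eastward from the point; crossings are counted
#' per ring and combined, so rings may be outer boundaries, holes, or parts
#' of a multipolygon in any orientation.
#'
#' @param lon,lat Scalar coordinates of the point.
#' @param rings List of n x 2 matrices (columns lon, lat).
#' @return One of `"inside"`, `"outside"`, `"boundary"`.
#' @export
point_in_rings <- function(lon, lat, rings) {
  stopifnot(is.list(rings), length(rings) > 0)
  crossings <- 0L
  for (ring in rings) {
    n <- nrow(ring)
    # drop explicit closure vertex if present
    if (n > 1 && ring[1, 1] == ring[n, 1] && ring[1, 2] == ring[n, 2]) {
      n <- n - 1L
    }
    if (n < 3) next
    x <- ring[seq_len(n), 1]
    y <- ring[seq_len(n), 2]
    j <- n
    for (i in seq_len(n)) {
      x1 <- x[j]; y1 <- y[j]; x2 <- x[i]; y2 <- y[i]
      if (.on_segment(lon, lat, x1, y1, x2, y2)) return("boundary")
      # count crossing of the eastward ray with half-open vertex rule
      if ((y1 > lat) != (y2 > lat)) {
        xint <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
        if (xint > lon) crossings <- crossings + 1L
      }
      j <- i
    }
  }
  if (crossings %% 2L == 1L) "inside" else "outside"
}

# point exactly on segment (x1,y1)-(x2,y2)?
.on_segment <- function(px, py, x1, y1, x2, y2) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (cross != 0) return(FALSE)
  px >= min(x1, x2) && px <= max(x1, x2) &&
    py >= min(y1, y2) && py <= max(y1, y2)
}

#' Vectorised containment test
#'
#' @param lon,lat Numeric vectors of equal length.
#' @param rings List of rings (see [point_in_rings()]).
#' @param boundary_inside Logical: should boundary points count as inside?
#' @return Logical vector.
#' @export
points_in_rings <- function(lon, lat, rings, boundary_inside = TRUE) {
  vapply(seq_along(lon), function(k) {
    st <- point_in_rings(lon[k], lat[k], rings)
    st == "inside" || (boundary_inside && st == "boundary")
  }, logical(1))
}

#' Build a rectangular ring
#'
#' @param lon_min,lat_min,lon_max,lat_max Rectangle edges, decimal degrees.
#' @return A closed 5 x 2 ring matrix usable in polygon ring lists.
#' @export
rect_ring <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max, lat_min))
}

# --- GeoJSON ------------------------------------------------------------

.geom_to_rings <- function(geom) {
  type <- geom$type
  co <- geom$coordinates
  ring_mat <- function(r) {
    m <- do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  if (identical(type, "Polygon")) {
    lapply(co, ring_mat)
  } else if (identical(type, "MultiPolygon")) {
    unlist(lapply(co, function(poly) lapply(poly, ring_mat)),
           recursive = FALSE)
  } else {
    stop("unsupported geometry type for polygon feature: ", type,
         call. = FALSE)
  }
}

#' Read a GeoJSON FeatureCollection
#'
#' Parses Polygon/MultiPolygon features into ring lists and Point features
#' into coordinate rows. Geometries must be valid WGS84 GeoJSON; an invalid
#' or unsupported geometry is a hard error at load time.
#'
#' @param path Path to a GeoJSON file.
#' @return A list with elements `polygons` (tibble: `name`, `kind`, and a
#'   list-column `rings`) and `points` (tibble: `name`, `kind`, `lon`, `lat`).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  polys <- list(); pts <- list()
  for (f in gj$features) {
    props <- f$properties
    nm <- props$region_name %||% props$name %||% NA_character_
    kd <- props$kind %||% NA_character_
    ty <- f$geometry$type
    if (ty %in% c("Polygon", "MultiPolygon")) {
      rings <- .geom_to_rings(f$geometry)
      if (any(vapply(rings, nrow, 0L) < 4)) {
        stop("invalid polygon ring (fewer than 3 distinct vertices) in ",
             path, call. = FALSE)
      }
      polys[[length(polys) + 1L]] <-
        tibble::tibble(name = nm, kind = kd, rings = list(rings))
    } else if (identical(ty, "Point")) {
      co <- f$geometry$coordinates
      pts[[length(pts) + 1L]] <-
        tibble::tibble(name = nm, kind = kd, lon = co[[1]], lat = co[[2]])
    } else {
      stop("unsupported geometry type in ", path, ": ", ty, call. = FALSE)
    }
  }
  list(
    polygons = if (length(polys)) dplyr::bind_rows(polys) else
      tibble::tibble(name = character(), kind = character(),
                     rings = list()),
    points = if (length(pts)) dplyr::bind_rows(pts) else
      tibble::tibble(name = character(), kind = character(),
                     lon = numeric(), lat = numeric())
  )
}

.rings_to_geom <- function(rings) {
  list(type = "Polygon",
       coordinates = lapply(rings, function(m) {
         if (!(m[1, 1] == m[nrow(m), 1] && m[1, 2] == m[nrow(m), 2])) {
           m <- rbind(m, m[1, , drop = FALSE])
         }
         lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
       }))
}

#' Write polygon and point features to GeoJSON
#'
#' @param path Output path.
#' @param polygons Optional tibble with columns `name`, `kind`, list-column
#'   `rings` (as returned by [read_geojson()]). Each feature is written as a
#'   Polygon whose rings are the feature's ring list.
#' @param points Optional tibble with columns `name`, `kind`, `lon`, `lat`.
#' @param extra_properties Optional data.frame of additional per-polygon
#'   properties (row-aligned with `polygons`).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(path, polygons = NULL, points = NULL,
                          extra_properties = NULL) {
  feats <- list()
  if (!is.null(polygons) && nrow(polygons)) {
    for (i in seq_len(nrow(polygons))) {
      props <- list(region_name = polygons$name[i], kind = polygons$kind[i])
      if (!is.null(extra_properties)) {
        props <- c(props, as.list(extra_properties[i, , drop = FALSE]))
      }
      feats[[length(feats) + 1L]] <- list(
        type = "Feature", properties = props,
        geometry = .rings_to_geom(polygons$rings[[i]]))
    }
  }
  if (!is.null(points) && nrow(points)) {
    for (i in seq_len(nrow(points))) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(region_name = points$name[i],
                          kind = points$kind[i]),
        geometry = list(type = "Point",
                        coordinates = c(points$lon[i], points$lat[i])))
    }
  }
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
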