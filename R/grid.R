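#' Grid specification
#'
#' A regular longitude/latitude lattice. Cells are half-open
#' `[edge, edge + cell_size)` in both axes, so a point exactly on a cell
#' edge belongs to the higher-index cell. The default origin anchors the
#' lattice at (-180, -90), aligning cells with the integer-degree graticule
#' regardless of the data extent, so cell identities are reproducible across
#' datasets.
#'
#' @param cell_size Cell edge in degrees (default 0.1, roughly a
#'   10 x 10 km cell at the equator).
#' @param origin Length-2 `(lon0, lat0)` lattice anchor.
#' @param extent Length-4 `(lon_min, lat_min, lon_max, lat_max)` bounding
#'   box every point must fall in.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(cell_size = 0.1, origin = c(-180, -90),
                      extent = c(-180, -90, 180, 90)) {
  stopifnot(cell_size > 0, length(origin) == 2, length(extent) == 4,
            extent[3] > extent[1], extent[4] > extent[2])
  structure(list(cell_size = cell_size, origin = origin, extent = extent),
            class = "grid_spec")
}

# floor((x - x0)/cs) with an epsilon bump so points sitting exactly on a
# cell edge land in the higher-index cell despite the binary representation
# of 0.1-degree lattices (e.g. (-179.9 - -180)/0.1 < 1 in doubles).
.cell_index <- function(x, x0, cs) {
  v <- (x - x0) / cs
  i <- floor(v)
  frac <- v - i
  bump <- frac > 1 - 1e-7
  i[bump] <- i[bump] + 1
  as.integer(i)
}

#' Assign points to grid cells
#'
#' @param lon,lat Numeric vectors, decimal degrees.
#' @param grid A [grid_spec()].
#' @return Tibble with integer columns `cell_i` (column, from west) and
#'   `cell_j` (row, from south). A point outside the grid extent is a hard
#'   error naming the point.
#' @export
#' @examples
#' assign_cell(0.05, 0.05, grid_spec(0.1, origin = c(0, 0), extent = c(0, 0, 1, 1)))
assign_cell <- function(lon, lat, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ext <- grid$extent
  bad <- lon < ext[1] | lon > ext[3] | lat < ext[2] | lat > ext[4]
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("point (%g, %g) lies outside the grid extent", lon[k],
                 lat[k]), call. = FALSE)
  }
  tibble::tibble(
    cell_i = .cell_index(lon, grid$origin[1], grid$cell_size),
    cell_j = .cell_index(lat, grid$origin[2], grid$cell_size))
}

#' Build the species-by-cell presence table
#'
#' Presence is binary per (species, cell): duplicate records within a cell
#' collapse, so all downstream metrics are invariant under record
#' duplication. Range size `C_s` is the count of distinct occupied cells.
#'
#' @param occurrences Tibble with `taxon_id`, `lon`, `lat` (cleaned records
#'   inside the grid extent).
#' @param grid A [grid_spec()].
#' @return List of class `species_range_table`: `presence` (tibble
#'   `taxon_id`, `cell_i`, `cell_j`, one row per occupied species-cell pair)
#'   and `range_size` (tibble `taxon_id`, `range_cells`).
#' @export
build_presence <- function(occurrences, grid) {
  if (nrow(occurrences) == 0) {
    return(structure(list(
      presence = tibble::tibble(taxon_id = character(),
                                cell_i = integer(), cell_j = integer()),
      range_size = tibble::tibble(taxon_id = character(),
                                  range_cells = integer())),
      class = "species_range_table"))
  }
  cells <- assign_cell(occurrences$lon, occurrences$lat, grid)
  presence <- dplyr::distinct(
    tibble::tibble(taxon_id = occurrences$taxon_id,
                   cell_i = cells$cell_i, cell_j = cells$cell_j))
  range_size <- presence |>
    dplyr::count(.data$taxon_id, name = "range_cells")
  structure(list(presence = presence, range_size = range_size),
            class = "species_range_table")
}

#' Per-cell diversity metrics: SR, WE, CWE
#'
#' For each occupied cell: species richness `SR` (distinct species
#' present), weighted endemism `WE = sum over present species of
#' 1 / C_s` where `C_s` is the species' range size in cells (a single-cell
#' endemic contributes 1, a widespread species contributes little), and
#' corrected weighted endemism `CWE = WE / SR`, in (0, 1], highlighting
#' cells whose flora is disproportionately narrow-ranged regardless of
#' absolute richness. Summed over all cells WE equals the number of gridded
#' species, since each species contributes `C_s * (1 / C_s) = 1`.
#'
#' @param occurrences Tibble with `taxon_id`, `lon`, `lat`; alternatively a
#'   prebuilt [build_presence()] table via `presence`.
#' @param grid A [grid_spec()].
#' @param presence Optional `species_range_table`, overriding
#'   `occurrences`.
#' @return Tibble with one row per occupied cell — `cell_i`, `cell_j`,
#'   `lon_min`, `lat_min`, `lon_max`, `lat_max`, `SR`, `WE`, `CWE` — ordered
#'   by `cell_j` then `cell_i` ascending.
#' @export
compute_grid_metrics <- function(occurrences = NULL, grid = grid_spec(),
                                 presence = NULL) {
  if (is.null(presence)) presence <- build_presence(occurrences, grid)
  stopifnot(inherits(presence, "species_range_table"))
  pr <- presence$presence
  if (nrow(pr) == 0) {
    return(tibble::tibble(cell_i = integer(), cell_j = integer(),
                          lon_min = numeric(), lat_min = numeric(),
                          lon_max = numeric(), lat_max = numeric(),
                          SR = integer(), WE = numeric(), CWE = numeric()))
  }
  pr <- dplyr::left_join(pr, presence$range_size, by = "taxon_id")
  out <- pr |>
    dplyr::group_by(.data$cell_i, .data$cell_j) |>
    dplyr::summarise(SR = dplyr::n(),
                     WE = sum(1 / .data$range_cells), .groups = "drop") |>
    dplyr::mutate(CWE = .data$WE / .data$SR) |>
    dplyr::arrange(.data$cell_j, .data$cell_i)
  cs <- grid$cell_size
  tibble::tibble(
    cell_i = out$cell_i, cell_j = out$cell_j,
    lon_min = grid$origin[1] + out$cell_i * cs,
    lat_min = grid$origin[2] + out$cell_j * cs,
    lon_max = grid$origin[1] + (out$cell_i + 1) * cs,
    lat_max = grid$origin[2] + (out$cell_j + 1) * cs,
    SR = out$SR, WE = out$WE, CWE = out$CWE)
}

#' Weighted endemism of one cell
#'
#' Convenience single-cell accessors over a [build_presence()] table;
#' [compute_grid_metrics()] is the bulk path.
#'
#' @param cell_i,cell_j Integer cell index.
#' @param presence A `species_range_table`.
#' @return `weighted_endemism`: WE of the cell; `corrected_weighted_endemism`:
#'   WE / SR. Asking for an unoccupied cell is an error.
#' @export
weighted_endemism <- function(cell_i, cell_j, presence) {
  stopifnot(inherits(presence, "species_range_table"))
  pr <- presence$presence
  sp <- pr$taxon_id[pr$cell_i == cell_i & pr$cell_j == cell_j]
  if (!length(sp)) stop("cell is not occupied", call. = FALSE)
  cs <- presence$range_size$range_cells[
    match(sp, presence$range_size$taxon_id)]
  sum(1 / cs)
}

#' @rdname weighted_endemism
#' @export
corrected_weighted_endemism <- function(cell_i, cell_j, presence) {
  pr <- presence$presence
  sr <- sum(pr$cell_i == cell_i & pr$cell_j == cell_j)
  weighted_endemism(cell_i, cell_j, presence) / sr
}

#' Write the cell-metrics table as CSV and/or GeoJSON squares
#'
#' @param metrics Output of [compute_grid_metrics()].
#' @param csv_path,geojson_path Output paths; `NULL` skips that format.
#' @return `metrics`, invisibly.
#' @export
write_grid_metrics <- function(metrics, csv_path = NULL,
                               geojson_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(metrics, csv_path, progress = FALSE)
  }
  if (!is.null(geojson_path)) {
    polys <- tibble::tibble(
      name = sprintf("cell_%d_%d", metrics$cell_i, metrics$cell_j),
      kind = "grid_cell",
      rings = lapply(seq_len(nrow(metrics)), function(k) {
        list(rect_ring(metrics$lon_min[k], metrics$lat_min[k],
                       metrics$lon_max[k], metrics$lat_max[k]))
      }))
    write_geojson(geojson_path, polygons = polys,
                  extra_properties = as.data.frame(
                    metrics[, c("SR", "WE", "CWE")]))
  }
  invisible(metrics)
}
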