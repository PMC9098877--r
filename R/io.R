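#' Read a Darwin-Core-style occurrence CSV
#'
#' Requires columns `scientificName`, `decimalLatitude`,
#' `decimalLongitude`; coordinates are read as text and preserved verbatim
#' alongside their parsed values, because recorded precision lives in the
#' source string. Row numbers become `source_id` when the file carries
#' none. Unparseable coordinate rows are kept here — the cleaning pipeline
#' removes and counts them.
#'
#' @param path CSV path (comma-delimited, UTF-8, `.` decimal separator).
#' @return Tibble: `source_id`, `scientificName`, `lat_text`, `lon_text`,
#'   `lat`, `lon`.
#' @export
read_occurrences <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  req <- c("scientificName", "decimalLatitude", "decimalLongitude")
  missing_cols <- setdiff(req, colnames(x))
  if (length(missing_cols)) {
    stop("occurrence file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (ncol(x) == 1 && grepl(";", colnames(x)[1])) {
    stop("occurrence file appears to be ';'-delimited; expected commas",
         call. = FALSE)
  }
  tibble::tibble(
    source_id = if ("source_id" %in% colnames(x)) x$source_id else
      sprintf("row%06d", seq_len(nrow(x))),
    scientificName = x$scientificName,
    lat_text = x$decimalLatitude,
    lon_text = x$decimalLongitude,
    lat = suppressWarnings(as.numeric(x$decimalLatitude)),
    lon = suppressWarnings(as.numeric(x$decimalLongitude)))
}

.md5 <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline on a simulated scenario
#'
#' End-to-end driver: simulate the scenario, reconcile occurrence names
#' against the backbone, clean the records, compute grid metrics, aggregate
#' over departments and bioregions (summaries, breadth distribution,
#' richness-versus-records regression), summarise the catalogue, and write
#' every stage's outputs plus a machine-readable run manifest (package
#' version, seed, input/output MD5 hashes, per-stage counts). Rerunning
#' with the same seed and config reproduces every output byte for byte.
#'
#' @param out_dir Output directory.
#' @param config A [scenario_config()].
#' @return List of class `pipeline_result` with all stage results and the
#'   manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = scenario_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  scen <- simulate_scenario(config, out_dir = in_dir)

  # reconcile: map occurrence names to backbone-accepted taxa
  occ_raw <- read_occurrences(file.path(in_dir, "occurrences.csv"))
  rec <- reconcile_names(occ_raw$scientificName, scen$backbone)
  idx <- match(normalize_name(occ_raw$scientificName),
               normalize_name(rec$mapping$input_name))
  occ_raw$taxon_id <- rec$mapping$taxon_id[idx]
  matched <- occ_raw[!is.na(occ_raw$taxon_id), ]

  fc <- filter_config(
    min_decimals = 3,
    centroid = scen$geometry$centroid, centroid_radius_km = 5,
    institution_points = scen$geometry$institutions,
    institution_buffer_m = 100,
    urban_polygons = scen$geometry$urban,
    land_polygon = scen$geometry$land)
  cleaned <- clean_pipeline(matched, fc)

  metrics <- compute_grid_metrics(cleaned$records, scen$grid)

  checklist <- flag_nus(scen$checklist, scen$crops$accepted_name)
  dep <- region_set(scen$geometry$departments)
  bio <- region_set(scen$geometry$bioregions)
  dep_summary <- summarize_regions(cleaned$records, checklist, dep)
  bio_summary <- summarize_regions(cleaned$records, checklist, bio)
  breadth <- breadth_distribution(cleaned$records, dep)
  regression <- richness_records_regression(dep_summary)
  cat_summary <- summarize_catalogue(checklist)

  # outputs
  paths <- list(
    cleaned = file.path(out_dir, "cleaned_occurrences.csv"),
    cleaning_report = file.path(out_dir, "cleaning_report.json"),
    grid_csv = file.path(out_dir, "grid_metrics.csv"),
    grid_geojson = file.path(out_dir, "grid_cells.geojson"),
    departments = file.path(out_dir, "region_summary_departments.csv"),
    bioregions = file.path(out_dir, "region_summary_bioregions.csv"),
    breadth = file.path(out_dir, "breadth.csv"),
    regression = file.path(out_dir, "regression.json"),
    catalogue_json = file.path(out_dir, "catalogue_summary.json"),
    catalogue_csv = file.path(out_dir, "catalogue_summary.csv"))
  readr::write_csv(
    tibble::tibble(taxon_id = cleaned$records$taxon_id,
                   decimalLongitude = cleaned$records$lon,
                   decimalLatitude = cleaned$records$lat),
    paths$cleaned, progress = FALSE)
  write_cleaning_report(cleaned, paths$cleaning_report)
  write_grid_metrics(metrics, csv_path = paths$grid_csv,
                     geojson_path = paths$grid_geojson)
  readr::write_csv(dep_summary, paths$departments, progress = FALSE)
  readr::write_csv(bio_summary, paths$bioregions, progress = FALSE)
  readr::write_csv(breadth$breadth, paths$breadth, progress = FALSE)
  jsonlite::write_json(unclass(regression), paths$regression,
                       auto_unbox = TRUE, digits = NA)
  write_catalogue_summary(cat_summary, json_path = paths$catalogue_json,
                          csv_path = paths$catalogue_csv)

  input_files <- list.files(in_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "floragrid",
    version = as.character(utils::packageVersion("floragrid")),
    seed = config$seed,
    n_species = config$n_species,
    inputs = stats::setNames(
      lapply(input_files, .md5),
      sub(paste0("^", in_dir, "/"), "", input_files)),
    outputs = stats::setNames(
      lapply(paths, .md5),
      vapply(paths, basename, character(1))),
    stage_counts = list(
      occurrences_read = nrow(occ_raw),
      names_unmatched = length(rec$unmatched),
      records_reconciled = nrow(matched),
      cleaning = cleaned$report,
      occupied_cells = nrow(metrics),
      gridded_species = nrow(
        build_presence(cleaned$records, scen$grid)$range_size),
      regions_departments = nrow(dep_summary),
      regions_bioregions = nrow(bio_summary),
      unassigned_records = attr(dep_summary, "n_unassigned")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(structure(
    list(scenario = scen, cleaned = cleaned, metrics = metrics,
         checklist = checklist, dep_summary = dep_summary,
         bio_summary = bio_summary, breadth = breadth,
         regression = regression, catalogue_summary = cat_summary,
         manifest = manifest),
    class = "pipeline_result"))
}
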