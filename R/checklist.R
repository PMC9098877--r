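#' Normalise a taxon name for matching
#'
#' Conservative normalisation: trims outer whitespace, collapses internal
#' runs of whitespace to one space, lower-cases the string and re-capitalises
#' the first letter (genus). No fuzzy or phonetic matching is attempted:
#' fuzzy matching silently merges taxa.
#'
#' @param x Character vector of verbatim names.
#' @return Character vector of normalised names.
#' @export
#' @examples
#' normalize_name("  Inga   EDULIS ")
normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x <- tolower(x)
  first <- toupper(substring(x, 1, 1))
  paste0(first, substring(x, 2))
}

#' Reconcile verbatim names against a taxonomic backbone
#'
#' Exact matching after [normalize_name()] against a locally supplied
#' backbone table (columns `input_name`, `accepted_name`, `taxon_id`,
#' `match_status`). Names hitting a backbone row whose `match_status` is
#' `"unmatched"` are reported as unmatched, like names absent from the
#' backbone. Two verbatim names resolving to the same accepted name collapse
#' to one taxon.
#'
#' @param names Character vector of verbatim taxon names.
#' @param backbone Data frame with columns `input_name`, `accepted_name`,
#'   `taxon_id`, `match_status`.
#' @return List with `mapping` (tibble: `input_name`, `accepted_name`,
#'   `taxon_id`; one row per distinct input name that matched) and
#'   `unmatched` (character vector of distinct unmatched input names).
#' @export
reconcile_names <- function(names, backbone) {
  req <- c("input_name", "accepted_name", "taxon_id", "match_status")
  missing_cols <- setdiff(req, colnames(backbone))
  if (length(missing_cols)) {
    stop("backbone is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bb <- tibble::as_tibble(backbone)
  bb$key <- normalize_name(bb$input_name)
  dup <- bb |>
    dplyr::group_by(.data$key) |>
    dplyr::filter(dplyr::n_distinct(.data$accepted_name) > 1) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    stop("backbone has conflicting accepted names for input name(s): ",
         paste(unique(dup$key), collapse = "; "), call. = FALSE)
  }
  bb <- bb[!duplicated(bb$key), ]

  names <- unique(names)   # each verbatim input name appears exactly once
  keys <- normalize_name(names)
  idx <- match(keys, bb$key)
  hit <- !is.na(idx) & bb$match_status[idx] != "unmatched"
  mapping <- tibble::tibble(
    input_name = names[hit],
    accepted_name = bb$accepted_name[idx[hit]],
    taxon_id = bb$taxon_id[idx[hit]]
  )
  list(mapping = mapping,
       unmatched = names[!hit])
}

#' Flag neglected and underutilized species (NUS)
#'
#' A catalogued edible species is NUS exactly when its accepted name is
#' absent from the supplied crop-census list: `is_nus == !in_crop_census`
#' for every entry, so the NUS/census partition is exhaustive and exclusive.
#' An empty crop list flags every species as NUS.
#'
#' @param entries Checklist tibble with column `accepted_name`.
#' @param crop_names Character vector of census accepted names (same
#'   backbone spelling as the checklist).
#' @return `entries` with logical columns `in_crop_census` and `is_nus`
#'   (re)set.
#' @export
flag_nus <- function(entries, crop_names) {
  entries <- tibble::as_tibble(entries)
  entries$in_crop_census <-
    normalize_name(entries$accepted_name) %in% normalize_name(crop_names)
  entries$is_nus <- !entries$in_crop_census
  entries
}

#' Percentage share, rounded to one decimal
#'
#' `100 * k / n` rounded half away from zero to one decimal place — the
#' rounding convention used for every percentage this package reports.
#'
#' @param k Count (0 <= k <= n).
#' @param n Positive total.
#' @return Numeric percentage with one decimal.
#' @export
#' @examples
#' compute_share(146, 3805) # 3.8
compute_share <- function(k, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  x <- 100 * k / n
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

.habit_levels <- c("tree", "shrub", "herb", "climber", "other")

#' Split pipe-separated growth habits into a list of habit sets
#'
#' The habit vocabulary is fixed to tree / shrub / herb / climber / other;
#' unknown habit strings map to `"other"` with a warning.
#'
#' @param habits Character vector, pipe-separated habit strings.
#' @return List of character vectors (one set per entry).
#' @export
parse_habits <- function(habits) {
  sets <- strsplit(ifelse(is.na(habits) | habits == "", "other", habits),
                   "|", fixed = TRUE)
  lapply(sets, function(h) {
    h <- trimws(tolower(h))
    bad <- !(h %in% .habit_levels)
    if (any(bad)) {
      warning("unknown growth habit(s) mapped to 'other': ",
              paste(unique(h[bad]), collapse = ", "), call. = FALSE)
      h[bad] <- "other"
    }
    unique(h)
  })
}

#' Catalogue-level summary statistics
#'
#' Counts and one-decimal percentage shares over a curated checklist:
#' distinct species (taxon ids), families and genera, and counts of native,
#' endemic, naturalised, cultivated, locally reported and NUS species. All
#' shares are relative to the species total and computed with
#' [compute_share()].
#'
#' @param entries Checklist tibble with columns `taxon_id`, `family`,
#'   `genus`, and logical flags `native`, `endemic`, `naturalised`,
#'   `cultivated`, `locally_reported`, `is_nus`.
#' @return A list of class `catalogue_summary` with components `counts`
#'   (named integer vector) and `shares` (named numeric vector of
#'   percentages).
#' @export
summarize_catalogue <- function(entries) {
  if (nrow(entries) == 0) stop("empty checklist", call. = FALSE)
  entries <- entries[!duplicated(entries$taxon_id), ]
  counts <- c(
    n_species = nrow(entries),
    n_families = dplyr::n_distinct(entries$family),
    n_genera = dplyr::n_distinct(entries$genus),
    n_native = sum(entries$native),
    n_endemic = sum(entries$endemic),
    n_naturalised = sum(entries$naturalised),
    n_cultivated = sum(entries$cultivated),
    n_locally_reported = sum(entries$locally_reported),
    n_not_locally_reported = sum(!entries$locally_reported),
    n_nus = sum(entries$is_nus),
    n_in_census = sum(!entries$is_nus)
  )
  share_of <- counts[-1]
  shares <- compute_share(share_of, counts[["n_species"]])
  names(shares) <- sub("^n_", "pct_", names(share_of))
  structure(list(counts = counts, shares = shares),
            class = "catalogue_summary")
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat("Edible-species catalogue summary\n")
  cat(sprintf("  species: %d  families: %d  genera: %d\n",
              x$counts[["n_species"]], x$counts[["n_families"]],
              x$counts[["n_genera"]]))
  for (nm in c("n_native", "n_endemic", "n_naturalised", "n_cultivated",
               "n_locally_reported", "n_nus")) {
    pct <- x$shares[[sub("^n_", "pct_", nm)]]
    cat(sprintf("  %-20s %6d  (%.1f%%)\n", sub("^n_", "", nm),
                x$counts[[nm]], pct))
  }
  invisible(x)
}

#' Rank families by genus and species counts
#'
#' @param entries Checklist tibble (`taxon_id`, `family`, `genus`, `native`).
#' @param n Number of top families to return; if larger than the number of
#'   families, all are returned.
#' @param native_only If `TRUE`, counts are recomputed over native entries
#'   only.
#' @return Tibble `family`, `n_genera`, `n_species`, sorted by genus count
#'   (descending), ties broken by species count then family name.
#' @export
rank_families <- function(entries, n = 20, native_only = FALSE) {
  stopifnot(n >= 1)
  e <- entries[!duplicated(entries$taxon_id), ]
  if (native_only) e <- e[e$native, ]
  tab <- e |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_genera = dplyr::n_distinct(.data$genus),
                     n_species = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_genera), dplyr::desc(.data$n_species),
                   .data$family)
  utils::head(tab, n)
}

#' Rank genera by species count within one growth habit
#'
#' A species recorded under several habits is counted once under each, so
#' habit tables overlap by design (set semantics on the habit column).
#'
#' @param entries Checklist tibble with `taxon_id`, `genus` and a
#'   `growth_habits` pipe-separated column.
#' @param habit One of `"tree"`, `"shrub"`, `"herb"`, `"climber"`, `"other"`.
#' @param n Number of top genera to return.
#' @return Tibble `genus`, `n_species`, sorted by species count descending,
#'   ties alphabetical.
#' @export
rank_genera_by_habit <- function(entries, habit, n = 10) {
  habit <- match.arg(habit, .habit_levels)
  e <- entries[!duplicated(entries$taxon_id), ]
  sets <- parse_habits(e$growth_habits)
  keep <- vapply(sets, function(h) habit %in% h, logical(1))
  e <- e[keep, ]
  tab <- e |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(n_species = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_species), .data$genus)
  utils::head(tab, n)
}

#' Read a checklist CSV
#'
#' Expected columns: `taxon_id`, `accepted_name`, `family`, `genus`,
#' logical flags `native`, `endemic`, `naturalised`, `cultivated`,
#' `locally_reported`, pipe-separated `growth_habits`, and optionally
#' `in_crop_census`.
#'
#' @param path CSV path.
#' @return Checklist tibble; if `in_crop_census` is present, `is_nus` is
#'   derived as its negation.
#' @export
read_checklist <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("taxon_id", "accepted_name", "family", "genus", "native",
           "endemic", "naturalised", "cultivated", "locally_reported",
           "growth_habits")
  missing_cols <- setdiff(req, colnames(x))
  if (length(missing_cols)) {
    stop("checklist is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (fl in c("native", "endemic", "naturalised", "cultivated",
               "locally_reported", "in_crop_census")) {
    if (fl %in% colnames(x)) x[[fl]] <- as.logical(x[[fl]])
  }
  if ("in_crop_census" %in% colnames(x)) x$is_nus <- !x$in_crop_census
  bad <- x$endemic & !x$native
  if (any(bad)) {
    stop("endemic implies native; violated by: ",
         paste(utils::head(x$accepted_name[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Write a catalogue summary as JSON and/or CSV
#'
#' @param summary A `catalogue_summary` object.
#' @param json_path,csv_path Output paths; `NULL` skips that format.
#' @return `summary`, invisibly.
#' @export
write_catalogue_summary <- function(summary, json_path = NULL,
                                    csv_path = NULL) {
  stopifnot(inherits(summary, "catalogue_summary"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(counts = as.list(summary$counts),
                              shares = as.list(summary$shares)),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- tibble::tibble(
      statistic = c(names(summary$counts), names(summary$shares)),
      value = c(unname(summary$counts), unname(summary$shares)))
    readr::write_csv(df, csv_path, progress = FALSE)
  }
  invisible(summary)
}
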