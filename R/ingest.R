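## Ingest: read and validate the three input tables, classify growth forms,
## and apply the plot-level filters that define the analysis data set.

.cover_cols   <- c("plot_id", "species_id", "stratum", "cover")
.species_cols <- c("species_id", "genus", "growth_habit", "is_hemiparasite",
                   "life_history")
.plot_cols    <- c("plot_id", "latitude", "longitude", "area_m2", "year",
                   "park_id", "ecoregion_l4")

#' Growth-habit vocabularies
#'
#' Habit labels mapped to the herbaceous and woody growth forms. Matching is
#' case-insensitive after trimming; multi-valued habit strings (for example
#' `"Forb/herb, Subshrub"`) are resolved to their first listed habit.
#'
#' @format Character vectors of habit labels.
#' @name growth_habits
NULL

#' @rdname growth_habits
#' @export
herbaceous_habits <- c("forb/herb", "graminoid", "subshrub")

#' @rdname growth_habits
#' @export
woody_habits <- c("tree", "shrub")

.check_columns <- function(dt, required, file) {
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop(sprintf("schema error in '%s': missing required column(s): %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and validate the cover, species and plot tables
#'
#' Reads the three CSV inputs of the pipeline, checks their schemas, coerces
#' types, drops zero-cover rows, and cross-checks referential integrity:
#' cover rows citing a plot or species absent from the metadata tables are
#' rejected and listed in the validation report rather than silently kept.
#'
#' @param cover_path CSV with columns `plot_id, species_id, stratum, cover`.
#' @param species_path CSV with columns
#'   `species_id, genus, growth_habit, is_hemiparasite, life_history`.
#' @param plots_path CSV with columns
#'   `plot_id, latitude, longitude, area_m2, year, park_id, ecoregion_l4`.
#' @return A list with elements `cover`, `species`, `plots` (data.tables) and
#'   `report`, a list describing rejected rows and row counts.
#' @export
load_tables <- function(cover_path, species_path, plots_path) {
  for (p in c(cover_path, species_path, plots_path)) {
    if (!file.exists(p)) stop(sprintf("input file not found: '%s'", p), call. = FALSE)
  }
  cover   <- data.table::fread(cover_path,   colClasses = list(character = c("plot_id", "species_id")))
  species <- data.table::fread(species_path, colClasses = list(character = "species_id"))
  plots   <- data.table::fread(plots_path,   colClasses = list(character = "plot_id"))

  .check_columns(cover, .cover_cols, cover_path)
  .check_columns(species, .species_cols, species_path)
  .check_columns(plots, .plot_cols, plots_path)

  ## cover must be numeric; report offending data lines (header = line 1)
  if (!is.numeric(cover$cover)) {
    bad <- which(is.na(suppressWarnings(as.numeric(cover$cover))) & !is.na(cover$cover))
    stop(sprintf("non-numeric cover in '%s', column 'cover', line(s): %s",
                 cover_path,
                 paste(head(bad + 1L, 5L), collapse = ", ")), call. = FALSE)
  }
  for (col in c("latitude", "longitude", "area_m2")) {
    if (!is.numeric(plots[[col]])) {
      stop(sprintf("non-numeric values in '%s', column '%s'", plots_path, col),
           call. = FALSE)
    }
  }
  if (!is.logical(species$is_hemiparasite)) {
    species[, is_hemiparasite := as.logical(is_hemiparasite)]
  }

  if (anyDuplicated(species$species_id)) {
    stop(sprintf("duplicate species_id in '%s'", species_path), call. = FALSE)
  }
  if (anyDuplicated(plots$plot_id)) {
    stop(sprintf("duplicate plot_id in '%s'", plots_path), call. = FALSE)
  }
  dup <- duplicated(cover[, .(plot_id, species_id, stratum)])
  if (any(dup)) {
    stop(sprintf("duplicate (plot_id, species_id, stratum) rows in '%s' (e.g. line %d)",
                 cover_path, which(dup)[1L] + 1L), call. = FALSE)
  }

  ## out-of-range coordinates are a data error, not a filter case
  bad_coord <- plots[!is.na(latitude) & !is.na(longitude) &
                       (abs(latitude) > 90 | abs(longitude) > 180)]
  if (nrow(bad_coord) > 0L) {
    stop(sprintf("coordinates out of range in '%s' for plot(s): %s",
                 plots_path, paste(head(bad_coord$plot_id, 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!is.na(plots$area_m2) & plots$area_m2 <= 0)) {
    stop(sprintf("non-positive plot area in '%s'", plots_path), call. = FALSE)
  }

  n_zero <- sum(cover$cover <= 0, na.rm = TRUE)
  cover <- cover[!is.na(cover) & cover > 0]

  unknown_plot    <- cover[!plot_id %in% plots$plot_id]
  unknown_species <- cover[!species_id %in% species$species_id]
  cover <- cover[plot_id %in% plots$plot_id & species_id %in% species$species_id]

  report <- list(
    n_cover_rows      = nrow(cover),
    n_species         = nrow(species),
    n_plots           = nrow(plots),
    n_zero_cover_dropped = n_zero,
    rejected_unknown_plot    = unknown_plot,
    rejected_unknown_species = unknown_species
  )
  list(cover = cover, species = species, plots = plots, report = report)
}

#' Classify species into growth forms
#'
#' Adds a `growth_form` column (`"herbaceous"`, `"woody"` or `"excluded"`) to
#' the species catalog. Herbaceous covers the forb/herb, graminoid and
#' subshrub habits; woody covers tree and shrub. Habit strings are trimmed
#' and matched case-insensitively; multi-valued strings take the first listed
#' habit. Hemiparasites are always classified as herbaceous, whatever their
#' habit string. Species matching neither vocabulary are marked `"excluded"`
#' and take no part in community metrics.
#'
#' @param species Species catalog as returned by [load_tables()].
#' @return The catalog with a `growth_form` column added (copy; input unchanged).
#' @export
classify_growth_form <- function(species) {
  stopifnot(is.data.frame(species), "growth_habit" %in% names(species))
  out <- data.table::as.data.table(species)
  out[, habit_first := tolower(trimws(sub(",.*$", "", growth_habit)))]
  out[, growth_form := data.table::fcase(
    habit_first %in% herbaceous_habits, "herbaceous",
    habit_first %in% woody_habits, "woody",
    default = "excluded"
  )]
  out[is_hemiparasite == TRUE, growth_form := "herbaceous"]
  out[, habit_first := NULL]
  out[]
}

#' Filter plots and consolidate the cover table
#'
#' Restricts the plot table to plots with recorded coordinates and the target
#' survey area (400 m2 by default, the modal plot size of the source survey),
#' restricts the cover table to the surviving plots, and collapses multiple
#' strata of the same species within a plot into a single summed cover, the
#' per-plot abundance used by all downstream metrics.
#'
#' @param plots Plot metadata table.
#' @param cover Cover observations table.
#' @param area_keep Plot area (m2) to retain; default 400.
#' @return List with filtered `plots`, consolidated `cover` (one row per
#'   plot x species), and a `report` of exclusion counts.
#' @export
filter_plots <- function(plots, cover, area_keep = 400) {
  stopifnot(area_keep > 0)
  plots <- data.table::as.data.table(plots)
  cover <- data.table::as.data.table(cover)

  has_coord <- !is.na(plots$latitude) & !is.na(plots$longitude)
  keep <- has_coord & !is.na(plots$area_m2) & plots$area_m2 == area_keep
  report <- list(
    n_input            = nrow(plots),
    n_missing_coord    = sum(!has_coord),
    n_wrong_area       = sum(has_coord & !keep),
    n_retained         = sum(keep)
  )
  if (!any(keep)) stop("no plots survive filters", call. = FALSE)

  plots_out <- plots[keep]
  cover_out <- cover[plot_id %in% plots_out$plot_id,
                     .(cover = sum(cover)), by = .(plot_id, species_id)]
  list(plots = plots_out, cover = cover_out, report = report)
}
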