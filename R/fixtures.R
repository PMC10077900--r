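## Small deterministic datasets used by the test suite, built in code.

#' Bundled test fixtures
#'
#' Deterministic small datasets exercising the pipeline, including its
#' degenerate cases. `"tiny_null"` and `"tiny_effect"` are ~200-plot
#' generator outputs without and with a focal effect; `"pairing_grid"` is a
#' hand-built plot layout containing a non-mutual nearest-neighbour chain,
#' a duplicate-coordinate pair and a singleton ecoregion;
#' `"single_taxon_plots"` contains plots whose growth-form communities have
#' exactly one species (defined richness, undefined evenness).
#'
#' @param name One of `"tiny_null"`, `"tiny_effect"`, `"pairing_grid"`,
#'   `"single_taxon_plots"`.
#' @return List with `cover`, `species`, `plots` (and `truth` for the
#'   generated fixtures).
#' @export
make_fixture <- function(name) {
  fixtures <- c("tiny_null", "tiny_effect", "pairing_grid",
                "single_taxon_plots")
  if (!name %in% fixtures) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 name, paste(fixtures, collapse = ", ")), call. = FALSE)
  }
  switch(
    name,
    tiny_null = generate_communities(.tiny_config(effect_evenness = 0)),
    tiny_effect = generate_communities(.tiny_config(effect_evenness = 0.6)),
    pairing_grid = .pairing_grid_fixture(),
    single_taxon_plots = .single_taxon_fixture()
  )
}

.tiny_config <- function(...) {
  generator_config(
    n_species = 300L, n_focal = 12L, n_ecoregions = 4L,
    parks_per_ecoregion = 2L, plots_per_park = 25L,
    focal_occupancy_target = 0.25, seed = 42L, ...)
}

.pairing_grid_fixture <- function() {
  plots <- data.table::data.table(
    plot_id = sprintf("pg%02d", 1:8),
    latitude = c(0, 0, 0, 10, 10, 20, 40, 40),
    longitude = c(0, 0.010, 0.030, 10, 10, -100, -100, -100.010),
    area_m2 = 400,
    year = c(2000L, 2000L, 2001L, 2001L, 2002L, 2002L, 2003L, 2003L),
    park_id = c("PA", "PA", "PA", "PB", "PB", "PC", "PD", "PD"),
    ecoregion_l4 = c("EA", "EA", "EA", "EB", "EB", "EC", "ED", "ED"))
  species <- data.table::data.table(
    species_id = c("hemi1", "grass1", "tree1"),
    genus = c("Castilleja", "Genus001", "Genus002"),
    growth_habit = c("forb/herb", "graminoid", "tree"),
    is_hemiparasite = c(TRUE, FALSE, FALSE),
    life_history = c("perennial", "perennial", "perennial"))
  cover <- data.table::CJ(plot_id = plots$plot_id,
                          species_id = c("grass1", "tree1"))
  cover[, `:=`(stratum = ifelse(species_id == "tree1", "tree", "field"),
               cover = 10)]
  cover <- data.table::rbindlist(list(cover, data.table::data.table(
    plot_id = c("pg01", "pg07"), species_id = "hemi1",
    stratum = "field", cover = 2)))
  data.table::setorder(cover, plot_id, species_id)
  list(cover = cover, species = species, plots = plots)
}

.single_taxon_fixture <- function() {
  plots <- data.table::data.table(
    plot_id = sprintf("st%02d", 1:6),
    latitude = 40 + (1:6) / 100,
    longitude = -100 + (1:6) / 100,
    area_m2 = 400,
    year = rep(c(2005L, 2006L), 3),
    park_id = "P1", ecoregion_l4 = "E1")
  species <- data.table::data.table(
    species_id = c("hemi1", "forb1", "grass1", "tree1", "shrub1"),
    genus = c("Pedicularis", "Genus001", "Genus002", "Genus003", "Genus004"),
    growth_habit = c("forb/herb", "forb/herb", "graminoid", "tree", "shrub"),
    is_hemiparasite = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    life_history = "perennial")
  cover <- data.table::rbindlist(list(
    ## st01: single herbaceous taxon -> herb evenness undefined
    data.table::data.table(plot_id = "st01", species_id = "hemi1",
                           stratum = "field", cover = 5),
    ## st02: two herb taxa, one woody -> woody evenness undefined
    data.table::data.table(plot_id = "st02",
                           species_id = c("hemi1", "forb1", "tree1"),
                           stratum = c("field", "field", "tree"),
                           cover = c(3, 7, 40)),
    ## st03-st06: richer communities
    data.table::data.table(plot_id = "st03",
                           species_id = c("forb1", "grass1", "tree1", "shrub1"),
                           stratum = c("field", "field", "tree", "shrub"),
                           cover = c(10, 30, 50, 15)),
    data.table::data.table(plot_id = "st04",
                           species_id = c("hemi1", "forb1", "grass1"),
                           stratum = "field", cover = c(1, 20, 40)),
    data.table::data.table(plot_id = "st05",
                           species_id = c("forb1", "grass1", "shrub1"),
                           stratum = c("field", "field", "shrub"),
                           cover = c(25, 25, 10)),
    data.table::data.table(plot_id = "st06",
                           species_id = c("grass1", "tree1"),
                           stratum = c("field", "tree"), cover = c(60, 30))))
  list(cover = cover, species = species, plots = plots)
}

#' Write a dataset bundle to CSV files
#'
#' Writes `cover.csv`, `species.csv` and `plots.csv` (the exact dialects read
#' by [load_tables()]) into a directory.
#'
#' @param dataset List with `cover`, `species`, `plots`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cover = file.path(dir, "cover.csv"),
             species = file.path(dir, "species.csv"),
             plots = file.path(dir, "plots.csv"))
  data.table::fwrite(dataset$cover, paths["cover"])
  data.table::fwrite(dataset$species, paths["species"])
  data.table::fwrite(dataset$plots, paths["plots"])
  invisible(paths)
}
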