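## End-to-end orchestration: ingest -> metrics -> rank/null framework ->
## pairing -> inference, from a single configuration, with all artifacts
## written as CSV/JSON and all randomness flowing from one master seed.

#' Default pipeline configuration
#'
#' @param ... Named overrides.
#' @return Configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "synthetic",          # "synthetic" or "files"
    generator = list(),          # overrides for generator_config()
    paths = list(cover = NULL, species = NULL, plots = NULL),
    analyses = c("presence", "abundance"),
    focal = list(definition = "guild", k = NULL, band = NULL, genus = NULL),
    responses = NULL,            # NULL = all six response x growth-form pairs
    n_replicates = 1000L,
    epsilon = 1e-6,
    area_keep = 400,
    min_obs = 10L,
    seed = 1L,
    out_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown pipeline config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  cfg
}

## focal definitions: the guild itself, its k most abundant members, a band
## of its internal abundance order, or a genus subset. The null rank window
## is recomputed from whatever set results.
.resolve_focal <- function(species, ra, focal) {
  guild <- species[is_hemiparasite == TRUE, species_id]
  guild <- intersect(guild, ra$species_id)
  if (length(guild) == 0L) stop("no focal guild species in the data", call. = FALSE)
  ord <- ra[species_id %in% guild][order(rank), species_id]
  def <- focal$definition %||% "guild"
  set <- switch(def,
    guild = ord,
    top_k = {
      stopifnot(!is.null(focal$k))
      head(ord, focal$k)
    },
    rank_band = {
      stopifnot(!is.null(focal$band), length(focal$band) == 2L)
      ord[seq(focal$band[1], min(focal$band[2], length(ord)))]
    },
    genus = {
      stopifnot(!is.null(focal$genus))
      g <- species[species_id %in% ord & genus == focal$genus, species_id]
      if (length(g) == 0L) {
        stop(sprintf("no guild species of genus '%s'", focal$genus), call. = FALSE)
      }
      g
    },
    stop(sprintf("unknown focal definition '%s'", def), call. = FALSE))
  set
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates ingest, metrics, the rank-abundance null framework, spatial
#' pairing and the mixed-model analyses from one configuration, writing all
#' stage outputs (`metrics.csv`, `pairs.csv`, `rank_abundance.csv`,
#' `results.csv`, `null_coefficients.csv`, `discards.csv`, `run_log.json`)
#' when `out_dir` is set. Deterministic given the master seed.
#'
#' @param config A [pipeline_config()] list or path to a YAML file with the
#'   same fields.
#' @return List with `results`, `null_coefficients`, `metrics`, `pairs`,
#'   `rank_abundance`, `focal_set`, `diagnostics` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- do.call(pipeline_config, yaml::read_yaml(config))
  stopifnot(config$mode %in% c("synthetic", "files"))

  ## --- data ----------------------------------------------------------------
  if (config$mode == "synthetic") {
    gen_over <- config$generator
    if (is.null(gen_over$seed)) gen_over$seed <- config$seed
    gcfg <- do.call(generator_config, gen_over)
    sim <- generate_communities(gcfg)
    cover <- sim$cover; species <- sim$species; plots <- sim$plots
  } else {
    loaded <- load_tables(config$paths$cover, config$paths$species,
                          config$paths$plots)
    cover <- loaded$cover; species <- loaded$species; plots <- loaded$plots
  }

  species <- classify_growth_form(species)
  filt <- filter_plots(plots, cover, area_keep = config$area_keep)
  plots_f <- filt$plots; cover_f <- filt$cover

  met <- community_metrics(cover_f, species, plots_f)
  ra <- build_rank_abundance(cover_f)

  focal <- .resolve_focal(species, ra, config$focal)
  rr <- focal_rank_range(ra, focal)
  n_sets <- config$n_replicates
  sets <- if (n_sets > 0L) {
    draw_null_sets(ra, focal, n_sets = n_sets, master_seed = config$seed,
                   rank_range = rr)
  } else list()

  responses <- if (is.null(config$responses)) .default_responses() else
    data.table::as.data.table(config$responses)

  results <- list(); null_coefs <- list(); pairs_out <- NULL; discards <- NULL
  if ("presence" %in% config$analyses) {
    pr <- pair_plots(plots_f)
    pairs_out <- pr$pairs; discards <- pr$discards
    pa <- run_presence_analysis(cover_f, met, plots_f, pr$pairs, focal, sets,
                                responses = responses,
                                epsilon = config$epsilon,
                                min_obs = config$min_obs)
    results$presence <- pa$results
    null_coefs$presence <- pa$null_coefficients
  }
  if ("abundance" %in% config$analyses) {
    ab <- run_abundance_analysis(cover_f, met, plots_f, focal, sets,
                                 responses = responses,
                                 epsilon = config$epsilon,
                                 min_obs = config$min_obs)
    results$abundance <- ab$results
    null_coefs$abundance <- ab$null_coefficients
  }
  results <- data.table::rbindlist(results, idcol = "analysis")
  null_coefs <- data.table::rbindlist(
    null_coefs[!vapply(null_coefs, is.null, TRUE)], idcol = "analysis")

  diag_sets <- c(list(list(species_ids = focal, label = "focal")),
                 head(sets, 50L))
  diagnostics <- occupancy_diagnostics(cover_f, diag_sets)

  log <- list(
    seed = config$seed, mode = config$mode,
    n_plots_retained = nrow(plots_f),
    n_species_observed = nrow(ra),
    n_focal = length(focal), focal_rank_range = rr,
    n_replicates = n_sets,
    filter_report = filt$report,
    package_version = as.character(utils::packageVersion("nullcomm")),
    r_version = R.version.string)

  out <- list(results = results, null_coefficients = null_coefs,
              metrics = met, pairs = pairs_out, discards = discards,
              rank_abundance = ra, focal_set = focal,
              diagnostics = diagnostics, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x)) data.table::fwrite(x, file.path(config$out_dir, f))
    w(met, "metrics.csv")
    w(pairs_out, "pairs.csv")
    w(discards, "discards.csv")
    w(ra, "rank_abundance.csv")
    w(results, "results.csv")
    w(null_coefs, "null_coefficients.csv")
    w(diagnostics, "set_occupancy.csv")
    if (length(sets) > 0L) {
      jsonlite::write_json(
        lapply(sets, function(s) list(label = s$label, seed = s$seed,
                                      species_ids = s$species_ids)),
        file.path(config$out_dir, "null_sets.json"), auto_unbox = TRUE)
    }
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}
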