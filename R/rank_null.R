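## Global rank-abundance structure and rank-matched null focal sets.
##
## The null framework asks: is the focal guild's association with community
## structure stronger than that of equally uncommon plants? Each null
## replicate draws a set of non-focal species whose global abundance ranks
## fall inside the guild's rank window, and the whole analysis is re-run with
## that set substituted for the guild.

#' Build the global rank-abundance table
#'
#' Each species' global abundance is its summed cover over all retained
#' plots; ranks are assigned by descending abundance (rank 1 = most
#' abundant), with ties broken lexicographically by `species_id` so that
#' ranking is deterministic.
#'
#' @param cover Consolidated cover table (plot_id, species_id, cover).
#' @return data.table with columns `species_id, abundance, rank`.
#' @export
build_rank_abundance <- function(cover) {
  cover <- data.table::as.data.table(cover)
  if (nrow(cover) == 0L) stop("empty cover table", call. = FALSE)
  ra <- cover[, .(abundance = sum(cover)), by = species_id]
  data.table::setorder(ra, -abundance, species_id)
  ra[, rank := seq_len(.N)]
  ra[]
}

#' Rank range occupied by a focal set
#'
#' @param ra Rank-abundance table from [build_rank_abundance()].
#' @param focal Character vector of focal species ids.
#' @return Integer vector `c(min_rank, max_rank)`.
#' @export
focal_rank_range <- function(ra, focal) {
  if (length(focal) == 0L) stop("focal set is empty", call. = FALSE)
  missing <- setdiff(focal, ra$species_id)
  if (length(missing) > 0L) {
    stop(sprintf("focal species absent from rank-abundance table: %s",
                 paste(head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  r <- ra$rank[ra$species_id %in% focal]
  c(min(r), max(r))
}

.replicate_seed <- function(master_seed, replicate) {
  ## deterministic per-replicate substream; stays inside 32-bit integer range
  as.integer((as.numeric(master_seed) + 1000003 * as.numeric(replicate)) %%
               2147483647)
}

#' Sample one rank-matched null focal set
#'
#' Draws `size` species uniformly without replacement from the non-focal
#' species whose global rank falls inside the focal guild's rank window.
#' Reproducible from `rng_seed`; the global RNG state is left untouched.
#'
#' @param ra Rank-abundance table.
#' @param focal Character vector of guild species ids.
#' @param rng_seed Integer seed for this draw.
#' @param size Number of species to draw (defaults to `length(focal)`).
#' @param rank_range Optional rank window `c(lo, hi)`; defaults to
#'   [focal_rank_range()] of `focal`.
#' @param label Label stored with the set.
#' @param method `"uniform"` (default) draws candidates with equal weight
#'   across the window; `"stratified"` matches the focal set's own rank
#'   profile by sampling within equal-width rank bins in proportion to the
#'   focal counts there — a sensitivity analysis for guilds clustered at one
#'   end of their window.
#' @return List with `species_ids`, `label` and `rank_range`.
#' @export
sample_null_set <- function(ra, focal, rng_seed, size = length(focal),
                            rank_range = NULL, label = "null",
                            method = c("uniform", "stratified")) {
  method <- match.arg(method)
  if (is.null(rank_range)) rank_range <- focal_rank_range(ra, focal)
  pool_dt <- ra[rank >= rank_range[1] & rank <= rank_range[2] &
                  !species_id %in% focal]
  if (nrow(pool_dt) < size) {
    stop(sprintf(
      "null candidate pool (%d species in ranks %d-%d) smaller than requested set size %d",
      nrow(pool_dt), rank_range[1], rank_range[2], size), call. = FALSE)
  }
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(rng_seed)
  if (method == "uniform" || nrow(pool_dt) == size) {
    pool <- pool_dt$species_id
    ids <- if (length(pool) == size) pool else sample(pool, size)
  } else {
    breaks <- seq(rank_range[1], rank_range[2], length.out = 11L)
    breaks[11L] <- breaks[11L] + 1
    fr <- ra[species_id %in% focal, rank]
    want <- tabulate(findInterval(fr, breaks), nbins = 10L)
    want <- round(want * size / sum(want))
    bin <- findInterval(pool_dt$rank, breaks)
    ids <- character(0)
    for (b in which(want > 0L)) {
      cand <- pool_dt$species_id[bin == b]
      take <- min(want[b], length(cand))
      if (take > 0L) {
        ids <- c(ids, if (length(cand) == take) cand else sample(cand, take))
      }
    }
    left <- setdiff(pool_dt$species_id, ids)
    deficit <- size - length(ids)
    if (deficit > 0L) {
      ids <- c(ids, if (length(left) == deficit) left else sample(left, deficit))
    } else if (deficit < 0L) {
      ids <- sample(ids, size)
    }
  }
  list(species_ids = sort(ids), label = label, rank_range = rank_range)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Draw an ensemble of null focal sets
#'
#' Each replicate uses its own seed derived from the master seed and the
#' replicate index, so individual replicates are reproducible in isolation.
#'
#' @param ra Rank-abundance table.
#' @param focal Guild species ids.
#' @param n_sets Number of null sets.
#' @param size Set size; defaults to the guild size.
#' @param master_seed Master integer seed.
#' @param rank_range Optional explicit rank window.
#' @param method Sampling method, as in [sample_null_set()].
#' @return List of null sets as returned by [sample_null_set()]; each
#'   carries its own `seed` for standalone reproduction.
#' @export
draw_null_sets <- function(ra, focal, n_sets, size = length(focal),
                           master_seed = 1L, rank_range = NULL,
                           method = "uniform") {
  if (is.null(rank_range)) rank_range <- focal_rank_range(ra, focal)
  lapply(seq_len(n_sets), function(i) {
    s <- sample_null_set(ra, focal, rng_seed = .replicate_seed(master_seed, i),
                         size = size, rank_range = rank_range,
                         label = sprintf("null_rep_%04d", i), method = method)
    s$seed <- .replicate_seed(master_seed, i)
    s
  })
}

#' Occupancy diagnostics for focal and null sets
#'
#' Reports, for a collection of species sets, both the per-species plot
#' occupancy range (how many plots each member occupies) and the per-set
#' joint plot count (how many plots contain at least one member). The two
#' readings of set occupancy differ by orders of magnitude for rare guilds,
#' so both are reported.
#'
#' @param cover Consolidated cover table.
#' @param sets List of sets (each with `species_ids` and `label`).
#' @return data.table with one row per set:
#'   `label, n_species, per_species_min, per_species_max, joint_plots`.
#' @export
occupancy_diagnostics <- function(cover, sets) {
  cover <- data.table::as.data.table(cover)
  occ <- cover[, .(n_plots = data.table::uniqueN(plot_id)), by = species_id]
  data.table::rbindlist(lapply(sets, function(s) {
    per <- occ[species_id %in% s$species_ids, n_plots]
    if (length(per) == 0L) per <- 0L
    data.table::data.table(
      label = s$label,
      n_species = length(s$species_ids),
      per_species_min = min(per),
      per_species_max = max(per),
      joint_plots = cover[species_id %in% s$species_ids,
                          data.table::uniqueN(plot_id)]
    )
  }))
}
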