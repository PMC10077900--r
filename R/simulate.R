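## Synthetic plot x species communities with the statistical structure the
## analysis assumes and a known, tunable focal-guild effect.
##
## Two-tier cover model. Common species (the head of the intended
## rank-abundance curve) share each plot's growth-form cover total through a
## geometric dominance series with plot-specific dominance parameter delta.
## Tail species -- the rank window where the focal guild and all null
## candidates live -- occur rarely and get per-occurrence lognormal covers
## that do not depend on delta. The focal effect enters causally through
## dominance only: delta_plot = inv_logit(logit(delta0) - gamma *
## ln(1 + focal cover) + group intercepts + noise), so focal cover lowers
## dominance and raises herbaceous evenness while leaving richness flat
## (unless effect_richness is set). Because every tail species is generated
## by the same mechanism, focal and null-candidate species are exchangeable
## when gamma = 0, which is what makes the empirical null calibrated.

.hemi_genera <- c("Pedicularis", "Castilleja", "Krameria", "Comandra",
                  "Aureolaria", "Cordylanthus", "Dasistoma", "Euphrasia",
                  "Geocaulon", "Orthocarpus", "Triphysaria", "Seymeria")
.hemi_genus_wts <- c(0.32, 0.25, 0.20, 0.13, rep(0.10 / 8, 8))

## Dominance-reduction coefficient of the calibrated effect preset: chosen
## numerically (see config_effect) so the generator's large-sample truth on
## the logit-evenness scale is about 0.19 per unit log focal cover.
.gamma_star <- 1.05

#' Generator configuration
#'
#' Returns the full configuration list for [generate_communities()], with
#' defaults that emulate the structure of a continental vegetation-plot
#' survey: ~7,000 species, most rare; a hierarchical ecoregion > park > plot
#' design with group-level intercepts on community metrics; a minority focal
#' guild of 78 herbaceous taxa occupying ~13% of plots and spanning a wide,
#' abundant-skewed window of the rank-abundance curve; and ~12,500 plots of
#' 400 m2. Override any field by name.
#'
#' @param ... Named overrides of the defaults.
#' @return Configuration list (class `nullcomm_config`).
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_species = 6987L,
    n_focal = 78L,
    n_ecoregions = 42L,
    parks_per_ecoregion = 3L,
    plots_per_park = 99L,
    years = 1997:2012,
    ## heavy-tailed intended species-abundance distribution (lognormal)
    sad_meanlog = 0, sad_sdlog = 1.8,
    ## common-tier occupancy: occ_max * rank^(-occupancy_decay)
    occ_max = 0.6, occupancy_decay = 0.6,
    ## boundary between the common tier and the rare tail (fraction of N)
    tail_start_frac = 0.09,
    ## focal ranks drawn from this window (fractions of N), skewed toward
    ## the abundant end by a Beta(shape1, shape2) profile
    focal_window_frac = c(0.114, 0.987),
    focal_rank_shape = c(1.2, 3.0),
    ## per-occurrence cover scale (%) across the tail, and its spread
    tail_cover_hi = 0.30, tail_cover_lo = 0.25, tail_cover_sdlog = 0.6,
    ## plot dominance (geometric-series parameter) and its drivers
    delta0 = 0.25, delta0_woody = 0.35,
    effect_evenness = 0,    # gamma: dominance reduction per unit ln(1+A_f)
    effect_richness = 0,    # extra herb species per unit ln(1+A_f)
    re_sd_even = c(ecoregion = 0.6, park = 0.4, year = 0.2),
    resid_sd_even = 0.7,
    re_sd_rich = c(ecoregion = 0.20, park = 0.12, year = 0.05),
    resid_sd_rich = 0.18,
    ## plot growth-form cover totals (%), lognormal
    total_cover_meanlog = log(75), total_cover_sdlog = 0.25,
    woody_cover_meanlog = log(45), woody_cover_sdlog = 0.35,
    habit_probs = c("forb/herb" = 0.42, "graminoid" = 0.15,
                    "subshrub" = 0.08, "shrub" = 0.16, "tree" = 0.11,
                    "vine" = 0.05, "nonvascular" = 0.03),
    focal_occupancy_target = 0.13,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown generator config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  .validate_config(cfg)
  structure(cfg, class = "nullcomm_config")
}

.validate_config <- function(cfg) {
  stopifnot(cfg$n_species >= 20, cfg$n_focal >= 1,
            cfg$delta0 > 0, cfg$delta0 < 1,
            cfg$delta0_woody > 0, cfg$delta0_woody < 1,
            cfg$effect_evenness >= 0,
            all(cfg$re_sd_even >= 0), all(cfg$re_sd_rich >= 0),
            cfg$resid_sd_even >= 0, cfg$resid_sd_rich >= 0,
            cfg$tail_start_frac > 0, cfg$tail_start_frac < cfg$focal_window_frac[1],
            cfg$focal_window_frac[1] < cfg$focal_window_frac[2],
            cfg$focal_window_frac[2] <= 1)
  if (cfg$focal_occupancy_target <= 0 || cfg$focal_occupancy_target >= 1) {
    stop("infeasible focal_occupancy_target: must lie in (0, 1)", call. = FALSE)
  }
  window_n <- floor(diff(cfg$focal_window_frac) * cfg$n_species)
  if (cfg$n_focal >= window_n) {
    stop(sprintf("infeasible config: %d focal taxa will not fit the %d-species rank window",
                 cfg$n_focal, window_n), call. = FALSE)
  }
  invisible(cfg)
}

#' Scaled-down calibration preset
#'
#' Desk-scale configuration used for type-I-error calibration runs: 2,000
#' plots in 20 ecoregions, no focal effect, species count scaled to 1,500
#' with the common-tier occupancy raised so per-plot richness stays at
#' study-scale levels despite the smaller species pool.
#'
#' @param ... Further overrides.
#' @export
config_calibration <- function(...) {
  generator_config(n_species = 1500L, n_focal = 78L, n_ecoregions = 20L,
                   parks_per_ecoregion = 2L, plots_per_park = 50L,
                   occ_max = 0.9, occupancy_decay = 0.5,
                   effect_evenness = 0, ...)
}

#' Calibrated positive-effect preset
#'
#' Study-scale configuration whose dominance-reduction coefficient gamma was
#' fixed, via the generator's own large-sample regression ([true_effect()]),
#' so the true focal coefficient on the logit herbaceous-evenness scale is
#' about 0.19 per unit log focal cover.
#'
#' @param ... Further overrides.
#' @export
config_effect <- function(...) {
  generator_config(effect_evenness = .gamma_star, ...)
}

## distinct integer focal ranks: Beta-profile quantiles over the window
.focal_ranks <- function(cfg) {
  n <- cfg$n_species
  lo <- ceiling(cfg$focal_window_frac[1] * n)
  hi <- floor(cfg$focal_window_frac[2] * n)
  q <- stats::qbeta((seq_len(cfg$n_focal) - 0.5) / cfg$n_focal,
                    cfg$focal_rank_shape[1], cfg$focal_rank_shape[2])
  r <- lo + round(q * (hi - lo))
  ## enforce distinctness (relevant only at fixture scale)
  for (i in seq_along(r)[-1]) if (r[i] <= r[i - 1]) r[i] <- r[i - 1] + 1L
  if (max(r) > hi) r <- lo + ((r - lo) %% (hi - lo + 1L))
  sort(unique(r))
}

#' Generate a synthetic plot x species data set
#'
#' Produces the three tables of the ingest module (cover, species catalog,
#' plot metadata) plus a per-plot truth table recording the realised
#' dominance parameter, focal cover and group intercepts. Fully deterministic
#' given `config$seed`.
#'
#' @param config A [generator_config()] list.
#' @return List with `cover`, `species`, `plots`, `truth` (data.tables).
#'   `truth` carries the config as attribute `"config"`.
#' @export
generate_communities <- function(config = generator_config()) {
  cfg <- .validate_config(config)
  set.seed(cfg$seed)
  n <- cfg$n_species

  ## --- species catalog -----------------------------------------------------
  species_id <- sprintf("sp%05d", seq_len(n))
  ## intended SAD: deterministic lognormal quantile sequence (expected order
  ## statistics), so the species-level scaffold is a property of the
  ## configuration rather than of the seed
  sad <- stats::qlnorm(seq(1 - 0.5 / n, 0.5 / n, length.out = n),
                       cfg$sad_meanlog, cfg$sad_sdlog)
  r_tail <- max(2L, ceiling(cfg$tail_start_frac * n))
  tier <- ifelse(seq_len(n) < r_tail, "common", "tail")

  ## growth habits follow the configured proportions through a deterministic
  ## low-discrepancy sequence: the catalog is shared scaffold across every
  ## plot, so a random draw here would make whole-dataset properties (e.g.
  ## the herbaceous share of the common tier) wobble between seeds
  hp <- cfg$habit_probs / sum(cfg$habit_probs)
  u <- ((seq_len(n) * 0.6180339887498949) + 0.5) %% 1
  habit <- names(hp)[findInterval(u, cumsum(hp), rightmost.closed = TRUE) + 1L]
  habit[is.na(habit)] <- names(hp)[length(hp)]
  ## unclassifiable habits are kept to the rare tail so the dominance series
  ## is built from classified taxa only
  common_idx <- which(tier == "common")
  bad <- common_idx[habit[common_idx] %in% c("vine", "nonvascular")]
  if (length(bad) > 0L) {
    habit[bad] <- sample(c("forb/herb", "graminoid", "subshrub", "shrub", "tree"),
                         length(bad), replace = TRUE,
                         prob = c(0.45, 0.18, 0.08, 0.17, 0.12))
  }

  focal_rank <- .focal_ranks(cfg)
  is_hemi <- seq_len(n) %in% focal_rank
  habit[is_hemi] <- "forb/herb"
  genus <- paste0("Genus", sprintf("%03d",
                                   sample.int(max(30L, n %/% 18L), n, replace = TRUE)))
  genus[is_hemi] <- sample(.hemi_genera, sum(is_hemi), replace = TRUE,
                           prob = .hemi_genus_wts)
  life <- sample(c("perennial", "annual", "unknown"), n, replace = TRUE,
                 prob = c(0.55, 0.35, 0.10))
  life[is_hemi] <- sample(c("perennial", "annual"), sum(is_hemi),
                          replace = TRUE, prob = c(0.85, 0.15))
  species <- data.table::data.table(
    species_id = species_id, genus = genus, growth_habit = habit,
    is_hemiparasite = is_hemi, life_history = life)

  ## --- plots ---------------------------------------------------------------
  n_parks <- cfg$n_ecoregions * cfg$parks_per_ecoregion
  n_plots <- n_parks * cfg$plots_per_park
  eco_ids <- sprintf("E%02d", seq_len(cfg$n_ecoregions))
  park_eco <- rep(seq_len(cfg$n_ecoregions), each = cfg$parks_per_ecoregion)
  park_ids <- sprintf("%s_P%02d", eco_ids[park_eco],
                      sequence(rep(cfg$parks_per_ecoregion, cfg$n_ecoregions)))
  eco_lat <- runif(cfg$n_ecoregions, 31, 47)
  eco_lon <- runif(cfg$n_ecoregions, -119, -76)
  park_lat <- eco_lat[park_eco] + rnorm(n_parks, 0, 0.35)
  park_lon <- eco_lon[park_eco] + rnorm(n_parks, 0, 0.35)
  plot_park <- rep(seq_len(n_parks), each = cfg$plots_per_park)
  plots <- data.table::data.table(
    plot_id = sprintf("plot%06d", seq_len(n_plots)),
    latitude = round(park_lat[plot_park] + rnorm(n_plots, 0, 0.03), 6),
    longitude = round(park_lon[plot_park] + rnorm(n_plots, 0, 0.03), 6),
    area_m2 = 400,
    year = sample(cfg$years, n_plots, replace = TRUE),
    park_id = park_ids[plot_park],
    ecoregion_l4 = eco_ids[park_eco[plot_park]])

  ## --- group intercepts ----------------------------------------------------
  year_levels <- sort(unique(plots$year))
  re <- function(sds, resid_sd) {
    e <- rnorm(cfg$n_ecoregions, 0, sds[["ecoregion"]])
    p <- rnorm(n_parks, 0, sds[["park"]])
    y <- rnorm(length(year_levels), 0, sds[["year"]])
    yi <- match(plots$year, year_levels)
    list(eco = e[park_eco[plot_park]], park = p[plot_park], year = y[yi],
         resid = rnorm(n_plots, 0, resid_sd))
  }
  re_e <- re(cfg$re_sd_even, cfg$resid_sd_even)   # herbaceous dominance channel
  re_w <- re(cfg$re_sd_even, cfg$resid_sd_even)   # woody channel, independent
  re_r <- re(cfg$re_sd_rich, cfg$resid_sd_rich)   # richness (occupancy) channel
  rho <- pmin(3, pmax(0.2, exp(re_r$eco + re_r$park + re_r$year + re_r$resid)))

  ## --- memberships ---------------------------------------------------------
  occ_tail <- 1 - (1 - cfg$focal_occupancy_target)^(1 / cfg$n_focal)
  occ_common <- cfg$occ_max * (seq_len(r_tail - 1L))^(-cfg$occupancy_decay)

  com_plot <- vector("list", r_tail - 1L)
  for (s in seq_len(r_tail - 1L)) {
    p <- pmin(0.95, occ_common[s] * rho)
    com_plot[[s]] <- which(runif(n_plots) < p)
  }
  common_occ <- data.table::data.table(
    sp = rep(seq_len(r_tail - 1L), lengths(com_plot)),
    plot = unlist(com_plot))

  tail_sp <- which(tier == "tail")
  tl_plot <- vector("list", length(tail_sp))
  for (i in seq_along(tail_sp)) {
    k <- rbinom(1L, n_plots, occ_tail)
    tl_plot[[i]] <- if (k > 0L) sample.int(n_plots, k) else integer(0)
  }
  tail_occ <- data.table::data.table(
    sp = rep(tail_sp, lengths(tl_plot)),
    plot = unlist(tl_plot))

  ## --- tail covers (delta-independent, rank-scaled lognormal) --------------
  ## log-linear mapping of the intended SAD into [tail_cover_lo, tail_cover_hi]
  la <- log(sad[tail_sp])
  scale_all <- numeric(n)
  scale_all[tail_sp] <- exp(log(cfg$tail_cover_lo) +
                              (la - min(la)) / max(1e-12, diff(range(la))) *
                              (log(cfg$tail_cover_hi) - log(cfg$tail_cover_lo)))
  tail_occ[, cover := rlnorm(.N, log(scale_all[sp]), cfg$tail_cover_sdlog)]

  ## focal cover per plot
  focal_cover <- numeric(n_plots)
  fo <- tail_occ[sp %in% focal_rank, .(cover_sum = sum(cover)), by = plot]
  focal_cover[fo$plot] <- fo$cover_sum

  ## optional causal richness effect: extra rare herb species on focal plots
  if (cfg$effect_richness > 0) {
    herb_tail <- tail_sp[habit[tail_sp] %in% herbaceous_habits &
                           !tail_sp %in% focal_rank]
    extra_n <- round(cfg$effect_richness * log1p(focal_cover))
    add <- which(extra_n > 0L)
    if (length(add) > 0L) {
      extras <- data.table::data.table(
        sp = unlist(lapply(extra_n[add], function(k)
          sample(herb_tail, min(k, length(herb_tail))))),
        plot = rep(add, extra_n[add]))
      extras[, cover := rlnorm(.N, log(scale_all[sp]), cfg$tail_cover_sdlog)]
      tail_occ <- unique(data.table::rbindlist(list(tail_occ, extras)),
                         by = c("sp", "plot"))
    }
  }

  ## --- dominance and common-tier covers ------------------------------------
  delta <- plogis(qlogis(cfg$delta0) - cfg$effect_evenness * log1p(focal_cover) +
                    re_e$eco + re_e$park + re_e$year + re_e$resid)
  delta_w <- plogis(qlogis(cfg$delta0_woody) +
                      re_w$eco + re_w$park + re_w$year + re_w$resid)
  t_herb <- rlnorm(n_plots, cfg$total_cover_meanlog, cfg$total_cover_sdlog)
  t_woody <- rlnorm(n_plots, cfg$woody_cover_meanlog, cfg$woody_cover_sdlog)

  geom_covers <- function(occ_dt, dlt, totals) {
    if (nrow(occ_dt) == 0L) return(occ_dt[, .(sp, plot, cover = numeric(0))])
    data.table::setorder(occ_dt, plot, sp)  # sp index = intended rank order
    occ_dt[, j_in_plot := seq_len(.N), by = plot]
    occ_dt[, n_sp := .N, by = plot]
    d <- dlt[occ_dt$plot]
    occ_dt[, share := d * (1 - d)^(j_in_plot - 1) / (1 - (1 - d)^n_sp)]
    occ_dt[, cover := share * totals[plot]]
    occ_dt[, .(sp, plot, cover)]
  }
  herb_common <- common_occ[habit[sp] %in% herbaceous_habits]
  woody_common <- common_occ[habit[sp] %in% woody_habits]
  cov_herb <- geom_covers(herb_common, delta, t_herb)
  cov_woody <- geom_covers(woody_common, delta_w, t_woody)

  cover <- data.table::rbindlist(list(cov_herb, cov_woody,
                                      tail_occ[, .(sp, plot, cover)]))
  strat <- c("forb/herb" = "field", "graminoid" = "field",
             "subshrub" = "shrub", "shrub" = "shrub", "tree" = "tree",
             "vine" = "field", "nonvascular" = "ground")
  cover <- cover[, .(plot_id = plots$plot_id[plot],
                     species_id = species_id[sp],
                     stratum = strat[habit[sp]],
                     cover = round(cover, 5))]
  cover <- cover[cover > 0]
  data.table::setorder(cover, plot_id, species_id)

  truth <- data.table::data.table(
    plot_id = plots$plot_id, delta = delta, focal_cover = focal_cover,
    b_ecoregion = re_e$eco, b_park = re_e$park, b_year = re_e$year)
  data.table::setattr(truth, "config", cfg)

  list(cover = cover, species = species, plots = plots, truth = truth)
}

#' Large-sample true focal coefficient of a generator configuration
#'
#' The causal link from focal cover to logit evenness has no simple closed
#' form (it passes through the dominance parameter, nonlinear inverse-logit
#' links and the finite community), so the truth is obtained numerically as
#' the large-sample limit of the analysis estimator itself: communities are
#' generated at large n under the full configuration (group intercepts
#' included, since the nonlinear links make the slope depend on where the
#' groups sit) and the abundance mixed model for herbaceous evenness is
#' fitted; the average coefficient over the truth seeds is returned.
#'
#' @param config A [generator_config()].
#' @param n_plots Approximate number of plots to simulate per truth seed.
#' @param seeds Seeds for the truth simulations (averaged).
#' @return Slope (logit evenness per unit log focal cover).
#' @export
true_effect <- function(config = generator_config(), n_plots = 24000,
                        seeds = c(20201L, 20202L)) {
  cfg <- config
  cfg$plots_per_park <-
    max(2L, ceiling(n_plots / (cfg$n_ecoregions * cfg$parks_per_ecoregion)))
  betas <- vapply(seeds, function(s) {
    cfg$seed <- s
    sim <- generate_communities(cfg)
    cat_cls <- classify_growth_form(sim$species)
    met <- community_metrics(sim$cover, cat_cls, sim$plots)
    focal <- cat_cls[is_hemiparasite == TRUE &
                       species_id %in% sim$cover$species_id, species_id]
    resp <- data.frame(response = "evenness", growth_form = "herbaceous")
    ab <- run_abundance_analysis(sim$cover, met, sim$plots, focal, list(),
                                 responses = resp, compute_aic = FALSE)
    ab$results$beta1
  }, 0)
  mean(betas)
}
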