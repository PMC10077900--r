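test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_species = 300L, n_focal = 10L, n_ecoregions = 3L,
                          parks_per_ecoregion = 2L, plots_per_park = 15L,
                          focal_occupancy_target = 0.3, seed = 9L)
  a <- generate_communities(cfg)
  b <- generate_communities(cfg)
  expect_identical(a$cover, b$cover)
  expect_identical(a$plots, b$plots)
  expect_identical(a$species, b$species)
  ## and the written files are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_dataset(a, d1); p2 <- write_dataset(b, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  c_ <- generate_communities(generator_config(
    n_species = 300L, n_focal = 10L, n_ecoregions = 3L,
    parks_per_ecoregion = 2L, plots_per_park = 15L,
    focal_occupancy_target = 0.3, seed = 10L))
  expect_false(identical(a$cover, c_$cover))
})

test_that("configuration validation rejects infeasible settings", {
  expect_error(generator_config(focal_occupancy_target = 1.5), "infeasible")
  expect_error(generator_config(focal_occupancy_target = 0), "infeasible")
  expect_error(generator_config(n_species = 100L, n_focal = 95L),
               "rank window")
  expect_error(generator_config(nonsense_field = 3), "unknown generator config")
  expect_error(generator_config(delta0 = 1.2))
})

test_that("the generated world has the intended macro-structure", {
  sim <- cached("study_sim", generate_communities(generator_config(seed = 303L)))
  cfg <- attr(sim$truth, "config")

  ## focal plot occupancy within 2 points of target
  occ <- mean(sim$truth$focal_cover > 0)
  expect_lt(abs(occ - cfg$focal_occupancy_target), 0.02)

  ## heavy-tailed abundance distribution: top decile holds > 50% of cover
  ra <- build_rank_abundance(sim$cover)
  data.table::setorder(ra, rank)
  top_share <- sum(ra$abundance[seq_len(nrow(ra) %/% 10)]) / sum(ra$abundance)
  expect_gt(top_share, 0.5)

  ## focal guild is herbaceous and spans a wide, abundant-skewed rank window
  cls <- classify_growth_form(sim$species)
  expect_true(all(cls[is_hemiparasite == TRUE, growth_form] == "herbaceous"))
  focal <- cls[is_hemiparasite == TRUE & species_id %in% ra$species_id,
               species_id]
  rr <- focal_rank_range(ra, focal)
  expect_lt(rr[1] / nrow(ra), 0.25)
  expect_gt(rr[2] / nrow(ra), 0.75)
  med <- stats::median(ra[species_id %in% focal, rank])
  expect_lt(med - rr[1], (rr[2] - rr[1]) / 2)  # clustered toward abundant end

  ## truth table carries per-plot state
  expect_true(all(c("delta", "focal_cover", "b_ecoregion") %in%
                    names(sim$truth)))
  expect_true(all(sim$truth$delta > 0 & sim$truth$delta < 1))
})

test_that("without a focal effect, focal cover is uncorrelated with herbaceous evenness", {
  sim <- cached("study_sim", generate_communities(generator_config(seed = 303L)))
  cls <- classify_growth_form(sim$species)
  met <- community_metrics(sim$cover, cls, sim$plots)
  h <- merge(met[growth_form == "herbaceous" & !is.na(evenness)],
             sim$truth[focal_cover > 0, .(plot_id, focal_cover)],
             by = "plot_id")
  h <- merge(h, sim$plots[, .(plot_id, ecoregion_l4)], by = "plot_id")
  h[, y := transform_response(evenness, "logit")]
  ## partial out ecoregion means, then correlate
  h[, `:=`(yc = y - mean(y), xc = log(focal_cover) - mean(log(focal_cover))),
    by = ecoregion_l4]
  expect_lt(abs(cor(h$xc, h$yc)), 0.05)
})

test_that("a positive effect raises evenness with focal cover; richness stays flat", {
  sim <- cached("effect_sim_small", make_fixture("tiny_effect"))
  cls <- classify_growth_form(sim$species)
  met <- community_metrics(sim$cover, cls, sim$plots)
  h <- merge(met[growth_form == "herbaceous" & !is.na(evenness)],
             sim$truth[focal_cover > 0, .(plot_id, focal_cover)],
             by = "plot_id")
  expect_gt(cor(log(h$focal_cover),
                transform_response(h$evenness, "logit")), 0)
  ## dominance falls with focal cover by construction
  tr <- sim$truth[focal_cover > 0]
  expect_lt(cor(log1p(tr$focal_cover), qlogis(tr$delta)), 0)
})

test_that("effect_richness adds species with focal cover", {
  base <- generator_config(n_species = 400L, n_focal = 20L, n_ecoregions = 3L,
                           parks_per_ecoregion = 2L, plots_per_park = 40L,
                           focal_occupancy_target = 0.4, seed = 12L)
  rich <- generator_config(n_species = 400L, n_focal = 20L, n_ecoregions = 3L,
                           parks_per_ecoregion = 2L, plots_per_park = 40L,
                           focal_occupancy_target = 0.4, seed = 12L,
                           effect_richness = 4)
  s0 <- generate_communities(base)
  s1 <- generate_communities(rich)
  cls <- classify_growth_form(s1$species)
  m0 <- community_metrics(s0$cover, cls, s0$plots)
  m1 <- community_metrics(s1$cover, cls, s1$plots)
  focal_plots <- s1$truth[focal_cover > 0, plot_id]
  r0 <- m0[growth_form == "herbaceous" & plot_id %in% focal_plots,
           mean(richness)]
  r1 <- m1[growth_form == "herbaceous" & plot_id %in% focal_plots,
           mean(richness)]
  expect_gt(r1, r0)
})

test_that("fixtures are named, deterministic and cover the degenerate cases", {
  expect_error(make_fixture("nope"), "unknown fixture.*tiny_null")
  f1 <- make_fixture("tiny_null")
  f2 <- make_fixture("tiny_null")
  expect_identical(f1$cover, f2$cover)
  expect_lte(nrow(f1$plots), 200L)

  grid <- make_fixture("pairing_grid")
  expect_true(anyDuplicated(grid$plots[, .(latitude, longitude)]) > 0)

  st <- make_fixture("single_taxon_plots")
  cls <- classify_growth_form(st$species)
  met <- community_metrics(st$cover, cls, st$plots)
  expect_true(any(met$richness == 1 & is.na(met$evenness)))
})
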