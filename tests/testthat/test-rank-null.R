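toy_cover <- function() {
  data.table::data.table(
    plot_id = c("p1", "p1", "p2", "p2", "p3"),
    species_id = c("A", "B", "A", "C", "B"),
    cover = c(6, 3, 4, 1, 2))
}

test_that("rank abundance sums covers and ranks deterministically", {
  ra <- build_rank_abundance(toy_cover())
  expect_equal(ra[order(rank), species_id], c("A", "B", "C"))   # 10, 5, 1
  expect_equal(ra[species_id == "A", abundance], 10)
  expect_equal(sort(ra$rank), 1:3)

  ## tie broken lexicographically by species id
  tie <- data.table::data.table(plot_id = "p", species_id = c("zed", "abc"),
                                cover = c(5, 5))
  rt <- build_rank_abundance(tie)
  expect_equal(rt[rank == 1, species_id], "abc")

  ## single species
  one <- build_rank_abundance(data.table::data.table(
    plot_id = "p", species_id = "X", cover = 2))
  expect_equal(one$rank, 1L)
  expect_error(build_rank_abundance(toy_cover()[0]), "empty")
})

test_that("ranks are invariant to uniform cover rescaling", {
  sim <- tiny_sim()
  ra1 <- build_rank_abundance(sim$cover)
  scaled <- data.table::copy(sim$cover)[, cover := cover * 7.3]
  ra2 <- build_rank_abundance(scaled)
  expect_equal(ra1$species_id, ra2$species_id)
  expect_equal(ra1$rank, ra2$rank)
})

test_that("focal rank range brackets the member ranks", {
  ra <- build_rank_abundance(toy_cover())
  expect_equal(focal_rank_range(ra, "B"), c(2L, 2L))
  expect_equal(focal_rank_range(ra, c("A", "B", "C")), c(1L, 3L))

  five <- data.table::data.table(
    plot_id = "p", species_id = c("a", "b", "c", "d", "e"),
    cover = c(50, 40, 30, 20, 10))
  ra5 <- build_rank_abundance(five)
  expect_equal(focal_rank_range(ra5, c("b", "d")), c(2L, 4L))

  expect_error(focal_rank_range(ra, character(0)), "empty")
  expect_error(focal_rank_range(ra, "nope"), "absent")
})

test_that("null sets are rank-matched, focal-free and reproducible", {
  sim <- tiny_sim()
  ra <- build_rank_abundance(sim$cover)
  cls <- classify_growth_form(sim$species)
  focal <- cls[is_hemiparasite == TRUE & species_id %in% ra$species_id,
               species_id]
  rr <- focal_rank_range(ra, focal)

  s1 <- sample_null_set(ra, focal, rng_seed = 11)
  s2 <- sample_null_set(ra, focal, rng_seed = 11)
  s3 <- sample_null_set(ra, focal, rng_seed = 12)
  expect_identical(s1$species_ids, s2$species_ids)
  expect_false(identical(s1$species_ids, s3$species_ids))
  expect_length(s1$species_ids, length(focal))
  expect_length(intersect(s1$species_ids, focal), 0L)
  r <- ra[species_id %in% s1$species_ids, rank]
  expect_true(all(r >= rr[1] & r <= rr[2]))

  ## whole ensembles satisfy the invariants replicate by replicate
  sets <- draw_null_sets(ra, focal, n_sets = 25, master_seed = 3)
  for (s in sets) {
    expect_length(intersect(s$species_ids, focal), 0L)
    rk <- ra[species_id %in% s$species_ids, rank]
    expect_true(all(rk >= rr[1] & rk <= rr[2]))
  }
  ## replicate substreams are independent of ensemble size
  sets10 <- draw_null_sets(ra, focal, n_sets = 10, master_seed = 3)
  expect_identical(sets10[[7]]$species_ids, sets[[7]]$species_ids)
})

test_that("a pool exactly matching the set size is returned whole; smaller pools error", {
  ra <- build_rank_abundance(data.table::data.table(
    plot_id = "p", species_id = sprintf("s%02d", 1:6),
    cover = c(60, 50, 40, 30, 20, 10)))
  ## focal = ranks 2 and 5 -> window 2..5, pool = {s03, s04}
  s <- sample_null_set(ra, c("s02", "s05"), rng_seed = 1, size = 2)
  expect_equal(s$species_ids, c("s03", "s04"))
  expect_error(sample_null_set(ra, c("s02", "s05"), rng_seed = 1, size = 3),
               "pool \\(2 species")
})

test_that("null sampling is uniform over the candidate pool", {
  n_cand <- 100L
  ra <- build_rank_abundance(data.table::data.table(
    plot_id = "p", species_id = sprintf("c%03d", seq_len(n_cand + 2L)),
    cover = seq(n_cand + 2L, 1)))
  focal <- c("c001", sprintf("c%03d", n_cand + 2L))  # window = full range
  size <- 10L
  counts <- integer(n_cand)
  names(counts) <- setdiff(ra$species_id, focal)
  n_draws <- 10000L
  for (i in seq_len(n_draws)) {
    s <- sample_null_set(ra, focal, rng_seed = i, size = size)
    counts[s$species_ids] <- counts[s$species_ids] + 1L
  }
  expected <- n_draws * size / n_cand
  sigma <- sqrt(n_draws * (size / n_cand) * (1 - size / n_cand))
  expect_true(all(abs(counts - expected) <= 3 * sigma))
})

test_that("stratified null sampling tracks the focal rank profile", {
  n <- 400L
  ra <- build_rank_abundance(data.table::data.table(
    plot_id = "p", species_id = sprintf("s%04d", seq_len(n)),
    cover = seq(n, 1)))
  ## focal clustered toward the abundant end of a wide window
  focal <- ra[rank %in% c(41:60, 350L), species_id]
  su <- sample_null_set(ra, focal, rng_seed = 5, method = "uniform")
  ss <- sample_null_set(ra, focal, rng_seed = 5, method = "stratified")
  expect_length(ss$species_ids, length(focal))
  expect_length(intersect(ss$species_ids, focal), 0L)
  rr <- focal_rank_range(ra, focal)
  rs <- ra[species_id %in% ss$species_ids, rank]
  expect_true(all(rs >= rr[1] & rs <= rr[2]))
  ## stratified draws sit far closer to the abundant end than uniform draws
  ru <- ra[species_id %in% su$species_ids, rank]
  expect_lt(stats::median(rs), stats::median(ru))
  expect_lt(stats::median(rs), 110)
})

test_that("occupancy diagnostics report both per-species and joint plot counts", {
  sim <- tiny_sim()
  cls <- classify_growth_form(sim$species)
  focal <- cls[is_hemiparasite == TRUE & species_id %in% sim$cover$species_id,
               species_id]
  d <- occupancy_diagnostics(sim$cover,
                             list(list(species_ids = focal, label = "focal")))
  expect_equal(d$n_species, length(focal))
  expect_gte(d$joint_plots, d$per_species_max)
  expect_lte(d$per_species_min, d$per_species_max)
})
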