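sim_lmm_data <- function(n = 300, beta = 0.5, sd_g = 0.7, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    x = rnorm(n),
    g1 = factor(sample(letters[1:12], n, TRUE)),
    g2 = factor(sample(LETTERS[1:8], n, TRUE)),
    g3 = factor(sample(sprintf("y%02d", 1:15), n, TRUE)))
  d$y <- beta * d$x + sd_g * rnorm(12)[as.integer(d$g1)] +
    0.5 * rnorm(8)[as.integer(d$g2)] + rnorm(n)
  d
}

test_that("fit_lmm reproduces lme4::lmer exactly", {
  d <- sim_lmm_data(seed = 21)
  terms <- c("g1", "g2", "g3")
  fml <- y ~ x + (1 | g1) + (1 | g2) + (1 | g3)
  for (reml in c(TRUE, FALSE)) {
    ref <- suppressMessages(lme4::lmer(fml, d, REML = reml))
    got <- fit_lmm(d, terms, reml = reml)
    expect_equal(got$beta1, unname(lme4::fixef(ref)["x"]), tolerance = 1e-8)
    expect_equal(got$se1, unname(sqrt(diag(as.matrix(vcov(ref))))[2]),
                 tolerance = 1e-6)
    expect_equal(got$aic, AIC(ref), tolerance = 1e-6)
    vc <- as.data.frame(lme4::VarCorr(ref))
    expect_equal(sort(unname(got$varcomp)),
                 sort(vc$vcov[vc$grp != "Residual"]), tolerance = 1e-6)
    expect_equal(got$sigma2, vc$vcov[vc$grp == "Residual"], tolerance = 1e-6)
  }
  ## single random term
  ref1 <- suppressMessages(lme4::lmer(y ~ x + (1 | g1), d))
  got1 <- fit_lmm(d, "g1")
  expect_equal(got1$beta1, unname(lme4::fixef(ref1)["x"]), tolerance = 1e-8)
})

test_that("fit_lmm guards degenerate inputs", {
  d <- sim_lmm_data(n = 50, seed = 5)
  expect_error(fit_lmm(d[1:5, ], "g1"), "too few observations")
  d2 <- d; d2$x <- 1
  expect_error(fit_lmm(d2, "g1"), "constant predictor")
  expect_error(fit_lmm(d, "not_a_column"), "not in data")
})

test_that("single-level grouping factors are dropped without changing the slope", {
  d <- sim_lmm_data(seed = 31)
  d$park <- factor("only_one")
  expect_warning(f_with <- fit_lmm(d, c("g1", "park")), "single-level")
  f_without <- fit_lmm(d, "g1")
  expect_equal(f_with$beta1, f_without$beta1, tolerance = 1e-10)
  expect_equal(f_with$dropped_terms, "park")

  ## all factors degenerate -> OLS
  expect_warning(f_ols <- fit_lmm(d, "park"), "single-level")
  ref <- lm(y ~ x, d)
  expect_equal(f_ols$beta1, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(f_ols$aic, AIC(ref), tolerance = 1e-10)
})

test_that("confidence intervals cover a zero slope at the nominal rate", {
  ## 200 generator replicates with true beta = 0; Wald 95% CI coverage
  set.seed(606)
  cover_count <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    d <- data.frame(
      x = rnorm(120),
      g1 = factor(sample(letters[1:8], 120, TRUE)))
    d$y <- 0 * d$x + 0.6 * rnorm(8)[as.integer(d$g1)] + rnorm(120)
    f <- fit_lmm(d, "g1")
    ci <- f$beta1 + c(-1.96, 1.96) * f$se1
    if (ci[1] <= 0 && ci[2] >= 0) cover_count <- cover_count + 1L
  }
  expect_gte(cover_count / n_rep, 0.91)
  expect_lte(cover_count / n_rep, 0.99)
})

test_that("marginal and conditional R2 follow the variance decomposition", {
  expect_equal(unname(compute_r2(var_fixed = 1, var_random = 3, var_resid = 6)),
               c(0.1, 0.4))
  expect_equal(unname(compute_r2(var_fixed = 0, var_random = 3, var_resid = 6)),
               c(0, 1 / 3))
  expect_equal(unname(compute_r2(var_fixed = 2, var_random = 0, var_resid = 0)),
               c(1, 1))
  expect_error(compute_r2(var_fixed = 0, var_random = 0, var_resid = 0),
               "zero total variance")

  d <- sim_lmm_data(seed = 41)
  f <- fit_lmm(d, c("g1", "g2"))
  r2 <- compute_r2(f)
  expect_lte(r2["marginal"], r2["conditional"])
  expect_lte(r2["conditional"], 1)
  expect_gte(r2["marginal"], 0)
})

test_that("empirical p counts null coefficients at or above the observed", {
  ep <- empirical_p(c(1, 2, 3, 4), 2.5)
  expect_equal(ep$p, 0.5)
  expect_equal(empirical_p(c(1, 2, 3, 4), 0.5)$p, 1.0)
  hi <- empirical_p(rnorm(1000), 99)
  expect_equal(hi$p, 0)
  expect_match(hi$report, "p < 0.001")
  ## ties count ("equal to or greater")
  expect_equal(empirical_p(c(1, 2, 2, 3), 2)$p, 0.75)
  ## failed replicates are excluded and counted
  ep2 <- empirical_p(c(1, NA, 3, NA), 2)
  expect_equal(ep2$p, 0.5)
  expect_equal(ep2$n_failed, 2L)
  expect_error(empirical_p(c(NA_real_, NA_real_), 1), "empty")
  ## rank-based: invariant under strictly monotone transforms
  set.seed(8)
  nulls <- rnorm(200); obs <- 0.3
  p1 <- empirical_p(nulls, obs)$p
  p2 <- empirical_p(exp(nulls), exp(obs))$p
  p3 <- empirical_p(nulls * 100 - 7, obs * 100 - 7)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
  ## two-sided option compares magnitudes
  expect_equal(empirical_p(c(-3, -2, 1, 2), 2.5, two_sided = TRUE)$p, 0.25)
})

test_that("delta AIC is the reduced-minus-full difference with the >= 2 rule", {
  da <- delta_aic(100, 213)
  expect_equal(da$delta, 113)
  expect_true(da$significant)
  expect_equal(delta_aic(100, 100)$delta, 0)
  expect_false(delta_aic(100, 100)$significant)
  expect_equal(delta_aic(105, 100)$delta, -5)
  expect_false(delta_aic(105, 100)$significant)
  ## antisymmetry
  expect_equal(delta_aic(97.2, 104.5)$delta, -delta_aic(104.5, 97.2)$delta)
  ## mismatched observation counts across fits are an error
  f1 <- structure(list(aic = 10, n_obs = 100), class = "nullcomm_fit")
  f2 <- structure(list(aic = 12, n_obs = 99), class = "nullcomm_fit")
  expect_error(delta_aic(f1, f2), "different observations")
})

test_that("abundance analysis recovers structure on a small effect dataset", {
  sim <- cached("effect_sim_small", make_fixture("tiny_effect"))
  cls <- classify_growth_form(sim$species)
  met <- community_metrics(sim$cover, cls, sim$plots)
  ra <- build_rank_abundance(sim$cover)
  focal <- cls[is_hemiparasite == TRUE & species_id %in% ra$species_id,
               species_id]
  sets <- draw_null_sets(ra, focal, n_sets = 15, master_seed = 2)
  res <- run_abundance_analysis(sim$cover, met, sim$plots, focal, sets,
                                responses = data.frame(
                                  response = "evenness",
                                  growth_form = "herbaceous"))
  r <- res$results
  expect_equal(nrow(r), 1L)
  expect_true(is.finite(r$beta1))
  expect_equal(r$aic_reduced - r$aic_full, r$delta_aic)
  expect_equal(r$n_null, 15L)
  expect_equal(nrow(res$null_coefficients), 15L)
  expect_true(r$empirical_p >= 0 && r$empirical_p <= 1)
  expect_lte(r$marginal_r2, r$conditional_r2)
})

test_that("presence analysis errors on a contrast-free focal set", {
  sim <- tiny_sim()
  cls <- classify_growth_form(sim$species)
  met <- community_metrics(sim$cover, cls, sim$plots)
  pr <- pair_plots(sim$plots)
  ## a "focal set" of every observed species occupies every plot
  all_species <- unique(sim$cover$species_id)
  expect_error(
    run_presence_analysis(sim$cover, met, sim$plots, pr$pairs, all_species,
                          responses = data.frame(response = "richness",
                                                 growth_form = "all")),
    "constant predictor")
})

test_that("presence analysis produces coefficients and calibrated-looking p on null data", {
  sim <- tiny_sim()
  cls <- classify_growth_form(sim$species)
  met <- community_metrics(sim$cover, cls, sim$plots)
  ra <- build_rank_abundance(sim$cover)
  focal <- cls[is_hemiparasite == TRUE & species_id %in% ra$species_id,
               species_id]
  pr <- pair_plots(sim$plots)
  sets <- draw_null_sets(ra, focal, n_sets = 12, master_seed = 4)
  res <- run_presence_analysis(sim$cover, met, sim$plots, pr$pairs, focal, sets,
                               responses = data.frame(
                                 response = c("evenness", "richness"),
                                 growth_form = c("herbaceous", "herbaceous")))
  expect_equal(nrow(res$results), 2L)
  expect_true(all(is.finite(res$results$beta1)))
  expect_true(all(res$results$predictor == "presence"))
  expect_true(all(res$results$empirical_p >= 0 & res$results$empirical_p <= 1))
  expect_equal(nrow(res$null_coefficients), 24L)
})
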