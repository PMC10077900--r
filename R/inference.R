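## Mixed-model inference with empirical null coefficient distributions.
##
## Presence models: transformed response ~ focal presence, random intercepts
## for pair identity and survey year, fitted on mutual-nearest-neighbour
## pairs. Abundance models: transformed response ~ log focal summed cover,
## random intercepts for year, park and ecoregion, fitted on plots containing
## the focal (or null) set. Significance is the proportion of null-set
## coefficients at least as large as the observed one; the abundance models
## are additionally screened with the AIC difference between the full model
## and the model without the focal term.

.default_responses <- function() {
  data.table::CJ(response = c("evenness", "richness"),
                 growth_form = c("all", "herbaceous", "woody"))
}

.fast_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.conv.grad = "ignore",
                    check.conv.hess = "ignore")
}

## ---------------------------------------------------------------------------
## Random-intercept LMM core on lme4's modular API.
##
## All models in this package are Gaussian with intercept-only random
## effects, so the random-effects structures (indicator Zt, diagonal
## Lambdat) are assembled directly instead of re-deriving them from a
## formula for every fit; the resulting deviance function and optimum are
## identical to lme4::lmer's (asserted in the test suite). The observed and
## null-replicate fits run through this same core, differing only in the
## data handed to it.

.fit_rint_core <- function(y, x, flist, reml = TRUE, start = NULL) {
  n <- length(y)
  fr <- structure(
    data.frame(y = y, x = x),
    terms = stats::terms(y ~ x),
    class = "data.frame")
  X <- cbind("(Intercept)" = rep.int(1, n), x = x)
  k <- length(flist)
  q <- vapply(flist, nlevels, 0L)
  offs <- c(0L, cumsum(q))
  ## stacked random-intercept indicator matrix, assembled from triplets
  Zt <- Matrix::sparseMatrix(
    i = unlist(lapply(seq_len(k),
                      function(j) as.integer(flist[[j]]) + offs[j]),
               use.names = FALSE),
    j = rep.int(seq_len(n), k),
    x = 1,
    dims = c(sum(q), n))
  th <- if (!is.null(start) && length(start) == k) start else rep.int(1, k)
  Q <- sum(q)
  reTrms <- list(
    Zt = Zt, theta = th, Lind = rep.int(seq_len(k), q),
    Gp = unname(offs), lower = rep.int(0, k),
    Lambdat = Matrix::sparseMatrix(i = seq_len(Q), j = seq_len(Q),
                                   x = rep.int(th, q)),
    flist = structure(flist, assign = seq_len(k)),
    cnms = setNames(rep(list("(Intercept)"), k), names(flist)))
  ctl <- .fast_control()
  devfun <- lme4::mkLmerDevfun(fr, X, reTrms, REML = reml, control = ctl)
  opt <- lme4::nloptwrap(th, devfun, lower = reTrms$lower,
                         upper = rep.int(Inf, k))
  devfun(opt$par)  # leave the predictor module at the optimum
  rho <- environment(devfun)
  beta <- rho$pp$beta(1)
  list(beta0 = beta[1L], beta1 = beta[2L], theta = opt$par,
       converged = is.null(opt$conv) || opt$conv == 0,
       devfun = devfun, opt = opt, reTrms = reTrms, fr = fr)
}

## factor preparation shared by all fit entry points; returns NULL factors
## when no grouping factor has >= 2 levels (OLS fallback)
.prep_factors <- function(data, random_terms, warn = TRUE) {
  keep <- list(); dropped <- character(0)
  for (term in random_terms) {
    if (!term %in% names(data)) {
      stop(sprintf("grouping factor '%s' not in data", term), call. = FALSE)
    }
    f <- droplevels(factor(data[[term]]))
    if (nlevels(f) >= 2L) keep[[term]] <- f else dropped <- c(dropped, term)
  }
  if (warn && length(dropped) > 0L) {
    warning(sprintf("dropping single-level grouping factor(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  list(flist = keep, dropped = dropped)
}

## beta-only fit used inside the null-replicate loop (same core as fit_lmm)
.fit_beta_only <- function(data, random_terms, start = NULL, min_obs = 10) {
  ok <- is.finite(data$y) & is.finite(data$x)
  data <- data[ok, , drop = FALSE]
  if (nrow(data) < min_obs) {
    stop(sprintf("too few observations for model fit (%d < %d)",
                 nrow(data), min_obs), call. = FALSE)
  }
  if (length(unique(data$x)) < 2L) stop("constant predictor", call. = FALSE)
  pf <- .prep_factors(data, random_terms, warn = FALSE)
  if (length(pf$flist) == 0L) {
    fit <- stats::lm(y ~ x, data = data)
    return(list(beta1 = unname(stats::coef(fit)[2L]), converged = TRUE))
  }
  core <- .fit_rint_core(data$y, data$x, pf$flist, reml = TRUE, start = start)
  list(beta1 = core$beta1, converged = core$converged)
}

#' Fit a Gaussian linear mixed model with random intercepts
#'
#' Fits via lme4 (modular interface; numerically identical to
#' [lme4::lmer()], which the test suite asserts), implementing the
#' conventions of the analysis: intercept-only random effects, REML by
#' default (maximum likelihood refits are used for AIC comparison of nested
#' fixed-effect structures), grouping factors with fewer than two levels
#' dropped with a warning, and ordinary least squares as the degenerate case
#' when no grouping factor survives.
#'
#' @param data data.frame with columns `y` (transformed response), `x`
#'   (predictor) and the grouping factors named in `random_terms`.
#' @param random_terms Character vector of grouping-factor column names.
#' @param reml Fit by REML (default) or ML.
#' @param min_obs Minimum rows required; fewer is an error.
#' @param fast Use a reduced-check lme4 control (used for null replicates).
#' @param start Optional `theta` start values (recycled from a previous fit
#'   with the same random structure).
#' @return Object of class `nullcomm_fit`: a list with `beta0`, `beta1`,
#'   `se1`, `varcomp` (named per-term random-intercept variances), `sigma2`,
#'   `loglik`, `aic`, `n_obs`, `converged`, `dropped_terms`, `var_fixed`,
#'   `theta`, and the underlying `fit`.
#' @export
fit_lmm <- function(data, random_terms, reml = TRUE, min_obs = 10,
                    fast = FALSE, start = NULL) {
  data <- as.data.frame(data)
  stopifnot(all(c("y", "x") %in% names(data)))
  data <- data[is.finite(data$y) & is.finite(data$x), , drop = FALSE]
  if (nrow(data) < min_obs) {
    stop(sprintf("too few observations for model fit (%d < %d)",
                 nrow(data), min_obs), call. = FALSE)
  }
  if (length(unique(data$x)) < 2L) stop("constant predictor", call. = FALSE)

  pf <- .prep_factors(data, random_terms, warn = !fast)
  keep <- names(pf$flist)

  if (length(keep) == 0L) {
    fit <- stats::lm(y ~ x, data = data)
    cf <- stats::coef(fit)
    return(structure(list(
      beta0 = unname(cf[1]), beta1 = unname(cf[2]),
      se1 = unname(sqrt(diag(vcov(fit)))[2]),
      varcomp = numeric(0), sigma2 = summary(fit)$sigma^2,
      loglik = as.numeric(logLik(fit)), aic = AIC(fit),
      n_obs = nrow(data), converged = TRUE, dropped_terms = pf$dropped,
      var_fixed = var(cf[2] * data$x),
      theta = NULL, reml = reml, fit = fit), class = "nullcomm_fit"))
  }

  core <- .fit_rint_core(data$y, data$x, pf$flist, reml = reml, start = start)
  fit <- lme4::mkMerMod(environment(core$devfun), core$opt, core$reTrms,
                        fr = core$fr)
  vc <- lme4::VarCorr(fit)
  varcomp <- setNames(vapply(keep, function(t) as.numeric(vc[[t]]), 0), keep)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  structure(list(
    beta0 = core$beta0, beta1 = core$beta1,
    se1 = unname(se["x"]),
    varcomp = varcomp, sigma2 = stats::sigma(fit)^2,
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    n_obs = nrow(data), converged = core$converged, dropped_terms = pf$dropped,
    var_fixed = var(core$beta1 * data$x),
    theta = core$theta, reml = reml, fit = fit),
    class = "nullcomm_fit")
}

#' @export
print.nullcomm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model fit (%s): n = %d\n",
              if (isTRUE(x$reml)) "REML" else "ML", x$n_obs))
  cat(sprintf("  beta1 = %.5f (se %.5f)\n", x$beta1, x$se1))
  if (length(x$varcomp) > 0) {
    cat("  random-intercept variances:\n")
    for (nm in names(x$varcomp)) cat(sprintf("    %s: %.5f\n", nm, x$varcomp[nm]))
  }
  cat(sprintf("  residual variance: %.5f; AIC %.2f\n", x$sigma2, x$aic))
  invisible(x)
}

#' Marginal and conditional R-squared for a Gaussian mixed model
#'
#' Nakagawa-Schielzeth variance decomposition: the marginal R2 is the share
#' of total variance explained by the fixed effects alone, the conditional R2
#' the share explained by fixed plus random effects. Accepts either a
#' `nullcomm_fit` or raw variance components.
#'
#' @param fit A `nullcomm_fit`, or `NULL` when components are given directly.
#' @param var_fixed Variance of the fixed-effect predictor (`beta1 * x`);
#'   taken from `fit` when omitted.
#' @param var_random Summed random-intercept variances.
#' @param var_resid Residual variance.
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
compute_r2 <- function(fit = NULL, var_fixed = NULL, var_random = NULL,
                       var_resid = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "nullcomm_fit"))
    if (is.null(var_fixed)) var_fixed <- fit$var_fixed
    if (is.null(var_random)) var_random <- sum(fit$varcomp)
    if (is.null(var_resid)) var_resid <- fit$sigma2
  }
  stopifnot(var_fixed >= 0, var_random >= 0, var_resid >= 0)
  total <- var_fixed + var_random + var_resid
  if (total <= 0) stop("zero total variance", call. = FALSE)
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Empirical p-value from a null coefficient ensemble
#'
#' One-sided by default, exactly as the null-model contrast is posed: the
#' proportion of converged null-replicate coefficients equal to or greater
#' than the observed coefficient. When no null coefficient reaches the
#' observed value the report states `p < 1/n`.
#'
#' @param null_betas Numeric vector of null coefficients (`NA` = failed
#'   replicate, excluded and counted).
#' @param observed Observed coefficient.
#' @param two_sided Compare on absolute values instead (off by default).
#' @return List with `p`, `n_used`, `n_failed` and a human-readable `report`.
#' @export
empirical_p <- function(null_betas, observed, two_sided = FALSE) {
  usable <- null_betas[is.finite(null_betas)]
  n_failed <- length(null_betas) - length(usable)
  if (length(usable) == 0L) stop("empty null ensemble", call. = FALSE)
  if (two_sided) {
    count <- sum(abs(usable) >= abs(observed))
  } else {
    count <- sum(usable >= observed)
  }
  p <- count / length(usable)
  report <- if (count == 0L) {
    sprintf("p < %.4g (0 of %d null coefficients >= observed)",
            1 / length(usable), length(usable))
  } else {
    sprintf("p = %.4g (%d of %d null coefficients >= observed)",
            p, count, length(usable))
  }
  list(p = p, n_used = length(usable), n_failed = n_failed, report = report)
}

#' AIC difference between full and reduced model
#'
#' `delta = AIC(reduced) - AIC(full)`, so positive values mean the focal
#' predictor improves fit; differences of two or more are treated as
#' support for the added predictor. Both models must be fitted to the same
#' observations (checked when sample sizes are supplied or fits are passed).
#'
#' @param aic_full,aic_reduced AIC values, or `nullcomm_fit` objects.
#' @return List with `delta` and logical `significant` (`delta >= 2`).
#' @export
delta_aic <- function(aic_full, aic_reduced) {
  n_full <- n_red <- NULL
  if (inherits(aic_full, "nullcomm_fit")) {
    n_full <- aic_full$n_obs; aic_full <- aic_full$aic
  }
  if (inherits(aic_reduced, "nullcomm_fit")) {
    n_red <- aic_reduced$n_obs; aic_reduced <- aic_reduced$aic
  }
  if (!is.null(n_full) && !is.null(n_red) && n_full != n_red) {
    stop(sprintf("full and reduced models fitted to different observations (%d vs %d)",
                 n_full, n_red), call. = FALSE)
  }
  delta <- aic_reduced - aic_full
  list(delta = delta, significant = delta >= 2)
}

## ---------------------------------------------------------------------------
## shared model-data assembly: identical code path for focal and null sets;
## only the species-id set differs.

.transform_metric <- function(metrics_sub, response, epsilon) {
  if (response == "evenness") {
    m <- metrics_sub[!is.na(evenness)]
    m[, y := transform_response(evenness, "logit", epsilon)]
  } else {
    m <- metrics_sub[richness > 0]
    m[, y := transform_response(as.numeric(richness), "log")]
  }
  m[, .(plot_id, y)]
}

.set_log_cover <- function(cover, set_ids) {
  a <- cover[species_id %chin% set_ids, .(cover_sum = sum(cover)), by = plot_id]
  a[, x := log(cover_sum)]
  a[, .(plot_id, x)]
}

#' Run the abundance analysis for a focal set and its null ensemble
#'
#' For each response (by default evenness and richness of all, herbaceous and
#' woody plants), restricts the data to plots containing at least one member
#' of the focal set, and fits a linear mixed model of the transformed
#' response on the log summed cover of the set, with year, park and ecoregion
#' random intercepts. The identical code path is then rerun for every null
#' set, producing the empirical null distribution of coefficients. The full
#' model is compared with the reduced (intercept-only fixed structure) model
#' by ML-refit AIC.
#'
#' @param cover Consolidated cover table (post [filter_plots()]).
#' @param metrics Community metrics from [community_metrics()].
#' @param plots Plot table with `year`, `park_id`, `ecoregion_l4`.
#' @param focal Character vector of focal species ids.
#' @param null_sets List of null sets from [draw_null_sets()] (may be empty).
#' @param responses data.frame of `response`/`growth_form` combinations.
#' @param epsilon Logit boundary adjustment.
#' @param min_obs Minimum observations per fit.
#' @return List with `results` (one row per response) and
#'   `null_coefficients` (one row per response x replicate).
#' @export
run_abundance_analysis <- function(cover, metrics, plots, focal,
                                   null_sets = list(),
                                   responses = .default_responses(),
                                   epsilon = 1e-6, min_obs = 10,
                                   compute_aic = TRUE) {
  cover <- data.table::as.data.table(cover)
  metrics <- data.table::as.data.table(metrics)
  plots <- data.table::as.data.table(plots)
  responses <- data.table::as.data.table(responses)
  meta <- plots[, .(plot_id, year = factor(year), park_id = factor(park_id),
                    ecoregion_l4 = factor(ecoregion_l4))]
  rterms <- c("year", "park_id", "ecoregion_l4")

  ## static response-plus-grouping base per response; per-set assembly then
  ## reduces to one grouped sum and an index match
  bases <- lapply(seq_len(nrow(responses)), function(i) {
    y <- .transform_metric(metrics[growth_form == responses$growth_form[i]],
                           responses$response[i], epsilon)
    as.data.frame(merge(y, meta, by = "plot_id"))
  })
  all_ids <- unique(c(focal, unlist(lapply(null_sets, `[[`, "species_ids"))))
  cover_sub <- cover[species_id %chin% all_ids]

  assemble <- function(set_ids, i) {
    a <- cover_sub[species_id %chin% set_ids,
                   .(cover_sum = sum(cover)), by = plot_id]
    base <- bases[[i]]
    idx <- match(a$plot_id, base$plot_id)
    ok <- !is.na(idx)
    d <- base[idx[ok], , drop = FALSE]
    d$x <- log(a$cover_sum[ok])
    d
  }

  results <- list()
  null_rows <- list()
  for (i in seq_len(nrow(responses))) {
    d_obs <- assemble(focal, i)
    obs <- fit_lmm(d_obs, rterms, reml = TRUE, min_obs = min_obs)
    if (compute_aic) {
      full_ml <- fit_lmm(d_obs, rterms, reml = FALSE, min_obs = min_obs)
      red_ml <- .fit_reduced_ml(d_obs, rterms, min_obs)
      da <- delta_aic(full_ml, red_ml)
    } else {
      full_ml <- red_ml <- list(aic = NA_real_)
      da <- list(delta = NA_real_, significant = NA)
    }
    r2 <- compute_r2(obs)

    betas <- rep(NA_real_, length(null_sets))
    conv <- rep(FALSE, length(null_sets))
    for (k in seq_along(null_sets)) {
      dk <- assemble(null_sets[[k]]$species_ids, i)
      fk <- tryCatch(
        .fit_beta_only(dk, rterms, start = obs$theta, min_obs = min_obs),
        error = function(e) NULL)
      if (!is.null(fk)) {
        betas[k] <- fk$beta1
        conv[k] <- fk$converged
      }
    }
    betas[!conv] <- NA_real_
    ep <- if (length(null_sets) > 0L) empirical_p(betas, obs$beta1) else
      list(p = NA_real_, n_used = 0L, n_failed = 0L, report = "no null sets")

    results[[i]] <- data.table::data.table(
      response = responses$response[i], growth_form = responses$growth_form[i],
      predictor = "log_abundance",
      n = obs$n_obs, beta1 = obs$beta1, se = obs$se1,
      marginal_r2 = r2["marginal"], conditional_r2 = r2["conditional"],
      aic_full = full_ml$aic, aic_reduced = red_ml$aic,
      delta_aic = da$delta, delta_aic_significant = da$significant,
      empirical_p = ep$p, p_report = ep$report,
      n_null = length(null_sets), n_null_converged = ep$n_used)
    if (length(null_sets) > 0L) {
      null_rows[[i]] <- data.table::data.table(
        response = responses$response[i],
        growth_form = responses$growth_form[i],
        replicate = seq_along(null_sets), beta1 = betas, converged = conv)
    }
  }
  list(results = data.table::rbindlist(results),
       null_coefficients = if (length(null_rows) > 0L)
         data.table::rbindlist(null_rows) else NULL)
}

## reduced model: same random structure, intercept-only fixed part, ML fit
.fit_reduced_ml <- function(data, random_terms, min_obs) {
  data <- as.data.frame(data)
  data <- data[is.finite(data$y) & is.finite(data$x), , drop = FALSE]
  keep <- character(0)
  for (term in random_terms) {
    data[[term]] <- factor(data[[term]])
    if (nlevels(droplevels(data[[term]])) >= 2L) keep <- c(keep, term)
  }
  if (length(keep) == 0L) {
    fit <- stats::lm(y ~ 1, data = data)
    return(structure(list(aic = AIC(fit), n_obs = nrow(data),
                          loglik = as.numeric(logLik(fit)), converged = TRUE),
                     class = "nullcomm_fit"))
  }
  fml <- as.formula(paste("y ~ 1 +",
                          paste(sprintf("(1 | %s)", keep), collapse = " + ")))
  fit <- suppressMessages(
    suppressWarnings(lme4::lmer(fml, data = data, REML = FALSE,
                                control = .fast_control())))
  structure(list(aic = AIC(fit), n_obs = nrow(data),
                 loglik = as.numeric(logLik(fit)), converged = TRUE),
            class = "nullcomm_fit")
}

#' Run the presence analysis on mutual-nearest-neighbour pairs
#'
#' For each response, fits a linear mixed model of the transformed response
#' on a presence indicator (the plot contains at least one member of the
#' focal set), with pair identity and survey year as random intercepts,
#' across all paired plots. The same path is rerun per null set to build the
#' empirical null distribution. A focal set present in every plot (or
#' absent from all) has no contrast and is an error for the observed set; a
#' null replicate with no contrast is counted as failed.
#'
#' @inheritParams run_abundance_analysis
#' @param pairs Pair table from [pair_plots()] (`$pairs`).
#' @return List with `results` and `null_coefficients` as in
#'   [run_abundance_analysis()] (no AIC screen: the presence contrast is
#'   assessed against its empirical null only).
#' @export
run_presence_analysis <- function(cover, metrics, plots, pairs, focal,
                                  null_sets = list(),
                                  responses = .default_responses(),
                                  epsilon = 1e-6, min_obs = 10) {
  cover <- data.table::as.data.table(cover)
  metrics <- data.table::as.data.table(metrics)
  plots <- data.table::as.data.table(plots)
  pairs <- data.table::as.data.table(pairs)
  responses <- data.table::as.data.table(responses)

  paired <- data.table::rbindlist(list(
    pairs[, .(pair_id, plot_id = plot_a)],
    pairs[, .(pair_id, plot_id = plot_b)]))
  meta <- merge(paired, plots[, .(plot_id, year)], by = "plot_id")
  meta[, `:=`(pair_id = factor(pair_id), year = factor(year))]
  rterms <- c("pair_id", "year")

  bases <- lapply(seq_len(nrow(responses)), function(i) {
    y <- .transform_metric(metrics[growth_form == responses$growth_form[i]],
                           responses$response[i], epsilon)
    as.data.frame(merge(y, meta, by = "plot_id"))
  })
  all_ids <- unique(c(focal, unlist(lapply(null_sets, `[[`, "species_ids"))))
  cover_sub <- cover[species_id %chin% all_ids]

  assemble <- function(set_ids, i) {
    present <- unique(cover_sub[species_id %chin% set_ids, plot_id])
    d <- bases[[i]]
    d$x <- as.numeric(d$plot_id %in% present)
    d
  }

  results <- list()
  null_rows <- list()
  for (i in seq_len(nrow(responses))) {
    d_obs <- assemble(focal, i)
    obs <- fit_lmm(d_obs, rterms, reml = TRUE, min_obs = min_obs)
    betas <- rep(NA_real_, length(null_sets))
    conv <- rep(FALSE, length(null_sets))
    for (k in seq_along(null_sets)) {
      dk <- assemble(null_sets[[k]]$species_ids, i)
      fk <- tryCatch(
        .fit_beta_only(dk, rterms, start = obs$theta, min_obs = min_obs),
        error = function(e) NULL)
      if (!is.null(fk)) {
        betas[k] <- fk$beta1
        conv[k] <- fk$converged
      }
    }
    betas[!conv] <- NA_real_
    ep <- if (length(null_sets) > 0L) empirical_p(betas, obs$beta1) else
      list(p = NA_real_, n_used = 0L, n_failed = 0L, report = "no null sets")

    results[[i]] <- data.table::data.table(
      response = responses$response[i], growth_form = responses$growth_form[i],
      predictor = "presence",
      n = obs$n_obs, beta1 = obs$beta1, se = obs$se1,
      marginal_r2 = compute_r2(obs)["marginal"],
      conditional_r2 = compute_r2(obs)["conditional"],
      aic_full = NA_real_, aic_reduced = NA_real_,
      delta_aic = NA_real_, delta_aic_significant = NA,
      empirical_p = ep$p, p_report = ep$report,
      n_null = length(null_sets), n_null_converged = ep$n_used)
    if (length(null_sets) > 0L) {
      null_rows[[i]] <- data.table::data.table(
        response = responses$response[i],
        growth_form = responses$growth_form[i],
        replicate = seq_along(null_sets), beta1 = betas, converged = conv)
    }
  }
  list(results = data.table::rbindlist(results),
       null_coefficients = if (length(null_rows) > 0L)
         data.table::rbindlist(null_rows) else NULL)
}
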