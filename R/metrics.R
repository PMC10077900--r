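## Per-plot community metrics: richness, Shannon evenness and summed cover,
## computed for all plants and within growth forms, plus the response
## transforms used in the mixed models.

#' Shannon evenness of a cover vector
#'
#' Computes Pielou's form of Shannon evenness, `E = H / ln(S)`, where `H` is
#' the Shannon entropy of relative covers `p_i = c_i / sum(c)` (natural log)
#' and `S` the number of species. Evenness is undefined for communities of
#' fewer than two species and `NA` is returned in that case: a single-species
#' plot has a defined richness but no meaningful evenness.
#'
#' @param covers Numeric vector of positive per-species covers.
#' @return Evenness in `[0, 1]`, or `NA_real_` when `length(covers) < 2`.
#' @examples
#' shannon_evenness(c(4, 4, 4, 4)) # 1: perfectly even
#' shannon_evenness(c(8, 2))       # 0.7219
#' @export
shannon_evenness <- function(covers) {
  if (length(covers) == 0L) return(NA_real_)
  if (any(!is.finite(covers)) || any(covers <= 0)) {
    stop("all covers must be positive and finite", call. = FALSE)
  }
  s <- length(covers)
  if (s < 2L) return(NA_real_)
  p <- covers / sum(covers)
  -sum(p * log(p)) / log(s)
}

#' Richness and total cover of a cover vector
#'
#' @param covers Numeric vector of per-species covers for one plot and growth
#'   form (possibly empty).
#' @return `richness()` the species count; `total_cover()` the summed cover.
#' @export
richness <- function(covers) length(covers)

#' @rdname richness
#' @export
total_cover <- function(covers) if (length(covers) == 0L) 0 else sum(covers)

#' Transform a response for modelling
#'
#' Richness is log transformed (natural log) and evenness logit transformed,
#' since evenness is bounded in `[0, 1]`. Boundary evenness values (0 or 1,
#' the latter attainable exactly with equal covers) are clamped to
#' `[epsilon, 1 - epsilon]` before the logit.
#'
#' @param value Numeric vector to transform. `NA`s propagate.
#' @param kind `"log"` or `"logit"`.
#' @param epsilon Boundary adjustment for the logit; default `1e-6`.
#' @return Transformed numeric vector.
#' @export
transform_response <- function(value, kind = c("log", "logit"), epsilon = 1e-6) {
  kind <- match.arg(kind)
  if (kind == "log") {
    if (any(value <= 0, na.rm = TRUE)) {
      stop("log transform requires positive values", call. = FALSE)
    }
    return(log(value))
  }
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("logit transform requires values in [0, 1]", call. = FALSE)
  }
  v <- pmin(pmax(value, epsilon), 1 - epsilon)
  log(v / (1 - v))
}

#' Per-plot community metrics by growth form
#'
#' Computes richness, Shannon evenness and total summed cover for each plot
#' and growth form (`"all"`, `"herbaceous"`, `"woody"`). Species whose growth
#' form is `"excluded"` take no part in any growth form, including `"all"`.
#' Every retained plot appears in the output for every growth form, so a plot
#' with no woody species carries `richness = 0`, `total_cover = 0` and
#' `NA` evenness for the woody rows; single-species communities likewise have
#' `NA` evenness.
#'
#' @param cover Consolidated cover table (one row per plot x species), e.g.
#'   from [filter_plots()].
#' @param species Classified species catalog from [classify_growth_form()].
#' @param plots Plot table; defines the set of output plots.
#' @return data.table with columns
#'   `plot_id, growth_form, richness, evenness, total_cover`.
#' @export
community_metrics <- function(cover, species, plots) {
  stopifnot("growth_form" %in% names(species))
  cover <- data.table::as.data.table(cover)
  species <- data.table::as.data.table(species)
  plots <- data.table::as.data.table(plots)

  dt <- merge(cover, species[, .(species_id, growth_form)],
              by = "species_id", all.x = FALSE)
  dt <- dt[growth_form != "excluded"]

  ## vectorised evenness: group sums once, entropy terms in bulk
  one_form <- function(d, label) {
    d <- d[, .(plot_id, cover)]
    d[, total_cover := sum(cover), by = plot_id]
    d[, h_term := {p <- cover / total_cover; -p * log(p)}]
    m <- d[, .(richness = .N, h = sum(h_term), total_cover = total_cover[1L]),
           by = plot_id]
    m[, evenness := ifelse(richness >= 2L, h / log(richness), NA_real_)]
    m[, h := NULL]
    m[, growth_form := label]
    m
  }
  res <- data.table::rbindlist(list(
    one_form(dt, "all"),
    one_form(dt[growth_form == "herbaceous"], "herbaceous"),
    one_form(dt[growth_form == "woody"], "woody")
  ))

  ## complete the plot x growth-form grid with empty communities
  grid <- data.table::CJ(plot_id = plots$plot_id,
                         growth_form = c("all", "herbaceous", "woody"))
  res <- merge(grid, res, by = c("plot_id", "growth_form"), all.x = TRUE)
  res[is.na(richness), `:=`(richness = 0L, total_cover = 0)]
  data.table::setcolorder(res, c("plot_id", "growth_form", "richness",
                                 "evenness", "total_cover"))
  res[]
}
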