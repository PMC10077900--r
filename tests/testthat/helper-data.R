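## shared test data, built once per session

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

tiny_sim <- function() cached("tiny_sim", make_fixture("tiny_null"))

tiny_sim_classified <- function() {
  cached("tiny_cls", {
    sim <- tiny_sim()
    list(sim = sim, species = classify_growth_form(sim$species))
  })
}

## brute-force O(n^2) mutual-nearest-neighbour oracle, independent of the
## implementation: distances from geosphere, explicit double scan
oracle_mutual_nn <- function(plots) {
  plots <- as.data.frame(plots)
  out <- list()
  for (eco in unique(plots$ecoregion_l4)) {
    sub <- plots[plots$ecoregion_l4 == eco, , drop = FALSE]
    sub <- sub[order(sub$plot_id), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    nn <- integer(n); nd <- numeric(n)
    pts <- cbind(sub$longitude, sub$latitude)
    for (i in seq_len(n)) {
      d <- geosphere::distHaversine(pts[i, ], pts, r = 6371008.8) / 1000
      d[i] <- Inf
      nn[i] <- which.min(d)   # first index on ties = lexicographic plot_id
      nd[i] <- d[nn[i]]
    }
    for (i in seq_len(n)) {
      j <- nn[i]
      if (nn[j] == i && i < j && nd[i] > 0) {
        out[[length(out) + 1L]] <- data.frame(
          plot_a = sub$plot_id[i], plot_b = sub$plot_id[j],
          distance_km = nd[i], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(plot_a = character(), plot_b = character(),
                      distance_km = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$plot_a), , drop = FALSE]
}

## random plot layouts for pairing tests; optionally inject duplicate
## coordinates and singleton ecoregions
random_plot_layout <- function(n, n_eco = 3L, dup_frac = 0.05) {
  eco <- sample(sprintf("E%02d", seq_len(n_eco)), n, replace = TRUE)
  lat <- runif(n, 35, 45)
  lon <- runif(n, -110, -90)
  n_dup <- floor(n * dup_frac)
  if (n_dup > 0L && n > 2L) {
    src <- sample(seq_len(n), n_dup, replace = TRUE)
    dst <- sample(seq_len(n), n_dup)
    lat[dst] <- lat[src]; lon[dst] <- lon[src]; eco[dst] <- eco[src]
  }
  data.frame(plot_id = sprintf("p%04d", seq_len(n)),
             latitude = lat, longitude = lon,
             area_m2 = 400, year = 2000L, park_id = "P1",
             ecoregion_l4 = eco, stringsAsFactors = FALSE)
}

## brute-force Shannon evenness: explicit loop over the p_i
oracle_evenness <- function(covers) {
  s <- length(covers)
  if (s < 2L) return(NA_real_)
  tot <- 0
  for (c_i in covers) tot <- tot + c_i
  h <- 0
  for (c_i in covers) {
    p <- c_i / tot
    h <- h - p * log(p)
  }
  h / log(s)
}

## assemble abundance-model data (transformed response + log set cover +
## grouping columns) outside the package's own code path
assemble_abundance_data <- function(sim, metrics, set_ids,
                                    response = "evenness",
                                    growth_form = "herbaceous") {
  cov <- as.data.frame(sim$cover)
  a <- aggregate(cover ~ plot_id, data = cov[cov$species_id %in% set_ids, ],
                 FUN = sum)
  m <- as.data.frame(metrics)
  m <- m[m$growth_form == growth_form, ]
  d <- merge(m, a, by = "plot_id")
  if (response == "evenness") {
    d <- d[!is.na(d$evenness), ]
    d$y <- transform_response(d$evenness, "logit")
  } else {
    d <- d[d$richness > 0, ]
    d$y <- transform_response(as.numeric(d$richness), "log")
  }
  d$x <- log(d$cover)
  merge(d, as.data.frame(sim$plots), by = "plot_id")
}
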