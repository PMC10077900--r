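## Mutual-nearest-neighbour plot pairing within Level IV ecoregions.
##
## Presence contrasts compare each plot with its closest neighbour in the
## same ecoregion, but only when the relationship is mutual: a plot whose
## nearest neighbour is itself closer to a third plot is discarded, as are
## pairs whose members share identical coordinates (distance zero).

.earth_radius_km <- 6371.0088

#' Great-circle distance between points (haversine)
#'
#' Distance on a sphere of radius 6371.0088 km (the IUGG mean Earth radius).
#' Vectorised over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.195 km, one degree along the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range", call. = FALSE)
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * .earth_radius_km * asin(pmin(1, sqrt(a)))
}

## full pairwise distance matrix for one ecoregion (n x n, diagonal Inf)
.distance_matrix_km <- function(lat, lon) {
  n <- length(lat)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- haversine_km(lat[i], lon[i], lat, lon)
  }
  diag(m) <- Inf
  m
}

#' Pair plots by mutual nearest neighbour within ecoregion
#'
#' For every ecoregion with at least two plots, computes each plot's nearest
#' neighbour (great-circle distance; ties broken lexicographically by
#' `plot_id`) and keeps only mutual pairs. Pairs whose members have identical
#' coordinates are then removed, with both members discarded. A single pass
#' is made: discarded plots are not re-paired.
#'
#' @param plots Plot table with `plot_id, latitude, longitude, ecoregion_l4`.
#' @return List with `pairs` (data.table:
#'   `pair_id, plot_a, plot_b, ecoregion_l4, distance_km`) and `discards`
#'   (data.table: `plot_id, reason` with reasons `"singleton_ecoregion"`,
#'   `"non_mutual"`, `"zero_distance"`).
#' @export
pair_plots <- function(plots) {
  plots <- data.table::as.data.table(plots)
  stopifnot(all(c("plot_id", "latitude", "longitude", "ecoregion_l4") %in%
                  names(plots)))
  pair_list <- list()
  disc_list <- list()

  for (eco in unique(plots$ecoregion_l4)) {
    sub <- plots[ecoregion_l4 == eco]
    data.table::setorder(sub, plot_id)  # lexicographic tie-break via which.min
    n <- nrow(sub)
    if (n < 2L) {
      disc_list[[length(disc_list) + 1L]] <-
        data.table::data.table(plot_id = sub$plot_id, reason = "singleton_ecoregion")
      next
    }
    dm <- .distance_matrix_km(sub$latitude, sub$longitude)
    nn <- apply(dm, 1L, which.min)
    mutual <- which(nn[nn] == seq_len(n) & seq_len(n) < nn)
    non_mutual <- setdiff(seq_len(n), c(mutual, nn[mutual]))
    if (length(non_mutual) > 0L) {
      disc_list[[length(disc_list) + 1L]] <-
        data.table::data.table(plot_id = sub$plot_id[non_mutual], reason = "non_mutual")
    }
    if (length(mutual) > 0L) {
      a <- mutual
      b <- nn[mutual]
      d <- dm[cbind(a, b)]
      zero <- d <= 0
      if (any(zero)) {
        disc_list[[length(disc_list) + 1L]] <- data.table::data.table(
          plot_id = c(sub$plot_id[a[zero]], sub$plot_id[b[zero]]),
          reason = "zero_distance")
      }
      if (any(!zero)) {
        pair_list[[length(pair_list) + 1L]] <- data.table::data.table(
          plot_a = sub$plot_id[a[!zero]],
          plot_b = sub$plot_id[b[!zero]],
          ecoregion_l4 = eco,
          distance_km = d[!zero])
      }
    }
  }

  pairs <- if (length(pair_list) > 0L) data.table::rbindlist(pair_list) else
    data.table::data.table(plot_a = character(), plot_b = character(),
                           ecoregion_l4 = character(), distance_km = numeric())
  discards <- if (length(disc_list) > 0L) data.table::rbindlist(disc_list) else
    data.table::data.table(plot_id = character(), reason = character())
  data.table::setorder(pairs, plot_a)
  pairs[, pair_id := sprintf("pair_%05d", seq_len(.N))]
  data.table::setcolorder(pairs, c("pair_id", "plot_a", "plot_b",
                                   "ecoregion_l4", "distance_km"))
  list(pairs = pairs[], discards = discards[])
}
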