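#' Construct a region table
#'
#' A region table holds one row per areal unit (e.g. a ZCTA): its identifier,
#' an optional population centroid in decimal degrees, an optional population
#' count, and a flag saying whether the region carries a usable centroid.
#' Regions with zero population receive no population centroid and are
#' omitted from graph construction, although individual records assigned to
#' them are never dropped.
#'
#' @param region_id character vector of unique region identifiers. Treated as
#'   opaque strings; leading zeros (as in ZCTA codes) are preserved.
#' @param lon,lat numeric centroid coordinates in decimal degrees, or `NA`
#'   for regions without a centroid.
#' @param population optional nonnegative population counts.
#' @return A `data.frame` of class `region_table` with columns `region_id`,
#'   `lon`, `lat`, `population`, `has_centroid`.
#' @export
region_table <- function(region_id, lon = NA_real_, lat = NA_real_,
                         population = NA_real_) {
  region_id <- as.character(region_id)
  if (anyDuplicated(region_id))
    stop("region_id values must be unique", call. = FALSE)
  n <- length(region_id)
  lon <- rep_len(as.numeric(lon), n)
  lat <- rep_len(as.numeric(lat), n)
  population <- rep_len(as.numeric(population), n)
  if (any(population < 0, na.rm = TRUE))
    stop("populations must be nonnegative", call. = FALSE)
  out <- data.frame(
    region_id = region_id, lon = lon, lat = lat,
    population = population,
    has_centroid = is.finite(lon) & is.finite(lat),
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_table", "data.frame")
  out
}

#' Population-weighted region centroids
#'
#' Computes, for each region, the weighted arithmetic mean of the longitudes
#' and latitudes of a set of weighted points (for example high-resolution
#' population point estimates falling inside the region). Regions whose
#' points carry zero total weight get no centroid (`has_centroid = FALSE`),
#' mirroring the treatment of zero-population areal units.
#'
#' @param points a `data.frame` with columns `lon`, `lat`, `weight`.
#' @param region_assignment character vector assigning each point to a
#'   region id (recycled against `points` rows).
#' @return A [region_table] with one row per distinct region, total point
#'   weight reported as `population`.
#' @export
population_weighted_centroid <- function(points, region_assignment) {
  if (nrow(points) == 0L) {
    warning("empty point set; returning empty region table")
    return(region_table(character(0)))
  }
  stopifnot(all(c("lon", "lat", "weight") %in% names(points)))
  if (any(points$weight < 0, na.rm = TRUE))
    stop("point weights must be nonnegative", call. = FALSE)
  region <- rep_len(as.character(region_assignment), nrow(points))
  ids <- sort(unique(region))
  w_tot <- vapply(ids, function(r) sum(points$weight[region == r]), 0)
  cx <- cy <- rep(NA_real_, length(ids))
  ok <- w_tot > 0
  for (i in which(ok)) {
    sel <- region == ids[i]
    w <- points$weight[sel]
    cx[i] <- sum(w * points$lon[sel]) / w_tot[i]
    cy[i] <- sum(w * points$lat[sel]) / w_tot[i]
  }
  region_table(ids, lon = cx, lat = cy, population = w_tot)
}
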