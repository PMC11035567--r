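#' Construct and validate a travel-time matrix
#'
#' A travel-time matrix is a square numeric matrix with region ids as
#' dimnames, zero diagonal and nonnegative entries in minutes (or miles in
#' distance mode). `NA` entries mean "no route" and the pair is treated as
#' not neighbors downstream. Matrices from routing engines may be asymmetric;
#' symmetrize with [symmetrize_travel_times()] before building a graph.
#'
#' @param t square numeric matrix of pairwise times.
#' @param regions ordered character vector of region ids; defaults to
#'   `rownames(t)`.
#' @return the validated matrix with dimnames set to `regions`.
#' @export
travel_time_matrix <- function(t, regions = rownames(t)) {
  t <- as.matrix(t)
  if (nrow(t) != ncol(t))
    stop("travel-time matrix must be square", call. = FALSE)
  if (is.null(regions))
    stop("region ids required (supply `regions` or rownames)", call. = FALSE)
  regions <- as.character(regions)
  if (length(regions) != nrow(t))
    stop("length of region ids does not match matrix dimension", call. = FALSE)
  dimnames(t) <- list(regions, regions)
  if (any(diag(t) != 0, na.rm = TRUE))
    stop("travel-time matrix must have a zero diagonal", call. = FALSE)
  if (any(t < 0, na.rm = TRUE))
    stop("travel times must be nonnegative", call. = FALSE)
  t
}

#' Symmetrize a travel-time matrix
#'
#' Drive times returned by routing engines need not be direction-symmetric,
#' while the graph Laplacian penalty requires a symmetric adjacency. Each
#' unordered pair is replaced by `rule` applied to the two directed times;
#' if exactly one direction is missing the present value is used, and a pair
#' missing in both directions stays missing.
#'
#' @param t travel-time matrix (see [travel_time_matrix()]).
#' @param rule one of `"mean"` (default), `"min"`, `"max"`.
#' @return a symmetric travel-time matrix.
#' @export
symmetrize_travel_times <- function(t, rule = c("mean", "min", "max")) {
  rule <- match.arg(rule)
  t <- travel_time_matrix(t)
  f <- switch(rule, mean = function(a, b) (a + b) / 2, min = pmin, max = pmax)
  tt <- t(t)
  out <- f(t, tt)
  only_one <- is.na(t) != is.na(tt)
  out[only_one] <- ifelse(is.na(t[only_one]), tt[only_one], t[only_one])
  out[is.na(t) & is.na(tt)] <- NA_real_
  diag(out) <- 0
  out
}

# mean Earth radius in miles; 1 degree of longitude at the equator is then
# 2*pi*R/360 ~ 69.09 miles
.EARTH_RADIUS_MILES <- 3958.756

#' Great-circle distances between region centroids
#'
#' Haversine distances in miles between all pairs of region centroids, for
#' the Euclidean-threshold neighborhood mode used when drive times are not
#' available. Regions without a centroid are excluded with a warning.
#'
#' @param regions a [region_table].
#' @return symmetric matrix of distances in miles with zero diagonal,
#'   dimnames the retained region ids.
#' @export
great_circle_distances <- function(regions) {
  keep <- regions$has_centroid
  if (!all(keep))
    warning(sum(!keep), " region(s) without centroid excluded from distances")
  r <- regions[keep, , drop = FALSE]
  s <- nrow(r)
  coords <- cbind(r$lon, r$lat)
  d <- matrix(0, s, s, dimnames = list(r$region_id, r$region_id))
  if (s > 1) {
    for (i in seq_len(s))
      d[i, ] <- geosphere::distHaversine(coords[i, ], coords,
                                         r = .EARTH_RADIUS_MILES)
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  d
}

#' Read a travel-time CSV
#'
#' Accepts either long format (`from_id,to_id,minutes` — any third column
#' name) or wide format (square table whose header row and first column hold
#' region ids); the layout is auto-detected. Pairs absent from a long file
#' are `NA` ("no route").
#'
#' @param path CSV file path.
#' @return travel-time matrix with region-id dimnames.
#' @export
read_travel_times <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  is_long <- ncol(df) == 3 &&
    grepl("^from", tolower(names(df)[1])) &&
    grepl("^to", tolower(names(df)[2]))
  if (is_long) {
    from <- as.character(df[[1]]); to <- as.character(df[[2]])
    val <- as.numeric(df[[3]])
    ids <- sort(unique(c(from, to)))
    t <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    t[cbind(from, to)] <- val
    diag(t) <- 0
    return(travel_time_matrix(t))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  m[!nzchar(m)] <- NA_character_
  storage.mode(m) <- "double"
  travel_time_matrix(m, regions = ids)
}

#' Write a travel-time matrix as a wide CSV
#'
#' @param t travel-time matrix.
#' @param path output file path.
#' @export
write_travel_times <- function(t, path) {
  df <- data.frame(region_id = rownames(t), t, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
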