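#' Specify the neighborhood kernel
#'
#' Two regions are neighbors when the (symmetrized) travel time between
#' their population centroids is at most `threshold`. Within that ball the
#' edge weight is either constant (`binary`) or decays as a truncated
#' Gaussian in travel time (`gaussian`), so that closer regions exert more
#' influence on each other's effect estimates.
#'
#' @param kind `"gaussian"` (default) or `"binary"`.
#' @param threshold neighbor cutoff, in minutes (travel-time mode) or miles
#'   (distance mode). Default 30 minutes, matching typical one-way commute
#'   and care-seeking travel times.
#' @param bandwidth Gaussian bandwidth `h` in the same units as `threshold`;
#'   the weight at distance `t` is `exp(-t^2 / (2 h^2))`. Default
#'   `threshold / 2`, giving weight `exp(-2)` (about 0.135) at the cutoff.
#' @param units unit label recorded to prevent mixing time and distance
#'   thresholds.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("gaussian", "binary"), threshold = 30,
                        bandwidth = threshold / 2,
                        units = c("minutes", "miles")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  if (kind == "gaussian" && bandwidth <= 0)
    stop("bandwidth must be positive", call. = FALSE)
  structure(list(kind = kind, threshold = threshold,
                 bandwidth = if (kind == "gaussian") bandwidth else NA_real_,
                 units = units),
            class = "kernel_spec")
}

#' Build a weighted adjacency matrix from symmetric travel times
#'
#' Applies the kernel to each off-diagonal entry: zero beyond the threshold,
#' `exp(-t^2/(2 h^2))` (gaussian) or 1 (binary) within it. Missing travel
#' times yield weight 0 (unreachable pairs are not neighbors). Self-loops
#' are forbidden: the diagonal of the result is 0.
#'
#' @param t_sym symmetric travel-time (or distance) matrix with zero
#'   diagonal; symmetrize asymmetric drive times first with
#'   [symmetrize_travel_times()].
#' @param kernel a [kernel_spec].
#' @return symmetric nonnegative weight matrix `A` with zero diagonal.
#' @export
build_adjacency <- function(t_sym, kernel = kernel_spec()) {
  t_sym <- travel_time_matrix(t_sym)
  if (!isTRUE(all.equal(t_sym, t(t_sym))) ||
      !identical(is.na(t_sym), is.na(t(t_sym))))
    stop("travel times are asymmetric; apply symmetrize_travel_times() first",
         call. = FALSE)
  a <- matrix(0, nrow(t_sym), ncol(t_sym), dimnames = dimnames(t_sym))
  within <- !is.na(t_sym) & t_sym <= kernel$threshold
  if (kernel$kind == "binary") {
    a[within] <- 1
  } else {
    a[within] <- exp(-t_sym[within]^2 / (2 * kernel$bandwidth^2))
  }
  diag(a) <- 0
  a
}

#' Build the neighborhood graph and its Laplacian
#'
#' From a symmetric weighted adjacency matrix `A` this forms the degree
#' matrix `D` (`D_ss = sum_s' A_ss'`), the graph Laplacian `L = D - A`,
#' the neighbor sets, and connected-component labels. The Laplacian's
#' quadratic form `a' L a = 1/2 sum_ss' A_ss' (a_s - a_s')^2` is the
#' penalty that smooths region effects toward their neighbors.
#'
#' @param a symmetric nonnegative weight matrix with zero diagonal and
#'   region-id dimnames.
#' @param kernel optional [kernel_spec] recorded for provenance.
#' @return object of class `areal_graph`: list with `regions`, `A`, `D`,
#'   `L`, `neighbors` (named list of region-id character vectors) and
#'   `component` (integer component label per region).
#' @export
build_laplacian <- function(a, kernel = NULL) {
  a <- as.matrix(a)
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("R", seq_len(nrow(a))),
                        paste0("R", seq_len(nrow(a))))
  if (nrow(a) != ncol(a) || !isTRUE(all.equal(a, t(a), tolerance = 1e-12)))
    stop("adjacency must be a symmetric square matrix", call. = FALSE)
  if (any(a < 0)) stop("adjacency weights must be nonnegative", call. = FALSE)
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  a <- (a + t(a)) / 2  # remove floating-point asymmetry
  d <- rowSums(a)
  l <- diag(d, nrow(a)) - a
  dimnames(l) <- dimnames(a)
  regions <- rownames(a)
  neighbors <- lapply(seq_len(nrow(a)), function(s) regions[a[s, ] > 0])
  names(neighbors) <- regions
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)$membership
  structure(list(regions = regions, A = a, D = d, L = l,
                 neighbors = neighbors,
                 component = as.integer(comp[regions]),
                 kernel = kernel),
            class = "areal_graph")
}

#' @export
print.areal_graph <- function(x, ...) {
  cat("areal_graph:", length(x$regions), "regions,",
      sum(x$A > 0) / 2, "edges,",
      max(x$component), "connected component(s)\n")
  invisible(x)
}

#' Classify regions by estimability
#'
#' With the Laplacian penalty, a region's spatial effect is estimable when
#' the region has observations, or when some region in its connected
#' component does (information then flows along graph edges). A region with
#' zero observations is `empty_smoothable` if its component contains
#' observations, and `non_estimable` if it has no neighbors or its whole
#' component is unobserved — the situations in which the model cannot
#' produce an effect estimate.
#'
#' @param graph an `areal_graph`.
#' @param counts integer vector of per-region observation counts, either
#'   named by region id or aligned to `graph$regions`.
#' @return `data.frame` with `region_id`, `n_s`, `degree`, `component`,
#'   `status` (one of `observed`, `empty_smoothable`, `non_estimable`).
#' @export
connectivity_report <- function(graph, counts) {
  s <- length(graph$regions)
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), graph$regions))
      stop("count names do not match graph regions", call. = FALSE)
    counts <- counts[graph$regions]
  } else if (length(counts) != s) {
    stop("counts are not aligned with graph regions", call. = FALSE)
  }
  counts <- as.integer(counts)
  comp_has_obs <- tapply(counts > 0, graph$component, any)
  has_nb <- vapply(graph$neighbors, length, 0L) > 0
  status <- ifelse(counts > 0, "observed",
            ifelse(has_nb & comp_has_obs[as.character(graph$component)],
                   "empty_smoothable", "non_estimable"))
  data.frame(region_id = graph$regions, n_s = counts,
             degree = unname(graph$D), component = graph$component,
             status = unname(status), stringsAsFactors = FALSE)
}

#' Export a neighborhood graph as an edge list plus JSON sidecar
#'
#' Writes `from_id,to_id,weight` rows (each undirected edge once, ordered
#' ids) and a JSON sidecar with the kernel specification and component
#' labels.
#'
#' @param graph an `areal_graph`.
#' @param path edge-list CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @export
write_graph <- function(graph, path) {
  idx <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  edges <- data.frame(from_id = graph$regions[idx[, 1]],
                      to_id = graph$regions[idx[, 2]],
                      weight = graph$A[idx], stringsAsFactors = FALSE)
  utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(kernel = if (is.null(graph$kernel)) NULL
                           else unclass(graph$kernel),
                  regions = graph$regions,
                  component = graph$component)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Moran's I spatial autocorrelation over a neighborhood graph
#'
#' Standard Moran's I of a region-level variable with the graph's adjacency
#' as spatial weights; used to verify that simulated region effects are
#' positively spatially autocorrelated.
#'
#' @param x numeric vector aligned with `graph$regions`.
#' @param graph an `areal_graph`.
#' @return Moran's I statistic.
#' @export
moran_i <- function(x, graph) {
  z <- x - mean(x)
  w <- graph$A
  s0 <- sum(w)
  if (s0 == 0) stop("graph has no edges", call. = FALSE)
  length(z) * as.numeric(t(z) %*% w %*% z) / (s0 * sum(z^2))
}
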