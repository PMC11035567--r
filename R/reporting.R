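#' Rank regions by estimated spatial effect
#'
#' Ranks the estimable regions by the sum-to-zero effect deviation
#' `alpha_tilde` in descending order (rank 1 = highest effect = greatest
#' expected improvement in the outcome from residing there). Ties are
#' broken by lexicographic region id so the table is deterministic under
#' permutation of its input. Ranking by `alpha_tilde` or by `alpha_hat` is
#' equivalent — they differ by the constant overall level.
#'
#' @param fit an `areal_fit`, or a named numeric vector of effects (then
#'   `counts` supplies `n_s`).
#' @param counts optional named per-region observation counts.
#' @param quintile_k number of ranking bins (default 5 quintiles).
#' @return `data.frame` with `region_id`, `alpha_tilde`, `rank`, `quintile`,
#'   `n_s`, `estimability`; non-estimable regions carry `NA` rank.
#' @export
rank_regions <- function(fit, counts = NULL, quintile_k = 5) {
  if (inherits(fit, "areal_fit")) {
    eff <- fit$alpha_tilde
    counts <- stats::setNames(fit$estimability$n_s,
                              fit$estimability$region_id)[names(eff)]
    status <- stats::setNames(fit$estimability$status,
                              fit$estimability$region_id)[names(eff)]
  } else {
    eff <- fit
    if (is.null(names(eff)))
      names(eff) <- paste0("R", seq_along(eff))
    if (is.null(counts)) counts <- stats::setNames(rep(NA_integer_,
                                                       length(eff)),
                                                   names(eff))
    status <- ifelse(is.na(eff), "non_estimable",
                     ifelse(is.na(counts[names(eff)]) |
                            counts[names(eff)] > 0,
                            "observed", "empty_smoothable"))
  }
  est <- !is.na(eff)
  if (!any(est)) stop("no estimable effects to rank", call. = FALSE)
  ord <- order(-eff, names(eff), na.last = TRUE)
  rank <- stats::setNames(rep(NA_integer_, length(eff)), names(eff))
  rank[ord[seq_len(sum(est))]] <- seq_len(sum(est))
  quint <- stats::setNames(rep(NA_integer_, length(eff)), names(eff))
  if (sum(est) >= quintile_k)
    quint[est] <- quintile_bins(eff[est], k = quintile_k)
  out <- data.frame(region_id = names(eff), alpha_tilde = unname(eff),
                    rank = unname(rank), quintile = unname(quint),
                    n_s = unname(counts[names(eff)]),
                    estimability = unname(status),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$region_id, na.last = TRUE), , drop = FALSE]
}

#' Rank-based quantile bins
#'
#' Partitions values into `k` near-equal groups by rank. Bin `k` holds the
#' highest effects and bin 1 the lowest; when the count is not divisible by
#' `k` the larger bins are allocated from the top down. Ties in value are
#' broken by name (lexicographic) for determinism.
#'
#' @param effects named numeric vector without `NA`.
#' @param k number of bins, default 5 (quintiles).
#' @return integer vector of bin labels aligned with `effects`.
#' @export
quintile_bins <- function(effects, k = 5) {
  m <- length(effects)
  if (m < k)
    stop("fewer values (", m, ") than bins (", k,
         "); use a smaller k", call. = FALSE)
  if (is.null(names(effects))) names(effects) <- paste0("R", seq_len(m))
  ord <- order(-effects, names(effects))  # descending; rank 1 first
  base <- m %/% k
  extra <- m %% k
  sizes <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
  labels_desc <- rep(k:1, times = sizes)  # top bin = k for the best ranks
  bins <- integer(m)
  bins[ord] <- labels_desc
  stats::setNames(bins, names(effects))
}

#' Winsorize effects for display
#'
#' Clips values to `mean +/- c * sd` of the estimable effects, with the
#' mean and standard deviation computed before clipping over the estimable
#' entries only. Intended for choropleth display: the underlying estimates
#' are never altered. With the default `c = 3` only effects beyond three
#' standard deviations move.
#'
#' The clip bounds are computed from the pre-clip estimable values and are
#' attached to the result (attribute `winsor_bounds`), so re-applying the
#' transform to an already-winsorized vector reuses the original bounds and
#' is an exact no-op.
#'
#' @param effects numeric vector, `NA` allowed.
#' @param c clip width in standard deviations (default 3; `Inf` = identity).
#' @param sd_type `"population"` (default, divisor `n`) or `"sample"`.
#' @return vector of the same shape with extreme values clipped.
#' @export
winsorize_for_display <- function(effects, c = 3,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (!is.finite(c)) return(effects)
  bounds <- attr(effects, "winsor_bounds")
  if (is.null(bounds)) {
    est <- !is.na(effects)
    if (sum(est) < 2) stop("need at least 2 estimable values", call. = FALSE)
    mu <- mean(effects[est])
    sdv <- stats::sd(effects[est])
    if (sd_type == "population")
      sdv <- sdv * sqrt((sum(est) - 1) / sum(est))
    bounds <- c(mu - c * sdv, mu + c * sdv)
  }
  out <- pmin(pmax(effects, bounds[1]), bounds[2])
  attributes(out) <- attributes(effects)
  attr(out, "winsor_bounds") <- bounds
  out
}

#' Effect ranges for observed versus empty regions
#'
#' Reports the (min, max) of the untrimmed effect estimates within each
#' estimability class, plus flags for effects beyond 3 standard deviations
#' of the estimable mean — the regions a display would clip.
#'
#' @param effects named numeric effect vector (`alpha_hat` or
#'   `alpha_tilde`), `NA` for non-estimable regions.
#' @param counts named or aligned per-region observation counts.
#' @return list with `observed` and `empty` `(min, max)` ranges (`NA` when
#'   the class is empty) and `outliers`, the region ids beyond 3 sd.
#' @export
effect_range_summary <- function(effects, counts) {
  if (length(effects) != length(counts))
    stop("effects and counts are not aligned", call. = FALSE)
  if (!is.null(names(effects)) && !is.null(names(counts)))
    counts <- counts[names(effects)]
  est <- !is.na(effects)
  rng <- function(v) if (length(v)) c(min = min(v), max = max(v))
                     else c(min = NA_real_, max = NA_real_)
  obs <- est & counts > 0
  emp <- est & counts == 0
  mu <- mean(effects[est])
  sdv <- stats::sd(effects[est]) * sqrt((sum(est) - 1) / sum(est))
  out_ids <- names(effects)[est & abs(effects - mu) > 3 * sdv]
  list(observed = rng(effects[obs]), empty = rng(effects[emp]),
       outliers = if (is.null(out_ids)) character(0) else out_ids)
}
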