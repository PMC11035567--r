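#' Specify the categorical design
#'
#' Lists the categorical covariates in model order, each with an ordered set
#' of levels and a designated reference level. The design matrix carries one
#' dummy column per non-reference level and deliberately no intercept
#' column: the per-region spatial effect `alpha_s` plays the role of the
#' intercept, and the overall level `alpha_0` is recovered afterwards by
#' [decompose_effects()].
#'
#' @param variables named list; each element is a character vector of levels
#'   for that variable (at least two).
#' @param reference named character vector (or single unnamed value per
#'   variable) of reference levels; defaults to each variable's first level.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(variables, reference = NULL) {
  stopifnot(is.list(variables), length(names(variables)) == length(variables))
  for (v in names(variables)) {
    lev <- variables[[v]]
    if (length(lev) < 2)
      stop("variable '", v, "' needs at least 2 levels", call. = FALSE)
    if (anyDuplicated(lev))
      stop("variable '", v, "' has duplicated levels", call. = FALSE)
  }
  ref <- vapply(names(variables), function(v) {
    r <- if (!is.null(reference) && v %in% names(reference))
      reference[[v]] else variables[[v]][1]
    if (!r %in% variables[[v]])
      stop("reference level '", r, "' not among levels of '", v, "'",
           call. = FALSE)
    r
  }, "")
  structure(list(variables = variables, reference = ref),
            class = "design_spec")
}

#' Dummy-coded column labels of a design spec
#' @param spec a `design_spec`.
#' @return character vector `variable:level` in deterministic model order.
#' @export
design_terms <- function(spec) {
  unlist(lapply(names(spec$variables), function(v) {
    lev <- setdiff(spec$variables[[v]], spec$reference[[v]])
    paste(v, lev, sep = ":")
  }), use.names = FALSE)
}

#' Encode records into design matrices
#'
#' Builds the covariate dummy matrix `X` (n x p, no intercept), the region
#' incidence matrix `Z` (n x S, exactly one 1 per row, columns ordered as
#' `regions` and including all-zero columns for regions without records),
#' and the outcome vector `y`.
#'
#' @param records `data.frame` with columns `region_id`, `outcome`, and one
#'   column per design variable.
#' @param spec a [design_spec].
#' @param regions ordered character vector of all region ids.
#' @return list of class `areal_design`: `X`, `Z`, `y`, `regions`, `spec`,
#'   `n_s` (named per-region counts).
#' @export
encode_design <- function(records, spec, regions) {
  regions <- as.character(regions)
  if (!all(records$region_id %in% regions)) {
    bad <- setdiff(unique(records$region_id), regions)
    stop("records reference unknown region(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  x <- encode_covariates(records, spec)
  z <- matrix(0, n, length(regions), dimnames = list(NULL, regions))
  z[cbind(seq_len(n), match(as.character(records$region_id), regions))] <- 1
  y <- as.numeric(records$outcome)
  n_s <- colSums(z)
  structure(list(X = x, Z = z, y = y, regions = regions, spec = spec,
                 n_s = n_s),
            class = "areal_design")
}

# dummy-code covariates only (used by encode_design and predict)
encode_covariates <- function(records, spec) {
  n <- nrow(records)
  cols <- design_terms(spec)
  x <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (v in names(spec$variables)) {
    if (!v %in% names(records))
      stop("records lack design variable '", v, "'", call. = FALSE)
    vals <- as.character(records[[v]])
    unseen <- !vals %in% spec$variables[[v]]
    if (any(unseen))
      stop("unseen level '", vals[which(unseen)[1]], "' of variable '", v,
           "' at record ", which(unseen)[1], call. = FALSE)
    for (lev in setdiff(spec$variables[[v]], spec$reference[[v]]))
      x[vals == lev, paste(v, lev, sep = ":")] <- 1
  }
  x
}
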