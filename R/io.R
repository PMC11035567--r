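#' Read an individual-records CSV
#'
#' Expects at least `region_id` (or `zip_code`) and `outcome` columns plus
#' one column per demographic variable. Region identifiers are read as
#' character so ZCTA codes keep their leading zeros.
#'
#' @param path CSV path.
#' @return `data.frame` of records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if ("outcome" %in% names(df)) df$outcome <- as.numeric(df$outcome)
  df
}

#' Read a region-table CSV (`region_id,lon,lat,population`)
#' @param path CSV path.
#' @return a [region_table].
#' @export
read_regions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region_id = "character"))
  region_table(df$region_id,
               lon = if ("lon" %in% names(df)) df$lon else NA,
               lat = if ("lat" %in% names(df)) df$lat else NA,
               population = if ("population" %in% names(df))
                 df$population else NA)
}

#' Read a ZIP-to-region crosswalk CSV (`zip_code,zcta_id`)
#' @param path CSV path.
#' @return named character vector mapping zip code to region id.
#' @export
read_crosswalk <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (anyDuplicated(df[[1]]))
    stop("crosswalk zip codes must be unique", call. = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Map reported ZIP codes to analysis regions
#'
#' Applies a many-to-one ZIP-to-ZCTA crosswalk to a record table carrying a
#' `zip_code` column, adding a `region_id` column. Records whose ZIP code is
#' absent from the crosswalk are dropped with a warning (mismatches between
#' postal codes and census areal units are expected at a low rate); the
#' remap report counts records whose assigned region differs from the
#' reported ZIP.
#'
#' @param records `data.frame` with a `zip_code` column.
#' @param crosswalk named vector from [read_crosswalk()].
#' @return list with `records` (mapped) and `report` (`n_in`, `n_mapped`,
#'   `n_remapped`, `n_dropped`, `unmapped_zips`).
#' @export
apply_crosswalk <- function(records, crosswalk) {
  zips <- as.character(records$zip_code)
  region <- unname(crosswalk[zips])
  mapped <- !is.na(region)
  if (!any(mapped))
    stop("no record's ZIP code appears in the crosswalk", call. = FALSE)
  dropped <- unique(zips[!mapped])
  if (length(dropped) > 0)
    warning(sum(!mapped), " record(s) with unmapped ZIP code(s) dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  out <- records[mapped, , drop = FALSE]
  out$region_id <- region[mapped]
  list(records = out,
       report = list(n_in = length(zips), n_mapped = sum(mapped),
                     n_remapped = sum(out$region_id != out$zip_code),
                     n_dropped = sum(!mapped),
                     unmapped_zips = dropped))
}

#' Percentage summary of demographic variables
#'
#' Per-variable level percentages in the style of a study "Table 1".
#'
#' @param records `data.frame` of records.
#' @param variables character vector of columns to summarize; defaults to
#'   everything except `record_id`, `region_id`, `zip_code`, `outcome`.
#' @param digits rounding for the percentage column.
#' @return `data.frame` with `variable`, `level`, `n`, `percent`; attribute
#'   `n_total` holds the record count.
#' @export
summarize_demographics <- function(records, variables = NULL, digits = 1) {
  stopifnot(nrow(records) > 0)
  if (is.null(variables))
    variables <- setdiff(names(records),
                         c("record_id", "region_id", "zip_code", "outcome"))
  out <- do.call(rbind, lapply(variables, function(v) {
    tab <- table(records[[v]])
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               percent = round(100 * as.integer(tab) / nrow(records),
                               digits),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(records)
  out
}

#' Write fit artifacts as CSV files
#'
#' Writes `coefficients.csv` (term, estimate, se, lower, upper),
#' `effects.csv` (region_id, alpha_hat, alpha_tilde, estimability, n_s) and,
#' when a CV object is given, `cv_table.csv`.
#'
#' @param fit an `areal_fit`.
#' @param dir output directory.
#' @param cv optional `areal_cv`.
#' @return invisibly, the directory.
#' @export
write_fit <- function(fit, dir, cv = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(fit$intervals, file.path(dir, "coefficients.csv"),
                   row.names = FALSE, quote = FALSE)
  eff <- data.frame(region_id = names(fit$alpha_hat),
                    alpha_hat = unname(fit$alpha_hat),
                    alpha_tilde = unname(fit$alpha_tilde),
                    estimability = fit$estimability$status,
                    n_s = fit$estimability$n_s, stringsAsFactors = FALSE)
  utils::write.csv(eff, file.path(dir, "effects.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cv))
    utils::write.csv(cv$cv_table, file.path(dir, "cv_table.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration is the single source of truth for a pipeline run:
#' input paths, kernel settings, design specification, CV settings and
#' reporting options. Missing sections fall back to package defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

# JSON run manifest: config hash, seed, package/R versions
write_manifest <- function(dir, config_path, seed, extra = list()) {
  manifest <- c(list(
    config_md5 = unname(tools::md5sum(config_path)),
    seed = seed,
    package = "arealrank",
    package_version = as.character(utils::packageVersion("arealrank")),
    r_version = R.version.string), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
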