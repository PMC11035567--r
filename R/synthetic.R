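#' Configure a synthetic small-area study
#'
#' Describes a complete generative study: a synthetic geography (grid or
#' random points with an urban cluster), travel times derived from
#' great-circle distances and density-dependent driving speeds,
#' spatially autocorrelated true region effects drawn from the Gaussian
#' Markov random field implied by the Laplacian penalty, categorical
#' demographic covariates, and Gaussian individual outcomes on a 0-100
#' score scale. The defaults give a 64-region grid with a compact slow
#' urban block, one isolated region and one forced-empty interior region,
#' a mean of 30 respondents per region with 10% empty regions, residual
#' standard deviation 10 score units, and true region effects with a
#' spread of a few score units — the conditions used throughout the
#' package's recovery experiments.
#'
#' @param S number of non-isolated regions (default 64).
#' @param layout `"grid"` or `"random_points"`.
#' @param urban_fraction fraction of regions in the dense urban block.
#' @param spacing_rural,spacing_urban centroid spacing in miles.
#' @param speed_urban,speed_rural driving speeds in miles/minute (defaults
#'   0.4 = 24 mph urban, 1.0 = 60 mph rural), so a fixed drive-time
#'   threshold covers fewer miles in the urban block.
#' @param kernel [kernel_spec] for the neighborhood graph (default
#'   truncated Gaussian, 30-minute threshold, bandwidth 15).
#' @param n_isolated isolated empty regions appended far from the grid
#'   (non-estimable by construction).
#' @param n_forced_empty interior regions deterministically stripped of
#'   observations (empty but smoothable).
#' @param n_s_model per-region sample-size model: `list(kind = "fixed",
#'   n = )`, `list(kind = "poisson", mean = )`, or `list(kind =
#'   "zero_inflated", p0 = , mean = )`.
#' @param covariates named list; each element `list(levels =, freq =,
#'   ref =)`. Defaults to gender and urban/rural with nationwide marginal
#'   frequencies; see [demographic_profile()] for the full seven-variable
#'   set.
#' @param beta_true named vector of true coefficients per non-reference
#'   `variable:level` column, in outcome units.
#' @param alpha0_true overall outcome level (score units).
#' @param kappa,gamma0 scale and ridge of the GMRF effect prior with
#'   precision `(L + gamma0 I) / kappa`.
#' @param sigma residual standard deviation (score units).
#' @param clip_to_bounds clip outcomes to [0, 100]? Off by default because
#'   clipping biases linear-model recovery.
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(S = 64, layout = c("grid", "random_points"),
                       urban_fraction = 0.25,
                       spacing_rural = 18, spacing_urban = 6,
                       speed_urban = 0.4, speed_rural = 1.0,
                       kernel = kernel_spec("gaussian", threshold = 30,
                                            bandwidth = 15),
                       n_isolated = 1, n_forced_empty = 1,
                       n_s_model = list(kind = "zero_inflated",
                                        p0 = 0.1, mean = 30),
                       covariates = list(
                         gender = list(levels = c("Male", "Female"),
                                       freq = c(0.358, 0.642),
                                       ref = "Male"),
                         urban = list(levels = c("Rural", "Urban"),
                                      freq = c(0.168, 0.832),
                                      ref = "Rural")),
                       beta_true = c("gender:Female" = -0.8,
                                     "urban:Urban" = 17.5),
                       alpha0_true = 60, kappa = 50, gamma0 = 0.5,
                       sigma = 10, clip_to_bounds = FALSE, seed = 1L) {
  layout <- match.arg(layout)
  cfg <- mget(names(formals()))
  cfg$layout <- layout
  if (S < 2) stop("need at least 2 regions", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (kappa < 0 || gamma0 <= 0)
    stop("kappa must be >= 0 and gamma0 > 0", call. = FALSE)
  for (v in names(covariates)) {
    cv <- covariates[[v]]
    if (length(cv$levels) != length(cv$freq))
      stop("levels/freq mismatch for '", v, "'", call. = FALSE)
    if (any(cv$freq < 0) || abs(sum(cv$freq) - 1) > 1e-6)
      stop("frequencies of '", v, "' must be in [0,1] and sum to 1",
           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Nationwide demographic marginals and study-scale effect sizes
#'
#' The full seven-variable categorical profile (gender, age, race,
#' education, income, marital status, urban/rural) with nationwide marginal
#' frequencies and plausible true effects on the overall score, for
#' emulation studies that want the complete demographic design rather than
#' the compact default. Frequencies are normalized to sum to one per
#' variable.
#'
#' @return list with `covariates` (as accepted by [sim_config()]) and
#'   `beta_true`.
#' @export
demographic_profile <- function() {
  norm <- function(x) x / sum(x)
  covariates <- list(
    gender = list(levels = c("Male", "Female"),
                  freq = norm(c(35.8, 64.2)), ref = "Male"),
    age = list(levels = c("18-29", "30-44", "45-64", "65+"),
               freq = norm(c(14.2, 31.2, 46.6, 7.9)), ref = "18-29"),
    race = list(levels = c("White", "Black", "Hispanic/Latino", "Asian",
                           "Other"),
                freq = norm(c(73.4, 12.6, 7.6, 4.3, 2.1)), ref = "White"),
    education = list(levels = c("<High school", "High school", "College",
                                "Post-graduate"),
                     freq = norm(c(1.3, 24.9, 45.9, 27.9)),
                     ref = "<High school"),
    income = list(levels = c("<25K", "25-50K", "50-100K", "100K+"),
                  freq = norm(c(6.6, 15.8, 35.7, 42.0)), ref = "<25K"),
    marital = list(levels = c("Never married", "Married", "Other"),
                   freq = norm(c(21.1, 65.1, 13.8)), ref = "Never married"),
    urban = list(levels = c("Rural", "Urban"),
                 freq = norm(c(16.8, 83.2)), ref = "Rural"))
  beta_true <- c(
    "gender:Female" = -0.8,
    "age:30-44" = -0.4, "age:45-64" = 1.8, "age:65+" = 3.3,
    "race:Black" = 0.6, "race:Hispanic/Latino" = 2.9, "race:Asian" = 2.6,
    "race:Other" = -1.2,
    "education:High school" = 7.1, "education:College" = 8.2,
    "education:Post-graduate" = 10.9,
    "income:25-50K" = 3.4, "income:50-100K" = 7.5, "income:100K+" = 13.7,
    "marital:Married" = 1.7, "marital:Other" = -0.3,
    "urban:Urban" = 17.5)
  list(covariates = covariates, beta_true = beta_true)
}

#' Simulate a synthetic geography and travel-time matrix
#'
#' Places `S` region centroids (grid or uniform random points), designates
#' a compact urban block with tighter centroid spacing and slower driving
#' speeds, and derives pairwise travel times as great-circle distance
#' divided by the mean speed of the pair. Because a fixed travel-time
#' threshold covers fewer miles at urban speeds while urban centroids are
#' packed more densely, urban regions end up with more neighbors per
#' square mile — the density-dependent neighborhood asymmetry seen with
#' real drive times. `n_isolated` extra regions are appended far from the
#' grid so that they have no neighbors at any reasonable threshold.
#'
#' @param config a [sim_config()].
#' @return list with `regions` (a [region_table]; `urban` logical column
#'   added), `travel_times` (symmetric, minutes) and `urban` flags.
#' @export
simulate_geography <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$S
  u_side <- max(1L, round(sqrt(config$urban_fraction * S)))
  side <- ceiling(sqrt(S))
  if (config$layout == "grid") {
    ij <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(S), ]
    urban <- ij$i <= u_side & ij$j <= u_side
    sp <- ifelse(urban, config$spacing_urban, config$spacing_rural)
    x <- (ij$j - 1) * sp
    y <- (ij$i - 1) * sp
  } else {
    extent <- side * config$spacing_rural
    n_urb <- round(config$urban_fraction * S)
    urban <- seq_len(S) <= n_urb
    u_extent <- u_side * config$spacing_urban
    x <- ifelse(urban, stats::runif(S, 0, u_extent),
                stats::runif(S, 0, extent))
    y <- ifelse(urban, stats::runif(S, 0, u_extent),
                stats::runif(S, 0, extent))
  }
  if (config$n_isolated > 0) {
    k <- config$n_isolated
    x <- c(x, -500 - 200 * seq_len(k))
    y <- c(y, rep(0, k))
    urban <- c(urban, rep(FALSE, k))
  }
  ids <- c(sprintf("R%03d", seq_len(S)),
           if (config$n_isolated > 0)
             sprintf("ISO%02d", seq_len(config$n_isolated)))
  lat0 <- 42; lon0 <- -72
  mi_per_deg <- 2 * pi * .EARTH_RADIUS_MILES / 360
  lat <- lat0 + y / mi_per_deg
  lon <- lon0 + x / (mi_per_deg * cos(lat0 * pi / 180))
  pop <- round(exp(stats::rnorm(length(ids), log(5000), 0.5)))
  regions <- region_table(ids, lon = lon, lat = lat, population = pop)
  regions$urban <- urban
  d <- great_circle_distances(regions)
  speed <- ifelse(urban, config$speed_urban, config$speed_rural)
  pair_speed <- outer(speed, speed, function(a, b) (a + b) / 2)
  tt <- d / pair_speed
  diag(tt) <- 0
  tt <- symmetrize_travel_times(travel_time_matrix(tt, regions = ids))
  list(regions = regions, travel_times = tt, urban = urban)
}

#' Draw spatially autocorrelated true region effects
#'
#' One draw from the zero-mean Gaussian Markov random field with covariance
#' `kappa * (L + gamma0 I)^{-1}` — the prior under which the Laplacian
#' penalized estimator is the posterior mode — centered to sum to zero.
#' Neighboring regions therefore receive similar effects, and the draw's
#' Moran's I over the graph is positive with high probability.
#'
#' @param graph an `areal_graph`.
#' @param kappa variance scale (`kappa = 0` gives identically zero
#'   effects).
#' @param gamma0 positive ridge making the precision nonsingular.
#' @param seed integer seed.
#' @return named numeric vector of true effects summing to zero.
#' @export
simulate_spatial_effects <- function(graph, kappa, gamma0, seed = 1L) {
  if (gamma0 <= 0) stop("gamma0 must be positive", call. = FALSE)
  s <- length(graph$regions)
  if (kappa == 0) return(stats::setNames(rep(0, s), graph$regions))
  prec <- (graph$L + gamma0 * diag(s)) / kappa
  r <- tryCatch(chol(prec), error = function(e)
    stop("effect precision matrix is not positive definite", call. = FALSE))
  set.seed(seed)
  z <- stats::rnorm(s)
  alpha <- backsolve(r, z)
  alpha <- alpha - mean(alpha)
  stats::setNames(alpha, graph$regions)
}

#' Simulate individual records given a geography and true effects
#'
#' Draws a per-region sample size from the configured count model (with
#' zero inflation creating empty regions), forces the configured isolated
#' and interior regions to zero observations, samples covariate levels
#' independently per variable from the configured frequencies, and
#' generates outcomes `y = alpha0 + x' beta + alpha_s + N(0, sigma^2)`,
#' optionally clipped to [0, 100].
#'
#' @param regions a [region_table] (row order defines the region order).
#' @param alpha_true named true effect vector (sum-to-zero scale).
#' @param config a [sim_config()].
#' @return `data.frame` of records: `record_id`, `region_id`, `outcome`,
#'   and one column per covariate.
#' @export
simulate_individuals <- function(regions, alpha_true, config) {
  set.seed(config$seed + 1L)
  ids <- regions$region_id
  s <- length(ids)
  m <- config$n_s_model
  n_s <- switch(m$kind,
    fixed = rep(m$n, s),
    poisson = stats::rpois(s, m$mean),
    zero_inflated = ifelse(stats::runif(s) < m$p0, 0L,
                           stats::rpois(s, m$mean)),
    stop("unknown n_s model kind '", m$kind, "'", call. = FALSE))
  iso <- grepl("^ISO", ids)
  n_s[iso] <- 0L
  if (config$n_forced_empty > 0) {
    # deterministically empty interior regions: closest to the grid median
    grid_idx <- which(!iso)
    cx <- stats::median(regions$lon[grid_idx])
    cy <- stats::median(regions$lat[grid_idx])
    d2 <- (regions$lon[grid_idx] - cx)^2 + (regions$lat[grid_idx] - cy)^2
    force_idx <- grid_idx[order(d2)][seq_len(min(config$n_forced_empty,
                                                 length(grid_idx)))]
    n_s[force_idx] <- 0L
  }
  n <- sum(n_s)
  region_of <- rep(ids, times = n_s)
  rec <- data.frame(record_id = sprintf("I%05d", seq_len(max(n, 0))),
                    region_id = region_of, stringsAsFactors = FALSE)
  spec <- config_design_spec(config)
  for (v in names(config$covariates)) {
    cv <- config$covariates[[v]]
    rec[[v]] <- sample(cv$levels, n, replace = TRUE, prob = cv$freq)
  }
  x <- encode_covariates(rec, spec)
  beta <- config$beta_true[colnames(x)]
  if (anyNA(beta))
    stop("beta_true missing entries for: ",
         paste(colnames(x)[is.na(beta)], collapse = ", "), call. = FALSE)
  y <- config$alpha0_true + drop(x %*% beta) +
    as.numeric(alpha_true[region_of]) + stats::rnorm(n, 0, config$sigma)
  if (config$clip_to_bounds) y <- pmin(pmax(y, 0), 100)
  rec$outcome <- y
  rec[, c("record_id", "region_id", "outcome",
          names(config$covariates))]
}

# the design_spec implied by a sim_config
config_design_spec <- function(config) {
  design_spec(lapply(config$covariates, function(cv) cv$levels),
              vapply(config$covariates, function(cv) cv$ref, ""))
}

#' Generate a complete synthetic study
#'
#' Composes [simulate_geography()], the neighborhood graph,
#' [simulate_spatial_effects()] and [simulate_individuals()] into one
#' reproducible dataset with embedded truth. The default configuration
#' contains at least one empty-but-smoothable region (forced at the grid
#' interior) and one isolated non-estimable region.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_study`: `config`, `regions`,
#'   `travel_times`, `graph`, `records`, `design` (a `design_spec`),
#'   `beta_true`, `alpha_true` (`alpha0_true + alpha_tilde_true`),
#'   `alpha_tilde_true` (sums to zero).
#' @export
generate_study <- function(config = sim_config()) {
  geo <- simulate_geography(config)
  a <- build_adjacency(geo$travel_times, config$kernel)
  graph <- build_laplacian(a, kernel = config$kernel)
  alpha_tilde <- simulate_spatial_effects(graph, config$kappa,
                                          config$gamma0,
                                          seed = config$seed + 2L)
  records <- simulate_individuals(geo$regions, alpha_tilde, config)
  structure(list(config = config, regions = geo$regions,
                 travel_times = geo$travel_times, graph = graph,
                 records = records,
                 design = config_design_spec(config),
                 beta_true = config$beta_true,
                 alpha_true = config$alpha0_true + alpha_tilde,
                 alpha_tilde_true = alpha_tilde),
            class = "synthetic_study")
}

#' Write a synthetic study to CSV files
#'
#' Writes `records.csv`, `regions.csv`, `travel_times.csv` (wide),
#' `truth_effects.csv` and `truth_beta.csv` into `dir`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, quote = FALSE)
  w(study$records, "records.csv")
  w(as.data.frame(study$regions), "regions.csv")
  write_travel_times(study$travel_times, file.path(dir, "travel_times.csv"))
  w(data.frame(region_id = names(study$alpha_true),
               alpha_true = unname(study$alpha_true),
               alpha_tilde_true = unname(study$alpha_tilde_true),
               stringsAsFactors = FALSE), "truth_effects.csv")
  w(data.frame(term = names(study$beta_true),
               beta_true = unname(study$beta_true),
               stringsAsFactors = FALSE), "truth_beta.csv")
  invisible(dir)
}
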