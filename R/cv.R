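#' Choose smoothing parameters by cross-validated grid search
#'
#' K-fold cross-validation over a `(lambda, gamma)` grid, selecting the pair
#' that minimizes out-of-fold root mean squared error. Folds split
#' individuals, stratified by region wherever a region has at least `k`
#' records so every fold retains observations from the well-sampled regions;
#' records in smaller regions are assigned at random. Out-of-fold records
#' whose region is non-estimable in a training fit are excluded from that
#' fold's RMSE. Ties are broken deterministically toward the smaller
#' `lambda`, then the smaller `gamma`. A grid pair whose training system is
#' singular in any fold is marked failed and excluded.
#'
#' @param design an `areal_design`.
#' @param graph the matching `areal_graph`.
#' @param lambda_grid,gamma_grid numeric grids; defaults are log-spaced
#'   `10^(-2..4)` and `10^(-4..1)`.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold split.
#' @return list of class `areal_cv`: `lambda`, `gamma`, `cv_table`
#'   (`data.frame` with `lambda`, `gamma`, `rmse`, `failed`), `folds`, and
#'   `fit` — the final model refit on all data at the selected pair.
#' @export
cross_validate <- function(design, graph,
                           lambda_grid = 10^seq(-2, 4),
                           gamma_grid = 10^seq(-4, 1),
                           k = 5, seed = 1L) {
  stopifnot(length(lambda_grid) > 0, length(gamma_grid) > 0, k >= 2)
  n <- length(design$y)
  if (n < k) stop("need at least k observations", call. = FALSE)
  folds <- make_folds(design, k, seed)

  grid <- expand.grid(gamma = gamma_grid, lambda = lambda_grid)
  grid <- grid[order(grid$lambda, grid$gamma), c("lambda", "gamma")]
  rmse <- rep(NA_real_, nrow(grid))
  failed <- rep(FALSE, nrow(grid))

  fold_designs <- lapply(seq_len(k), function(f) {
    idx <- folds != f
    list(train = subset_design(design, idx),
         test_idx = which(!idx))
  })

  for (g in seq_len(nrow(grid))) {
    se_sum <- 0; n_pred <- 0L; bad <- FALSE
    for (f in seq_len(k)) {
      fd <- fold_designs[[f]]
      fit <- tryCatch(
        fit_penalized(fd$train, graph, grid$lambda[g], grid$gamma[g]),
        error = function(e) NULL)
      if (is.null(fit)) { bad <- TRUE; break }
      idx <- fd$test_idx
      xt <- cbind(design$X[idx, , drop = FALSE],
                  design$Z[idx, , drop = FALSE])
      coefs <- c(fit$beta_hat, fit$alpha_hat)
      pred <- drop(xt %*% ifelse(is.na(coefs), 0, coefs))
      ok <- !is.na(fit$alpha_hat[max.col(design$Z[idx, , drop = FALSE])])
      se_sum <- se_sum + sum((design$y[idx][ok] - pred[ok])^2)
      n_pred <- n_pred + sum(ok)
    }
    failed[g] <- bad
    if (!bad && n_pred > 0) rmse[g] <- sqrt(se_sum / n_pred)
  }
  if (all(failed | is.na(rmse)))
    stop("every (lambda, gamma) pair failed during cross-validation",
         call. = FALSE)
  best <- which(rmse == min(rmse, na.rm = TRUE))[1]
  cv_table <- data.frame(lambda = grid$lambda, gamma = grid$gamma,
                         rmse = rmse, failed = failed)
  structure(list(lambda = grid$lambda[best], gamma = grid$gamma[best],
                 cv_table = cv_table, folds = folds,
                 fit = fit_penalized(design, graph, grid$lambda[best],
                                     grid$gamma[best])),
            class = "areal_cv")
}

#' @export
print.areal_cv <- function(x, ...) {
  cat(sprintf("areal_cv: selected lambda = %g, gamma = %g (CV RMSE %.4f)\n",
              x$lambda, x$gamma,
              min(x$cv_table$rmse, na.rm = TRUE)))
  invisible(x)
}

# region-stratified fold assignment
make_folds <- function(design, k, seed) {
  n <- length(design$y)
  region_of <- design$regions[max.col(design$Z)]
  folds <- integer(n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  small <- integer(0)
  for (r in unique(region_of)) {
    idx <- which(region_of == r)
    if (length(idx) >= k) {
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    } else {
      small <- c(small, idx)
    }
  }
  if (length(small) > 0)
    folds[small] <- sample(rep_len(seq_len(k), length(small)))
  folds
}

# restrict an areal_design to a subset of rows (regions kept, counts update)
subset_design <- function(design, rows) {
  structure(list(X = design$X[rows, , drop = FALSE],
                 Z = design$Z[rows, , drop = FALSE],
                 y = design$y[rows],
                 regions = design$regions, spec = design$spec,
                 n_s = colSums(design$Z[rows, , drop = FALSE])),
            class = "areal_design")
}
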