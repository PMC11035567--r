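#' Fit the graph-Laplacian penalized regression
#'
#' Solves, in closed form, the penalized least-squares problem
#' \deqn{\min_{\beta,\alpha} \|y - X\beta - Z\alpha\|^2 +
#'       \lambda \alpha^\top (L + \gamma I)\alpha,}
#' whose minimizer is \eqn{(\hat\beta, \hat\alpha) = (\tilde X^\top \tilde X
#' + M)^{-1} \tilde X^\top y} with \eqn{\tilde X = [X\; Z]} and
#' \eqn{M = \mathrm{blockdiag}(0_{p\times p},\, \lambda L + \lambda\gamma
#' I_S)}. The Laplacian term pulls neighboring regions' effects together;
#' the ridge term \eqn{\lambda\gamma\sum_s \alpha_s^2} stabilizes the
#' otherwise singular Laplacian. The system is solved with a Cholesky
#' factorization of the augmented normal matrix, never an explicit inverse.
#'
#' Regions classified `non_estimable` by [connectivity_report()] (no
#' observations and no usable neighbors) are removed from `Z` and `L`
#' before solving and their effects reported as `NA`.
#'
#' @param design an `areal_design` from [encode_design()].
#' @param graph an `areal_graph` over the same regions (same order).
#' @param lambda smoothing strength, `>= 0`.
#' @param gamma ridge constant, required `> 0` whenever `lambda > 0` and
#'   some region is empty but smoothable.
#' @return object of class `areal_fit` with elements `beta_hat` (named),
#'   `alpha_hat` (named, `NA` for non-estimable regions), `alpha0`,
#'   `alpha_tilde`, `lambda`, `gamma`, `sigma2_hat`, `covariance`,
#'   `intervals`, `fit_stats`, `estimability`, `fitted`, `residuals`.
#' @export
fit_penalized <- function(design, graph, lambda, gamma = 0) {
  stopifnot(inherits(design, "areal_design"), inherits(graph, "areal_graph"))
  if (!identical(design$regions, graph$regions))
    stop("design and graph regions are not aligned", call. = FALSE)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (gamma < 0) stop("gamma must be nonnegative", call. = FALSE)

  report <- connectivity_report(graph, design$n_s)
  if (lambda > 0 && gamma == 0 &&
      any(report$status == "empty_smoothable"))
    stop("gamma must be > 0 when smoothing with empty regions present ",
         "(the graph Laplacian is singular by construction)", call. = FALSE)
  keep <- report$status != "non_estimable"
  if (!any(keep)) stop("no estimable regions", call. = FALSE)

  x <- design$X
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  z <- design$Z[, keep, drop = FALSE]
  y <- design$y
  l_keep <- graph$L[keep, keep, drop = FALSE]
  p <- ncol(x)
  s_keep <- ncol(z)

  xt <- cbind(x, z)
  xtx <- crossprod(xt)
  pen <- matrix(0, p + s_keep, p + s_keep)
  pen[(p + 1):(p + s_keep), (p + 1):(p + s_keep)] <-
    lambda * l_keep + lambda * gamma * diag(s_keep)
  h <- xtx + pen

  ch <- tryCatch(chol(h), error = function(e) NULL)
  if (is.null(ch))
    stop("augmented normal matrix is singular; increase lambda/gamma or ",
         "drop unobserved regions (lambda = 0 cannot smooth empty regions)",
         call. = FALSE)
  coefs <- backsolve(ch, forwardsolve(t(ch), crossprod(xt, y)))
  coefs <- drop(coefs)

  beta_hat <- if (p > 0) stats::setNames(coefs[seq_len(p)], colnames(x))
              else stats::setNames(numeric(0), character(0))
  alpha_keep <- coefs[p + seq_len(s_keep)]
  alpha_hat <- stats::setNames(rep(NA_real_, length(graph$regions)),
                               graph$regions)
  alpha_hat[keep] <- alpha_keep

  fitted <- drop(xt %*% coefs)
  resid <- y - fitted
  rss <- sum(resid^2)

  # effective degrees of freedom: trace of the hat matrix
  # tr(Xt (XtX + M)^-1 Xt') = tr((XtX + M)^-1 XtX)
  edf <- sum(diag(backsolve(ch, forwardsolve(t(ch), xtx))))
  n <- length(y)
  sigma2 <- rss / max(n - edf, 1e-8)

  hinv_xtx <- backsolve(ch, forwardsolve(t(ch), xtx))
  covariance <- sigma2 * backsolve(ch, forwardsolve(t(ch), t(hinv_xtx)))
  covariance <- (covariance + t(covariance)) / 2
  dimnames(covariance) <- list(colnames(xt), colnames(xt))

  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (n > edf + 1) 1 - (1 - r2) * (n - 1) / (n - edf - 1)
            else NA_real_
  fit_stats <- list(rmse = sqrt(rss / n), r_squared = r2,
                    adj_r_squared = adj_r2, edf = edf, n = n, rss = rss)

  dec <- decompose_effects(alpha_hat)
  fit <- structure(list(
    beta_hat = beta_hat, alpha_hat = alpha_hat,
    alpha0 = dec$alpha0, alpha_tilde = dec$alpha_tilde,
    lambda = lambda, gamma = gamma, sigma2_hat = sigma2,
    covariance = covariance, fit_stats = fit_stats,
    estimability = report, spec = design$spec, regions = design$regions,
    fitted = fitted, residuals = resid
  ), class = "areal_fit")
  fit$intervals <- coefficient_intervals(fit)
  fit
}

#' Split region effects into overall level and sum-to-zero deviations
#'
#' Writes `alpha_s = alpha0 + alpha_tilde_s` with the constraint that the
#' deviations sum to zero over the estimable regions. `alpha0` is the
#' unweighted mean of the estimable effects (an observation-weighted mean is
#' available via `weights`); `alpha_tilde_s` is the region's deviation and
#' is the quantity used for ranking. Missing (non-estimable) entries stay
#' missing.
#'
#' @param alpha_hat named numeric vector of region effects, `NA` allowed.
#' @param weights optional nonnegative weights (e.g. `n_s`) for a weighted
#'   overall level.
#' @return list with `alpha0` and `alpha_tilde`.
#' @export
decompose_effects <- function(alpha_hat, weights = NULL) {
  est <- !is.na(alpha_hat)
  if (!any(est)) stop("all region effects are missing", call. = FALSE)
  a0 <- if (is.null(weights)) mean(alpha_hat[est])
        else stats::weighted.mean(alpha_hat[est], weights[est])
  list(alpha0 = a0, alpha_tilde = alpha_hat - a0)
}

#' Predict outcome scores for new records
#'
#' \eqn{\hat y = x^\top \hat\beta + \hat\alpha_s}. Records in regions whose
#' effect could not be estimated get `NA` with a warning.
#'
#' @param object an `areal_fit`.
#' @param newdata `data.frame` with `region_id` and the design variables.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.areal_fit <- function(object, newdata, ...) {
  x <- encode_covariates(newdata, object$spec)
  rid <- as.character(newdata$region_id)
  unknown <- !rid %in% object$regions
  if (any(unknown))
    stop("prediction for unknown region(s): ",
         paste(utils::head(unique(rid[unknown]), 5), collapse = ", "),
         call. = FALSE)
  alpha <- object$alpha_hat[rid]
  if (anyNA(alpha))
    warning(sum(is.na(alpha)),
            " prediction(s) in non-estimable regions returned as NA")
  drop(x %*% object$beta_hat) + as.numeric(alpha)
}

#' Fit statistics of a penalized fit
#'
#' @param fit an `areal_fit`.
#' @return list with `rmse`, `r_squared`, `adj_r_squared`, `edf`, `n`.
#' @export
fit_statistics <- function(fit) fit$fit_stats

#' Normal-approximation confidence intervals for covariate coefficients
#'
#' Uses the sandwich covariance \eqn{\hat\sigma^2 (\tilde X^\top\tilde X +
#' M)^{-1} \tilde X^\top\tilde X (\tilde X^\top\tilde X + M)^{-1}} of the
#' penalized estimator, with normal quantiles. At `lambda = 0` this
#' collapses to the classical OLS covariance. The intervals are approximate:
#' they ignore smoothing bias in `alpha`.
#'
#' @param fit an `areal_fit`.
#' @param level coverage level, default 0.95.
#' @return `data.frame` with `term`, `estimate`, `se`, `lower`, `upper`.
#' @export
coefficient_intervals <- function(fit, level = 0.95) {
  p <- length(fit$beta_hat)
  if (p == 0)
    return(data.frame(term = character(0), estimate = numeric(0),
                      se = numeric(0), lower = numeric(0),
                      upper = numeric(0), stringsAsFactors = FALSE))
  v <- diag(fit$covariance)[seq_len(p)]
  if (any(!is.finite(v)))
    stop("non-finite coefficient covariance", call. = FALSE)
  se <- sqrt(pmax(v, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(term = names(fit$beta_hat),
             estimate = unname(fit$beta_hat), se = se,
             lower = unname(fit$beta_hat) - zq * se,
             upper = unname(fit$beta_hat) + zq * se,
             stringsAsFactors = FALSE)
}

#' @export
print.areal_fit <- function(x, ...) {
  st <- x$fit_stats
  cat("areal_fit: n =", st$n, ", p =", length(x$beta_hat),
      ", S =", length(x$alpha_hat), "\n")
  cat(sprintf("  lambda = %g, gamma = %g, edf = %.1f\n",
              x$lambda, x$gamma, st$edf))
  cat(sprintf("  RMSE = %.3f, R2 = %.4f, adj R2 = %.4f\n",
              st$rmse, st$r_squared, st$adj_r_squared))
  ne <- sum(x$estimability$status == "non_estimable")
  if (ne > 0) cat("  ", ne, "non-estimable region(s) reported NA\n")
  invisible(x)
}
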