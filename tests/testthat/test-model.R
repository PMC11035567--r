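test_that("design encoding produces dummy columns, region incidence and deterministic order", {
  rec <- toy_records()
  spec <- toy_spec()
  regions <- c("A", "B", "C", "D", "E")  # D, E have no records
  d <- encode_design(rec, spec, regions)
  expect_equal(colnames(d$X), c("gender:Female", "urban:Urban"))
  expect_equal(unname(d$X[1, ]), c(0, 1))   # Male, Urban
  expect_equal(unname(d$X[2, ]), c(1, 1))   # Female, Urban
  expect_equal(unname(d$Z[5, ]), c(0, 0, 1, 0, 0))  # third of five regions
  expect_equal(unname(d$n_s), c(2, 2, 2, 0, 0))
  expect_equal(rowSums(d$Z), rep(1, 6))
  # p = (2-1) + (4-1) for a 2-level and a 4-level variable
  spec2 <- design_spec(list(a = c("x", "y"), b = c("p", "q", "r", "s")))
  expect_length(design_terms(spec2), 4)
  bad <- rec; bad$gender[3] <- "Unknown"
  expect_error(encode_design(bad, spec, regions), "unseen level")
  expect_error(encode_design(rec, spec, c("A", "B")), "unknown region")
})

test_that("two observed regions with one edge solve to the hand-derived effects", {
  ids <- c("A", "B")
  g <- graph_from_edges(ids, list(c("A", "B")))
  rec <- data.frame(region_id = ids, outcome = c(0, 10),
                    stringsAsFactors = FALSE)
  d <- encode_design(rec, design_spec(list()), ids)
  fit <- fit_penalized(d, g, lambda = 1, gamma = 0)
  # stationarity: 2a1 - a2 = 0, 2a2 - a1 = 10
  expect_equal(unname(fit$alpha_hat), c(10 / 3, 20 / 3), tolerance = 1e-10)
})

test_that("lambda = 0 with all regions observed reproduces fixed-effects region means", {
  set.seed(41)
  inst <- random_instance(S = 6, n = 60, p = 0)
  fit <- fit_penalized(inst$design, inst$graph, lambda = 0)
  region_of <- inst$design$regions[max.col(inst$design$Z)]
  means <- tapply(inst$design$y, region_of, mean)[inst$design$regions]
  expect_equal(unname(fit$alpha_hat), as.vector(means), tolerance = 1e-8)
  # training predictions then reproduce region means
  rec <- data.frame(region_id = region_of, stringsAsFactors = FALSE)
  expect_equal(unname(predict(fit, rec)), as.vector(means[region_of]),
               tolerance = 1e-8)
})

test_that("empty smoothable regions satisfy the harmonic neighbor-average identity", {
  set.seed(42)
  inst <- random_instance(S = 12, n = 100, p = 2)
  # path backbone guarantees every region keeps at least one neighbor
  a <- inst$graph$A
  for (i in 1:11) a[i, i + 1] <- a[i + 1, i] <- max(a[i, i + 1], 0.5)
  inst$graph <- build_laplacian(a)
  # empty two regions that keep graph neighbors
  d <- inst$design
  empty <- c(3, 7)
  keep_rows <- !max.col(d$Z) %in% empty
  d2 <- structure(list(X = d$X[keep_rows, , drop = FALSE],
                       Z = d$Z[keep_rows, , drop = FALSE],
                       y = d$y[keep_rows], regions = d$regions,
                       spec = NULL,
                       n_s = colSums(d$Z[keep_rows, , drop = FALSE])),
                  class = "areal_design")
  gamma <- 0.05
  fit <- fit_penalized(d2, inst$graph, lambda = 2, gamma = gamma)
  rep <- fit$estimability
  for (s in which(rep$status == "empty_smoothable")) {
    nb <- inst$graph$A[s, ]
    expect_equal(fit$alpha_hat[s],
                 sum(nb * fit$alpha_hat, na.rm = TRUE) /
                   (inst$graph$D[s] + gamma),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  # and prediction there is the harmonic neighbor effect plus x'beta
  s1 <- which(rep$status == "empty_smoothable")[1]
  nd <- data.frame(region_id = d$regions[s1])
  x0 <- matrix(0, 1, 2, dimnames = list(NULL, colnames(d$X)))
  pred <- drop(x0 %*% fit$beta_hat) + fit$alpha_hat[s1]
  rec <- data.frame(region_id = d$regions[s1], v1 = 0, v2 = 0)
  # direct check of the formula (no covariate columns in spec-free design)
  expect_equal(unname(pred),
               unname(sum(inst$graph$A[s1, ] * fit$alpha_hat, na.rm = TRUE) /
                        (inst$graph$D[s1] + gamma)),
               tolerance = 1e-8)
})

test_that("fits reject invalid tuning and guard the singular Laplacian case", {
  set.seed(43)
  inst <- random_instance(S = 8, n = 60, p = 1)
  a <- inst$graph$A
  for (i in 1:7) a[i, i + 1] <- a[i + 1, i] <- max(a[i, i + 1], 0.5)
  inst$graph <- build_laplacian(a)
  expect_error(fit_penalized(inst$design, inst$graph, lambda = -1),
               "nonnegative")
  # empty a region, then gamma = 0 smoothing must be refused
  d <- inst$design
  keep_rows <- max.col(d$Z) != 2
  d2 <- structure(list(X = d$X[keep_rows, , drop = FALSE],
                       Z = d$Z[keep_rows, , drop = FALSE],
                       y = d$y[keep_rows], regions = d$regions, spec = NULL,
                       n_s = colSums(d$Z[keep_rows, , drop = FALSE])),
                  class = "areal_design")
  expect_error(fit_penalized(d2, inst$graph, lambda = 1, gamma = 0),
               "gamma")
  # lambda = 0 cannot estimate the empty region at all
  expect_error(fit_penalized(d2, inst$graph, lambda = 0), "singular")
})

test_that("effect decomposition recovers a sum-to-zero deviation around the overall level", {
  d <- decompose_effects(c(A = 1, B = 2, C = 3))
  expect_equal(d$alpha0, 2)
  expect_equal(unname(d$alpha_tilde), c(-1, 0, 1))
  expect_equal(decompose_effects(c(5, 5, 5))$alpha_tilde, rep(0, 3))
  dm <- decompose_effects(c(A = 1, B = NA, C = 5))
  expect_equal(sum(dm$alpha_tilde, na.rm = TRUE), 0)
  expect_true(is.na(dm$alpha_tilde[2]))
  expect_error(decompose_effects(c(NA_real_, NA_real_)), "missing")
})

test_that("predictions are x'beta + alpha_s, with NA in non-estimable regions", {
  rec <- toy_records()
  ids <- c("A", "B", "C", "Z")  # Z isolated and empty
  g <- graph_from_edges(ids, list(c("A", "B"), c("B", "C")))
  d <- encode_design(rec, toy_spec(), ids)
  fit <- fit_penalized(d, g, lambda = 0.5, gamma = 0.01)
  # all-reference-level record: prediction equals the region effect
  nd <- data.frame(region_id = "A", gender = "Male", urban = "Rural")
  expect_equal(unname(predict(fit, nd)), unname(fit$alpha_hat["A"]))
  ndz <- data.frame(region_id = "Z", gender = "Male", urban = "Rural")
  expect_warning(pz <- predict(fit, ndz), "non-estimable")
  expect_true(is.na(pz))
  ndu <- data.frame(region_id = "A", gender = "Nonbinary", urban = "Rural")
  expect_error(predict(fit, ndu), "unseen level")
})

test_that("fit statistics: perfect fit, ridge limit, and edf monotone in lambda", {
  ids <- c("A", "B")
  g <- graph_from_edges(ids, list(c("A", "B")))
  rec <- data.frame(region_id = c("A", "A", "B", "B"),
                    outcome = c(4, 4, 9, 9), stringsAsFactors = FALSE)
  d <- encode_design(rec, design_spec(list()), ids)
  fit0 <- fit_penalized(d, g, lambda = 0)
  expect_equal(fit_statistics(fit0)$r_squared, 1)  # y in the column space
  # enormous ridge shrinks alpha to zero and R^2 to zero (p = 0;
  # centered outcome so total and residual sums of squares coincide)
  recc <- data.frame(region_id = c("A", "A", "B", "B"),
                     outcome = c(-4, -4, 4, 4), stringsAsFactors = FALSE)
  dc <- encode_design(recc, design_spec(list()), ids)
  fitr <- fit_penalized(dc, g, lambda = 1e8, gamma = 1e8)
  expect_lt(max(abs(fitr$alpha_hat)), 1e-3)
  expect_lt(abs(fit_statistics(fitr)$r_squared), 1e-3)
  expect_lt(fit_statistics(fitr)$edf, 1e-3)
  set.seed(44)
  inst <- random_instance(S = 10, n = 80, p = 2)
  edf <- vapply(10^seq(-2, 3),
                function(l) fit_penalized(inst$design, inst$graph, l,
                                          0.1)$fit_stats$edf, 0)
  expect_true(all(diff(edf) <= 1e-8))
  expect_true(all(edf >= 2 - 1e-8 & edf <= 12 + 1e-8))
})

test_that("confidence intervals collapse to OLS at lambda 0 and scale with noise", {
  set.seed(45)
  rec <- toy_records()
  rec <- rec[rep(1:6, 5), ]
  rec$outcome <- rec$outcome + rnorm(nrow(rec))
  ids <- c("A", "B", "C")
  g <- graph_from_edges(ids, list(c("A", "B"), c("B", "C")))
  d <- encode_design(rec, toy_spec(), ids)
  fit <- fit_penalized(d, g, lambda = 0)
  ols <- stats::lm(outcome ~ gender + urban + region_id,
                   data = transform(rec, gender = factor(gender,
                     c("Male", "Female")), urban = factor(urban,
                     c("Rural", "Urban"))))
  # same coefficient estimates as unpenalized least squares
  expect_equal(unname(fit$beta_hat["gender:Female"]),
               unname(stats::coef(ols)["genderFemale"]), tolerance = 1e-8)
  # at lambda 0 the sandwich collapses to the classical OLS covariance
  se_lm <- summary(ols)$coefficients["genderFemale", "Std. Error"]
  se_fit <- fit$intervals$se[fit$intervals$term == "gender:Female"]
  expect_equal(se_fit, se_lm, tolerance = 1e-6)
  # z quantile at 95%
  iv <- fit$intervals
  expect_equal((iv$upper - iv$estimate) / iv$se,
               rep(stats::qnorm(0.975), nrow(iv)), tolerance = 1e-10)
  # doubling the noise roughly doubles interval widths
  set.seed(46)
  inst <- random_instance(S = 8, n = 200, p = 2)
  mu <- drop(inst$design$Z %*% rnorm(8, 50, 3))
  noise <- rnorm(200)
  w <- vapply(c(5, 10), function(sg) {
    d2 <- inst$design; d2$y <- mu + sg * noise
    f <- fit_penalized(d2, inst$graph, lambda = 1, gamma = 0.1)
    mean(f$intervals$upper - f$intervals$lower)
  }, 0)
  expect_equal(w[2] / w[1], 2, tolerance = 0.15)
})

test_that("heavy smoothing limits: alpha vanishes under ridge, pools when connected", {
  set.seed(47)
  inst <- random_instance(S = 10, n = 120, p = 2)
  # make the graph connected by adding a path backbone
  a <- inst$graph$A
  for (i in 1:9) a[i, i + 1] <- a[i + 1, i] <- max(a[i, i + 1], 0.5)
  g <- build_laplacian(a)
  # (i) lambda*gamma huge: alpha -> 0 and beta -> OLS on X alone
  fit1 <- fit_penalized(inst$design, g, lambda = 1e4, gamma = 1e4)
  expect_lt(max(abs(fit1$alpha_hat)), 1e-3)
  beta_ols <- stats::coef(stats::lm(inst$design$y ~ 0 + inst$design$X))
  expect_lt(max(abs(fit1$beta_hat - beta_ols)), 1e-3)
  # (ii) lambda huge, gamma 0, connected: complete pooling of effects
  fit2 <- fit_penalized(inst$design, g, lambda = 1e8, gamma = 0)
  expect_lt(diff(range(fit2$alpha_hat)), 1e-3)
})

test_that("closed form matches the numerical minimizer on random instances", {
  set.seed(48)
  for (i in 1:5) {
    inst <- random_instance()
    lambda <- sample(c(0.1, 1, 10), 1)
    gamma <- sample(c(0.01, 0.1), 1)
    fit <- fit_penalized(inst$design, inst$graph, lambda, gamma)
    theta <- c(fit$beta_hat, fit$alpha_hat)
    oracle <- oracle_minimize(inst$design, inst$graph, lambda, gamma)
    expect_lt(sqrt(sum((theta - oracle)^2)) / sqrt(sum(theta^2)), 1e-6)
    # and the closed form attains an objective no worse than the oracle
    expect_lte(penalized_objective(theta, inst$design, inst$graph,
                                   lambda, gamma),
               penalized_objective(oracle, inst$design, inst$graph,
                                   lambda, gamma) + 1e-6)
  }
})

test_that("penalty expansion: Laplacian-plus-ridge splits exactly", {
  set.seed(49)
  g <- build_laplacian(random_graph(12))
  for (i in 1:20) {
    alpha <- rnorm(12)
    lambda <- runif(1, 0.1, 10); gamma <- runif(1, 0.001, 1)
    lhs <- lambda * drop(t(alpha) %*% (g$L + gamma * diag(12)) %*% alpha)
    rhs <- lambda * drop(t(alpha) %*% g$L %*% alpha) +
      lambda * gamma * sum(alpha^2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})
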