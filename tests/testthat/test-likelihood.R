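ind_pairs <- function(n0, n1, n2) {
  base <- tibble::tibble(g0 = c(1, 0, 0), g1 = c(0, 1, 0), g2 = c(0, 0, 1))
  base[c(rep(1, n0), rep(2, n1), rep(3, n2)), ]
}

test_that("minmax tie and constraint boundary evaluate correctly", {
  expect_equal(minmax_beta2(0), 0)
  expect_equal(minmax_beta2(1), log(3.634 * exp(1) - 2.634))
  expect_equal(exp(minmax_beta2(1)), 3.634 * exp(1) - 2.634)
  expect_error(minmax_beta2(-5), "must be > 0")
  expect_equal(constraint_boundary_beta2(0), 0)
  expect_equal(constraint_boundary_beta2(0.5), log(2 * exp(0.5) - 1))
  expect_equal(constraint_boundary_beta2(0.5), 0.8318, tolerance = 1e-4)
  expect_error(constraint_boundary_beta2(-2), "must be > 0")
  # tangent at the null has slope 2 (beta2 ~ 2 beta1)
  h <- 1e-6
  expect_equal(constraint_boundary_beta2(h) / h, 2, tolerance = 1e-4)
})

test_that("relative risks follow the log-linear parameterisation", {
  expect_equal(unname(relative_risks(0, 0)), c(1, 1, 1))
  expect_equal(unname(relative_risks(log(2), log(3))), c(1, 2, 3))
  rr <- relative_risks(0, deltas = 0.1, x = 2)
  expect_equal(unname(rr), c(1, exp(0.2), 3.634 * exp(0.2) - 2.634))
  expect_error(relative_risks(0, 0, deltas = 0.1, x = 2), "not allowed")
  expect_error(relative_risks(0, deltas = 0.1, x = c(1, 2)), "same length")
})

test_that("pair likelihood ratio is the lambda-weighted posterior ratio", {
  expect_equal(pair_likelihood_ratio(c(0.2, 0.5, 0.3), c(1, 1, 1)), 1)
  expect_equal(pair_likelihood_ratio(c(0, 0, 1), c(1, 1, 2)), 2 / 1.25)
  expect_equal(pair_likelihood_ratio(c(0.25, 0.5, 0.25), c(1, 3, 7)), 1)
  expect_error(pair_likelihood_ratio(c(0, 0, 1), c(1, -1, 2)), "positive")
})

test_that("sample LOD is additive and matches the count closed form", {
  pairs <- ind_pairs(25, 50, 25)
  expect_equal(cl_lod(pairs, 0, 0), 0)
  one <- tibble::tibble(g0 = 0, g1 = 0, g2 = 1)
  two <- dplyr::bind_rows(one, one)
  expect_equal(cl_lod(two, 0.3, 0.9), 2 * cl_lod(one, 0.3, 0.9))
  # count-based closed form at lambda = (1, 2, 4)
  S <- 0.25 + 0.5 * 2 + 0.25 * 4
  closed <- 25 * log10(1 / S) + 50 * log10(2 / S) + 25 * log10(4 / S)
  expect_equal(cl_lod(pairs, log(2), log(4)), closed, tolerance = 1e-12)
  # concatenation additivity at fixed parameters
  a <- ind_pairs(3, 7, 5); b <- ind_pairs(6, 1, 2)
  expect_equal(cl_lod(dplyr::bind_rows(a, b), 0.2, 0.5),
               cl_lod(a, 0.2, 0.5) + cl_lod(b, 0.2, 0.5))
  expect_error(cl_lod(tibble::tibble(g0 = numeric(0), g1 = numeric(0),
                                     g2 = numeric(0)), 0, 0), "nonempty")
})

test_that("unconstrained two-parameter maximum equals the multinomial MLE", {
  # proportions at the null -> LOD 0
  f <- cl_fit_counts(25, 50, 25, "unconstrained_2p")
  expect_equal(f$lod, 0, tolerance = 1e-8)
  # interior MLE: zhat = (0.1, 0.5, 0.4)
  f <- cl_fit_counts(10, 50, 40, "unconstrained_2p")
  expect_equal(f$lod, 10 * log10(0.4) + 40 * log10(1.6), tolerance = 1e-7)
  expect_equal(exp(f$beta1), 0.5 / (2 * 0.1), tolerance = 1e-3)
  expect_equal(exp(f$beta2), 0.4 / 0.1, tolerance = 1e-3)
  expect_equal(f$lr, 2 * log(10) * f$lod)
})

test_that("Olson closed form holds across a sweep of count triples", {
  n <- 24
  for (n0 in 1:(n - 2)) for (n1 in 1:(n - n0 - 1)) {
    n2 <- n - n0 - n1
    z <- c(n0, n1, n2) / n
    closed <- sum(c(n0, n1, n2) * log10(z / c(0.25, 0.5, 0.25)))
    expect_equal(cl_fit_counts(n0, n1, n2, "unconstrained_2p")$lod,
                 closed, tolerance = 1e-6)
  }
})

test_that("constrained maxima match dense grid-search oracles", {
  for (n in list(c(40, 50, 10), c(10, 50, 40), c(20, 60, 20),
                 c(15, 40, 45), c(35, 45, 20))) {
    fit <- cl_fit_counts(n[1], n[2], n[3], "constrained_2p")
    expect_equal(fit$lod, grid_lod_constrained_2p(n), tolerance = 1e-4)
    # feasibility of the returned parameters
    expect_gte(fit$beta1, -1e-8)
    expect_gte(fit$beta2 - constraint_boundary_beta2(max(fit$beta1, 0)),
               -1e-8)
    f1 <- cl_fit_counts(n[1], n[2], n[3], "constrained_1p")
    expect_equal(f1$lod, grid_lod_1p(n, lo = 0), tolerance = 1e-4)
    u1 <- cl_fit_counts(n[1], n[2], n[3], "unconstrained_1p")
    expect_equal(u1$lod,
                 grid_lod_1p(n, lo = log(2.634 / 3.634) + 1e-6),
                 tolerance = 1e-4)
  }
})

test_that("maximised LODs are nested as constraints relax", {
  set.seed(31)
  for (r in 1:20) {
    n <- as.vector(stats::rmultinom(1, 60, c(0.25, 0.5, 0.25)))
    l <- vapply(c("constrained_1p", "unconstrained_1p",
                  "constrained_2p", "unconstrained_2p"),
                function(m) cl_fit_counts(n[1], n[2], n[3], m)$lod,
                numeric(1))
    expect_gte(l["unconstrained_1p"], l["constrained_1p"] - 1e-8)
    expect_gte(l["constrained_2p"], l["constrained_1p"] - 1e-8)
    expect_gte(l["unconstrained_2p"], l["constrained_2p"] - 1e-8)
    expect_true(all(l >= 0))
  }
})

test_that("soft posteriors and count fast path agree", {
  set.seed(32)
  G <- random_posteriors(40)
  pairs <- tibble::tibble(g0 = G[, 1], g1 = G[, 2], g2 = G[, 3])
  for (m in c("unconstrained_2p", "constrained_2p", "constrained_1p")) {
    fit <- cl_fit(pairs, model = m)
    expect_s3_class(fit, "cl_fit")
    expect_gte(fit$lod, 0)
  }
  ip <- ind_pairs(12, 30, 18)
  expect_equal(cl_fit(ip, model = "constrained_2p")$lod,
               cl_fit_counts(12, 30, 18, "constrained_2p")$lod,
               tolerance = 1e-8)
})

test_that("covariate fits match a dense grid oracle and are invariant to
           re-centered shifts", {
  set.seed(33)
  n <- 60
  ibd <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  G <- cbind(ibd == 0, ibd == 1, ibd == 2) * 1
  xraw <- rnorm(n) + rnorm(n)
  x <- xraw - mean(xraw)
  pairs <- tibble::tibble(g0 = G[, 1], g1 = G[, 2], g2 = G[, 3], x1 = x)
  fit <- cl_fit(pairs, model = "unconstrained_covariate")
  expect_equal(fit$lod, grid_lod_covariate(G, x, constrained = FALSE),
               tolerance = 1e-4)
  # shifting the raw covariate then re-centering changes nothing
  x2 <- (xraw + 5) - mean(xraw + 5)
  pairs2 <- pairs; pairs2$x1 <- x2
  fit2 <- cl_fit(pairs2, model = "unconstrained_covariate")
  expect_equal(fit2$lod, fit$lod, tolerance = 1e-8)

  # minimum-adjusted binary covariate, constrained model
  xb <- rbinom(n, 1, 0.2) + rbinom(n, 1, 0.2)
  xb <- xb - min(xb)
  pairsb <- tibble::tibble(g0 = G[, 1], g1 = G[, 2], g2 = G[, 3], x1 = xb)
  fitb <- cl_fit(pairsb, model = "constrained_covariate")
  expect_equal(fitb$lod, grid_lod_covariate(G, xb, constrained = TRUE),
               tolerance = 1e-4)
  # constraint satisfied: beta1 + xmax * delta >= 0
  if (any(xb > 0)) {
    expect_gte(fitb$beta1 + max(xb[xb > 0]) * fitb$deltas[1], -1e-8)
  }
  # constrained covariate fit never exceeds the unconstrained one
  fitu <- cl_fit(pairsb, model = "unconstrained_covariate")
  expect_gte(fitu$lod, fitb$lod - 1e-8)
})

test_that("LR statistic is 2 ln(10) times the LOD", {
  expect_equal(lr_statistic(0), 0)
  expect_equal(lr_statistic(3), 6 * log(10))
  expect_equal(lr_statistic(0.742), 3.417, tolerance = 1e-3)
  expect_error(lr_statistic(-1), "nonnegative")
})

test_that("fit objects expose tidy and glance methods", {
  fit <- cl_fit_counts(10, 50, 40, "constrained_2p")
  td <- tidy(fit)
  expect_equal(td$term, c("beta1", "beta2"))
  gl <- glance(fit)
  expect_equal(gl$model, "constrained_2p")
  expect_equal(gl$lr, 2 * log(10) * gl$lod)
  expect_true(gl$converged)
})
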