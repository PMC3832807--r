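test_that("gene dropping reproduces Mendelian IBD sharing", {
  set.seed(51)
  n <- 100000
  fam <- sim_families(n, marker_model("fully_informative"))
  cnt <- tabulate(fam$ibd_true + 1L, nbins = 3L) / n
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / n)
  expect_true(all(abs(cnt - c(0.25, 0.5, 0.25)) < 3 * se))
  # the realised IBD equals the fully-informative count statistic
  expect_equal(ibd_count_fully_informative(fam[1:500, ]),
               fam$ibd_true[1:500])
})

test_that("equifrequent founder genotypes follow Hardy-Weinberg", {
  set.seed(52)
  n <- 50000
  fam <- sim_families(n, marker_model("equifrequent", 2))
  # sib-1 genotype frequencies: (p^2, 2pq, q^2) with p = 1/2
  g <- paste(pmin(fam$s1_a1, fam$s1_a2), pmax(fam$s1_a1, fam$s1_a2))
  obs <- table(factor(g, levels = c("1 1", "1 2", "2 2")))
  gof <- stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))
  expect_gt(gof$p.value, 0.001)
})

test_that("masking removes parental genotypes only", {
  set.seed(53)
  fam <- sim_families(50, marker_model("equifrequent", 4,
                                       parents_typed = FALSE))
  expect_true(all(is.na(fam$f_a1) & is.na(fam$m_a2)))
  expect_true(!anyNA(fam[c("s1_a1", "s1_a2", "s2_a1", "s2_a2")]))
})

test_that("pair covariates have the stated null distributions", {
  set.seed(54)
  n <- 100000
  cont <- sim_pair_covariates(n, covariate_spec("continuous_mean_centered"))
  expect_equal(mean(cont$pair_raw), 0, tolerance = 3 * sqrt(2 / n))
  expect_equal(stats::var(cont$pair_raw), 2, tolerance = 0.05)
  bin <- sim_pair_covariates(
    n, covariate_spec("binary_minimum_adjusted", prevalence = 0.2))
  probs <- c(0.64, 0.32, 0.04)
  obs <- tabulate(bin$pair_raw + 1L, nbins = 3L) / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(obs - probs) < 3 * se))
  # a nonzero effect shifts the continuous covariate's location
  eff <- sim_pair_covariates(n, covariate_spec("continuous_mean_centered",
                                               effect = 1))
  expect_equal(mean(eff$pair_raw), 2, tolerance = 0.05)
  # adjustment contracts
  expect_equal(mean(adjust_covariate(cont$pair_raw, "mean_center")), 0)
  expect_equal(min(adjust_covariate(bin$pair_raw, "minimum_adjust")), 0)
})

test_that("replicate studies are a pure function of the seed", {
  a <- run_null_replicates(30, 20, "constrained_1p", seed = 99)
  b <- run_null_replicates(30, 20, "constrained_1p", seed = 99)
  expect_identical(a$replicates$lod, b$replicates$lod)
  c <- run_null_replicates(30, 20, "constrained_1p", seed = 100)
  expect_false(identical(a$replicates$lod, c$replicates$lod))
  expect_error(
    run_null_replicates(30, 5, "unconstrained_covariate", seed = 1),
    "covariate spec")
  expect_error(
    run_null_replicates(
      30, 5, "constrained_1p",
      covariate = covariate_spec("continuous_mean_centered"), seed = 1),
    "covariate_spec..none")
})

test_that("the constrained one-parameter boundary mass matches the exact
           finite-sample oracle and tightens toward one half", {
  # exact enumeration oracle for P(LOD = 0)
  p100 <- exact_zero_mass_c1p(100)
  p500 <- exact_zero_mass_c1p(500)
  expect_lt(abs(p500 - 0.5), abs(p100 - 0.5)) # convergence to 1/2
  study <- run_null_replicates(100, 2000, "constrained_1p", seed = 7)
  frac0 <- mean(study$replicates$lod <= 1e-9)
  se <- sqrt(p100 * (1 - p100) / 2000)
  expect_lt(abs(frac0 - p100), 3 * se)
})

test_that("empirical p-values follow the rank rule with stable ties", {
  expect_equal(empirical_pvalues(c(0.9, 0.5, 0.3, 0.1)),
               c(0.2, 0.4, 0.6, 0.8))
  expect_equal(empirical_pvalues(c(0.9, 0.5, 0.3, 0.1))[1], 1 / 5)
  # all-equal input: the full ladder in input order
  expect_equal(empirical_pvalues(rep(1.3, 5)), (1:5) / 6)
  n <- 1000
  expect_equal(min(empirical_pvalues(stats::runif(n))), 1 / (n + 1))
  expect_error(empirical_pvalues(numeric(0)), "nonempty")
})

test_that("empirical critical LODs are the alpha-rank order statistics", {
  lods <- seq(0.001, 0.999, length.out = 999) # distinct ladder
  out <- empirical_critical_lods(lods, alphas = 0.5)
  expect_equal(out$lod, sort(lods, decreasing = TRUE)[500])
  out <- empirical_critical_lods(lods, alphas = 1 / 1000)
  expect_equal(out$lod, max(lods))
  expect_error(empirical_critical_lods(lods, alphas = 1e-6), "resolution")
  # against the mixture quantile at scale: order-statistic oracle
  set.seed(55)
  mix <- mixture_for_model("constrained_1p")
  lods <- sample_mixture_lods(20000, c(0.5, 0.5), c(0, 1))
  emp <- empirical_critical_lods(lods, alphas = 0.05)$lod
  expect_equal(emp, critical_lod(0.05, mix), tolerance = 0.05)
})

test_that("qq tables are monotone and self-consistent on mixture draws", {
  set.seed(56)
  mix <- mixture_for_model("unconstrained_1p")
  lods <- sample_mixture_lods(2000, 1, 1)
  study <- structure(
    list(replicates = tibble::tibble(
           replicate = seq_along(lods), lod = lods, converged = TRUE,
           p = empirical_pvalues(lods)),
         model = "unconstrained_1p", n_families = NA_integer_,
         n_replicates = length(lods),
         marker = marker_model(), covariate = covariate_spec("none"),
         seed = 56),
    class = "cl_null")
  qq <- qq_table(study, mix)
  expect_true(all(diff(qq$lod) <= 0))
  expect_true(all(diff(qq$p_empirical) >= 0))
  expect_true(all(diff(qq$p_asymptotic) >= 0))
  # LODs drawn from the mixture itself: the asymptotic p of the i-th
  # ranked replicate stays inside the 95% pointwise order-statistic band
  # (up to -log10 p = 3) at about the nominal coverage
  n <- nrow(qq)
  i <- seq_len(n)
  lo <- stats::qbeta(0.025, i, n + 1 - i)
  hi <- stats::qbeta(0.975, i, n + 1 - i)
  sel <- qq$neglog10_asymptotic <= 3
  inside <- qq$p_asymptotic >= lo & qq$p_asymptotic <= hi
  expect_gt(mean(inside[sel]), 0.9)
})

test_that("lower marker information does not inflate the null LOD", {
  # the constrained CL-LR null is close to the same mixture at every
  # information level, so the contrast is near zero: test one-sided
  # with Monte-Carlo slack (2 SE of the difference in means)
  run <- function(mk, n_rep = 300) {
    st <- run_null_replicates(60, n_rep, "constrained_2p", marker = mk,
                              seed = 58)
    st$replicates$lod
  }
  lo <- run(marker_model("equifrequent", 2, parents_typed = FALSE))
  hi <- run(marker_model("fully_informative"))
  se_diff <- sqrt(stats::var(lo) / length(lo) + stats::var(hi) / length(hi))
  expect_lte(mean(lo), mean(hi) + 2 * se_diff)
})
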