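#' Marker models for simulation
#'
#' Either a fully informative marker (four distinct founder alleles per
#' family: alleles 1/2 for the father and 3/4 for the mother) or a marker
#' with `n_alleles` equally frequent alleles drawn under Hardy-Weinberg
#' equilibrium. `parents_typed = FALSE` masks both parental genotypes in
#' the simulated output.
#'
#' @param kind `"fully_informative"` or `"equifrequent"`.
#' @param n_alleles Number of equally frequent alleles (equifrequent
#'   markers).
#' @param parents_typed Report parental genotypes?
#' @return A `marker_model` list.
#' @export
marker_model <- function(kind = c("fully_informative", "equifrequent"),
                         n_alleles = NULL, parents_typed = TRUE) {
  kind <- match.arg(kind)
  if (kind == "equifrequent") {
    if (is.null(n_alleles) || n_alleles < 2) {
      abort("Equifrequent markers need `n_alleles` >= 2.")
    }
  }
  structure(list(kind = kind, n_alleles = n_alleles,
                 parents_typed = isTRUE(parents_typed)),
            class = "marker_model")
}

#' Covariate models for simulation
#'
#' Individual covariates are `N(0, 1)` draws plus a fixed `effect`
#' offset. The binary kind dichotomises the individual value at the
#' `(1 - prevalence)` quantile of its generating distribution, so the
#' population prevalence equals `prevalence` (default 0.2). The
#' pair-level covariate is the sum of the two sibs' values; sample-level
#' adjustment (mean-centering for the continuous kind,
#' minimum-adjustment for the binary kind) is applied at analysis time.
#'
#' @param kind `"none"`, `"continuous_mean_centered"`, or
#'   `"binary_minimum_adjusted"`.
#' @param effect Offset added to each individual `N(0, 1)` draw (under
#'   the null it only shifts location; default 0).
#' @param prevalence Population prevalence for the binary kind.
#' @return A `covariate_spec` list.
#' @export
covariate_spec <- function(kind = c("none", "continuous_mean_centered",
                                    "binary_minimum_adjusted"),
                           effect = 0, prevalence = 0.2) {
  kind <- match.arg(kind)
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must be in (0, 1).")
  }
  structure(list(kind = kind, effect = effect, prevalence = prevalence),
            class = "covariate_spec")
}

#' Gene-drop nuclear families with two affected sibs
#'
#' Simulates `n` independent families (two parents, two affected sibs)
#' at one unlinked marker: founder genotypes are assigned (unique
#' alleles, or Hardy-Weinberg draws from `freqs`), and each sib
#' independently receives one uniformly random allele from each parent.
#' No trait model is involved: pairs are ascertained as affected and the
#' marker is unlinked, so genotypes follow pure Mendelian segregation.
#'
#' @param n Number of families.
#' @param marker A [marker_model()].
#' @param freqs Allele frequencies (equifrequent markers only; defaults
#'   to `equal_allele_freqs(marker$n_alleles)`).
#' @return A families tibble (see [ibd_posterior()]) with an `ibd_true`
#'   column holding the realised IBD count; parental genotypes are `NA`
#'   when `marker$parents_typed` is `FALSE`.
#' @export
sim_families <- function(n, marker = marker_model(), freqs = NULL) {
  stopifnot(inherits(marker, "marker_model"), n >= 1)
  if (marker$kind == "fully_informative") {
    fa <- matrix(rep(c(1L, 2L), each = n), n, 2)
    mo <- matrix(rep(c(3L, 4L), each = n), n, 2)
  } else {
    p <- if (is.null(freqs)) equal_allele_freqs(marker$n_alleles)
         else allele_freqs(freqs)
    k <- length(p)
    draw <- function() matrix(sample.int(k, 2 * n, replace = TRUE, prob = p),
                              n, 2)
    fa <- draw(); mo <- draw()
  }
  pick <- function() sample.int(2L, n, replace = TRUE)
  fp1 <- pick(); mp1 <- pick(); fp2 <- pick(); mp2 <- pick()
  out <- tibble::tibble(
    family = seq_len(n),
    f_a1 = fa[, 1], f_a2 = fa[, 2],
    m_a1 = mo[, 1], m_a2 = mo[, 2],
    s1_a1 = fa[cbind(seq_len(n), fp1)], s1_a2 = mo[cbind(seq_len(n), mp1)],
    s2_a1 = fa[cbind(seq_len(n), fp2)], s2_a2 = mo[cbind(seq_len(n), mp2)],
    ibd_true = as.integer((fp1 == fp2) + (mp1 == mp2))
  )
  if (!marker$parents_typed) {
    out$f_a1 <- NA_integer_; out$f_a2 <- NA_integer_
    out$m_a1 <- NA_integer_; out$m_a2 <- NA_integer_
  }
  out
}

#' Simulate pair-level covariates
#'
#' @param n Number of pairs.
#' @param spec A [covariate_spec()] (kind must not be `"none"`).
#' @return A tibble with individual values `x1`, `x2` and their sum
#'   `pair_raw` (unadjusted pair covariate).
#' @export
sim_pair_covariates <- function(n, spec) {
  stopifnot(inherits(spec, "covariate_spec"))
  if (spec$kind == "none") abort("Covariate kind is 'none'.")
  z1 <- rnorm(n) + spec$effect
  z2 <- rnorm(n) + spec$effect
  if (spec$kind == "binary_minimum_adjusted") {
    thr <- qnorm(1 - spec$prevalence) + spec$effect
    z1 <- as.numeric(z1 > thr)
    z2 <- as.numeric(z2 > thr)
  }
  tibble::tibble(x1 = z1, x2 = z2, pair_raw = z1 + z2)
}

#' Sample-level covariate adjustment
#'
#' Mean-centering (`x - mean(x)`) for continuous covariates, so no
#' constraint binds on the coefficient, or minimum-adjustment
#' (`x - min(x)`) for binary/indicator covariates, which makes the
#' smallest value 0 and activates the linear constraint of the
#' constrained covariate model.
#'
#' @param x Pair-level covariate values.
#' @param method `"mean_center"` or `"minimum_adjust"`.
#' @return Adjusted values.
#' @export
adjust_covariate <- function(x, method = c("mean_center", "minimum_adjust")) {
  method <- match.arg(method)
  if (method == "mean_center") x - mean(x) else x - min(x)
}

# counter-based derivation of independent per-replicate seeds: replicate
# results do not depend on execution order
replicate_seed <- function(seed, r) {
  as.integer((as.double(seed %% 2147483647) + 48271 * as.double(r)) %%
               2147483647)
}

#' Replicate study of the null distribution of the maximised LOD
#'
#' For each replicate: gene-drop `n_families` ASP families at an
#' unlinked marker, compute IBD posteriors, simulate and adjust the pair
#' covariate if the model uses one (mean-centering for the continuous
#' kind, minimum-adjustment for the binary kind, applied per replicate
#' over the sampled pairs), maximise the LOD under `model`, and record
#' it. Each replicate uses an independently derived seed substream, so
#' the study is a pure function of `seed` and is order-independent.
#'
#' @param n_families Families (= independent ASPs) per replicate.
#' @param n_replicates Number of replicates.
#' @param model One of [cl_models].
#' @param marker A [marker_model()].
#' @param covariate A [covariate_spec()]; required non-`"none"` for
#'   covariate models, `"none"` otherwise.
#' @param freqs Optional allele frequencies for equifrequent markers.
#' @param seed Master seed.
#' @return A `cl_null` object: tibble `$replicates` with columns
#'   `replicate`, `lod`, `converged`, and `p` (empirical p-value by the
#'   rank rule, see [empirical_pvalues()]), plus the study settings.
#' @export
run_null_replicates <- function(n_families, n_replicates, model,
                                marker = marker_model(),
                                covariate = covariate_spec("none"),
                                freqs = NULL, seed = 1) {
  model <- check_model(model)
  stopifnot(inherits(marker, "marker_model"),
            inherits(covariate, "covariate_spec"),
            n_families >= 1, n_replicates >= 1)
  if (is_covariate_model(model) && covariate$kind == "none") {
    abort("Covariate models need a covariate spec other than 'none'.")
  }
  if (!is_covariate_model(model) && covariate$kind != "none") {
    abort("Non-covariate models must use covariate_spec('none').")
  }
  adj <- switch(covariate$kind,
                continuous_mean_centered = "mean_center",
                binary_minimum_adjusted = "minimum_adjust",
                NULL)
  fast <- marker$kind == "fully_informative" && covariate$kind == "none"
  if (!is.null(freqs)) freqs <- allele_freqs(freqs)

  lods <- numeric(n_replicates)
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(replicate_seed(seed, r))
    fam <- sim_families(n_families, marker, freqs)
    if (fast) {
      cnt <- tabulate(fam$ibd_true + 1L, nbins = 3L)
      fit <- cl_fit_counts(cnt[1], cnt[2], cnt[3], model = model)
    } else {
      if (marker$kind == "fully_informative") {
        ibd <- fam$ibd_true
        pairs <- tibble::tibble(g0 = as.numeric(ibd == 0),
                                g1 = as.numeric(ibd == 1),
                                g2 = as.numeric(ibd == 2))
      } else {
        p <- if (is.null(freqs)) equal_allele_freqs(marker$n_alleles)
             else freqs
        pairs <- ibd_posterior(fam, p)[c("g0", "g1", "g2")]
      }
      if (!is.null(adj)) {
        cov <- sim_pair_covariates(n_families, covariate)
        pairs$x1 <- adjust_covariate(cov$pair_raw, adj)
      }
      fit <- cl_fit(pairs, model = model)
    }
    lods[r] <- fit$lod
    conv[r] <- fit$converged
  }
  reps <- tibble::tibble(replicate = seq_len(n_replicates),
                         lod = lods, converged = conv,
                         p = empirical_pvalues(lods))
  structure(list(replicates = reps, model = model,
                 n_families = n_families, n_replicates = n_replicates,
                 marker = marker, covariate = covariate, seed = seed),
            class = "cl_null")
}

#' @export
print.cl_null <- function(x, ...) {
  cat(sprintf(
    "Empirical null study: %d replicates x %d families (%s, %s marker)\n",
    x$n_replicates, x$n_families, x$model, x$marker$kind))
  cat(sprintf("  LOD: mean %.4f, max %.4f, P(LOD = 0) = %.3f\n",
              mean(x$replicates$lod), max(x$replicates$lod),
              mean(x$replicates$lod <= 0)))
  invisible(x)
}

#' Empirical p-values by the rank rule
#'
#' Assigns `p = (r + 1) / (N + 1)` to the `r`-th ranked LOD score,
#' counting `r` from 0 at the largest value downward; ties are broken by
#' input order (stable sort), so the maximum receives `1 / (N + 1)`.
#'
#' @param lods Numeric vector of maximised LOD scores.
#' @return p-values aligned with `lods`, in `(0, 1)`.
#' @export
empirical_pvalues <- function(lods) {
  if (length(lods) == 0) abort("`lods` must be nonempty.")
  n <- length(lods)
  ord <- order(-lods) # stable: ties keep input order
  p <- numeric(n)
  p[ord] <- seq_len(n) / (n + 1)
  p
}

#' Empirical critical LOD scores
#'
#' The LOD whose empirical p-value is the largest value `<= alpha`,
#' i.e. the `ceiling(alpha (N + 1))`-th largest LOD.
#'
#' @param x A `cl_null` object or a numeric vector of LODs.
#' @param alphas Test sizes; each must be at least `1 / (N + 1)`.
#' @return A tibble with columns `alpha` and `lod`.
#' @export
empirical_critical_lods <- function(x, alphas = c(0.05, 0.01, 0.001, 0.0001)) {
  lods <- if (inherits(x, "cl_null")) x$replicates$lod else as.numeric(x)
  n <- length(lods)
  if (any(alphas < 1 / (n + 1))) {
    abort(sprintf(
      "alpha below the attainable resolution; the minimum is 1/(N+1) = %.3g.",
      1 / (n + 1)))
  }
  srt <- sort(lods, decreasing = TRUE)
  tibble::tibble(alpha = alphas,
                 lod = srt[ceiling(alphas * (n + 1))])
}

#' Empirical vs asymptotic p-values (QQ table)
#'
#' One row per replicate, sorted by LOD (descending): the LOD, its
#' empirical p-value, its asymptotic p-value under `mix`, and both on
#' the -log10 scale.
#'
#' @param x A `cl_null` object.
#' @param mix The asymptotic null [chisq_mixture()] to compare with.
#' @return A tibble with columns `lod`, `p_empirical`, `p_asymptotic`,
#'   `neglog10_empirical`, `neglog10_asymptotic`.
#' @export
qq_table <- function(x, mix) {
  stopifnot(inherits(x, "cl_null"))
  tb <- x$replicates[order(-x$replicates$lod, x$replicates$replicate), ]
  tibble::tibble(
    lod = tb$lod,
    p_empirical = tb$p,
    p_asymptotic = asymptotic_pvalue(tb$lod, mix),
    neglog10_empirical = -log10(tb$p),
    neglog10_asymptotic = -log10(asymptotic_pvalue(tb$lod, mix))
  )
}
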