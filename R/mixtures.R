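#' Chi-square mixture distributions
#'
#' A chi-bar-square null distribution: nonnegative weights (summing to 1)
#' on chi-square components; `df = 0` denotes a point mass at zero.
#'
#' @param weights Nonnegative weights summing to 1 (within 1e-12).
#' @param df Degrees of freedom per component (`>= 0`; 0 = point mass).
#' @return A `chisq_mixture` tibble with columns `weight` and `df`.
#' @examples
#' chisq_mixture(c(0.5, 0.5), c(0, 1)) # constrained one-parameter null
#' @export
chisq_mixture <- function(weights, df) {
  if (length(weights) != length(df)) {
    abort("`weights` and `df` must have the same length.")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    abort("Mixture weights must be nonnegative and sum to 1.")
  }
  if (any(df < 0)) abort("Degrees of freedom must be >= 0.")
  structure(tibble::tibble(weight = as.numeric(weights),
                           df = as.numeric(df)),
            class = c("chisq_mixture", "tbl_df", "tbl", "data.frame"))
}

#' Asymptotic null mixture of each analysis model
#'
#' * `unconstrained_2p`: chi-square, 2 df.
#' * `constrained_2p`: `(1/2 - c) chi2_0 + 1/2 chi2_1 + c chi2_2`
#'   (`c` from the triangle geometry, see [mixing_proportion()]).
#' * `unconstrained_1p`: chi-square, 1 df.
#' * `constrained_1p`: 50:50 point mass at 0 and chi2_1.
#' * `unconstrained_covariate` (K covariates): 50:50 chi2_K and
#'   chi2_(K+1).
#' * `constrained_covariate`: no general asymptotic null exists (it
#'   depends on the covariate distribution in the data); the returned
#'   50:50 point mass at 0 and chi2_1 is the empirically supported
#'   approximation for a single minimum-adjusted binary covariate, and a
#'   warning is raised.
#'
#' @param model One of [cl_models].
#' @param c Mixing proportion (required for, and only for,
#'   `"constrained_2p"`); in (0, 1/2).
#' @param n_covariates Number of covariates K (covariate models).
#' @return A [chisq_mixture()].
#' @export
mixture_for_model <- function(model, c = NULL, n_covariates = 1) {
  model <- check_model(model)
  if (model == "constrained_2p") {
    if (is.null(c) || c <= 0 || c >= 0.5) {
      abort("`constrained_2p` needs a mixing proportion c in (0, 1/2).")
    }
  } else if (!is.null(c)) {
    abort("`c` is only used by the constrained_2p model.")
  }
  if (is_covariate_model(model) && n_covariates < 1) {
    abort("Covariate models need n_covariates >= 1.")
  }
  switch(model,
    unconstrained_2p = chisq_mixture(1, 2),
    constrained_2p = chisq_mixture(c(1 / 2 - c, 1 / 2, c), c(0, 1, 2)),
    unconstrained_1p = chisq_mixture(1, 1),
    constrained_1p = chisq_mixture(c(1 / 2, 1 / 2), c(0, 1)),
    unconstrained_covariate =
      chisq_mixture(c(1 / 2, 1 / 2), c(n_covariates, n_covariates + 1)),
    constrained_covariate = {
      warn(paste(
        "The null of the constrained covariate model depends on the",
        "covariate distribution in the data; returning the 50:50 point",
        "mass / chi2_1 approximation supported for one minimum-adjusted",
        "binary covariate. Prefer simulation for p-values."))
      chisq_mixture(c(1 / 2, 1 / 2), c(0, 1))
    }
  )
}

#' Tail probability of a chi-square mixture
#'
#' `P(X > x)` for `x > 0`; at `x = 0` the full mass (including any point
#' mass at zero) is returned, so the survival function is 1 there.
#'
#' @param x Nonnegative quantile(s) on the chi-square (CL-LR) scale.
#' @param mix A [chisq_mixture()].
#' @return Tail probabilities in \[0, 1\].
#' @export
mixture_survival <- function(x, mix) {
  if (any(x < 0)) abort("`x` must be nonnegative.")
  stopifnot(inherits(mix, "chisq_mixture"))
  pos <- mix$df > 0
  s <- vapply(x, function(xi) {
    sum(mix$weight[pos] * pchisq(xi, mix$df[pos], lower.tail = FALSE))
  }, numeric(1))
  w0 <- sum(mix$weight[!pos])
  s + w0 * (x <= 0)
}

#' Critical LOD score of a mixture null
#'
#' Solves `P(CL-LR > 2 ln(10) L) = alpha` for the LOD score `L`, by
#' root-finding on `L` in \[0, 20\].
#'
#' @param alpha Test size, strictly between 0 and the mixture's mass
#'   above zero.
#' @inheritParams mixture_survival
#' @return Critical LOD score(s).
#' @examples
#' critical_lod(0.0001, mixture_for_model("unconstrained_covariate",
#'                                        n_covariates = 1)) # 3.77
#' @export
critical_lod <- function(alpha, mix) {
  stopifnot(inherits(mix, "chisq_mixture"))
  attainable <- sum(mix$weight[mix$df > 0])
  vapply(alpha, function(a) {
    if (a <= 0 || a >= attainable) {
      abort(sprintf(
        "alpha must be in (0, %.4g), the mixture's mass above zero.",
        attainable))
    }
    uniroot(function(L) mixture_survival(2 * ln10 * L, mix) - a,
            lower = 1e-12, upper = 20, tol = 1e-12)$root
  }, numeric(1))
}

#' Asymptotic p-value of a LOD score
#'
#' @param lod Nonnegative LOD score(s).
#' @inheritParams mixture_survival
#' @return `P(CL-LR > 2 ln(10) lod)` under the mixture null (1 at
#'   `lod = 0`).
#' @export
asymptotic_pvalue <- function(lod, mix) {
  if (any(lod < 0)) abort("`lod` must be nonnegative.")
  mixture_survival(2 * ln10 * lod, mix)
}

#' Critical LOD scores of the constrained two-parameter model
#'
#' Tabulates critical LOD scores for the `(1/2 - c, 1/2, c)` mixture at
#' the four canonical mixing proportions: the CL minimum (tangent-line
#' A2 geometry), the A1 value, the CL maximum (the boundary-asymptote
#' limit), and the classical allele-sharing (RH) value, across test
#' sizes including the LOD-3 criterion (1e-4) and the genome-wide
#' significance level 4.9e-5.
#'
#' @param alphas Test sizes (columns of the table).
#' @return A tibble with one row per mixing-proportion choice: columns
#'   `mixing`, `c`, and one column per test size.
#' @export
critical_lod_table <- function(alphas = c(0.05, 0.01, 0.001, 0.0001,
                                          0.000049, 0.00001)) {
  cs <- c("CL-c_min" = mixing_proportion(cl_triangle("A2")),
          "A1-c" = mixing_proportion(cl_triangle("A1")),
          "CL-c_max" = mixing_proportion_limit(),
          "RH-c" = rh_mixing_proportion())
  rows <- purrr::imap(cs, function(cc, nm) {
    mix <- mixture_for_model("constrained_2p", c = cc)
    vals <- critical_lod(alphas, mix)
    tibble::tibble(mixing = nm, c = cc,
                   !!!setNames(as.list(vals), paste0("alpha_", alphas)))
  })
  dplyr::bind_rows(rows)
}
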