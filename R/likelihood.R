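ln10 <- log(10)

#' Analysis models
#'
#' The six constraint regimes for the conditional-logistic LOD score:
#'
#' * `"unconstrained_2p"`: (beta1, beta2) free on the plane.
#' * `"constrained_2p"`: possible-triangle genetic constraints
#'   `beta1 >= 0`, `beta2 >= log(2 exp(beta1) - 1)`.
#' * `"unconstrained_1p"`: minmax one-parameter model, beta1 free.
#' * `"constrained_1p"`: minmax model with `beta1 >= 0`.
#' * `"unconstrained_covariate"`: constrained one-parameter base with free
#'   coefficients for mean-centered pair covariates.
#' * `"constrained_covariate"`: additionally, for minimum-adjusted
#'   covariates, `min over observed x > 0 of sum_j x_j delta_j >= -beta1`.
#'
#' @export
cl_models <- c("unconstrained_2p", "constrained_2p",
               "unconstrained_1p", "constrained_1p",
               "unconstrained_covariate", "constrained_covariate")

minmax_pi <- 2.634

is_covariate_model <- function(model) {
  model %in% c("unconstrained_covariate", "constrained_covariate")
}

check_model <- function(model) {
  model <- match.arg(model, cl_models)
  model
}

#' Minmax tie between the two log relative risks
#'
#' The one-parameter model fixes `lambda2 = (pi + 1) lambda1 - pi` with
#' `pi = 2.634`, i.e. `beta2 = log(3.634 exp(beta1) - 2.634)`, a mode of
#' inheritance approximately halfway between recessive and dominant.
#'
#' @param beta1 Log relative risk for sharing one allele IBD.
#' @return `beta2` implied by the minmax constraint.
#' @export
minmax_beta2 <- function(beta1) {
  arg <- (minmax_pi + 1) * exp(beta1) - minmax_pi
  if (any(arg <= 0)) {
    abort("minmax beta2 undefined: 3.634*exp(beta1) - 2.634 must be > 0.")
  }
  log(arg)
}

#' No-dominance boundary of the genetic constraint region
#'
#' The lower boundary `beta2 = log(2 exp(beta1) - 1)` (equivalently
#' `lambda2 = 2 lambda1 - 1`) of the possible-triangle constraints; its
#' tangent at the null has slope 2 (`beta2 ~ 2 beta1`).
#'
#' @inheritParams minmax_beta2
#' @return Boundary value of `beta2`.
#' @export
constraint_boundary_beta2 <- function(beta1) {
  arg <- 2 * exp(beta1) - 1
  if (any(arg <= 0)) {
    abort("Constraint boundary undefined: 2*exp(beta1) - 1 must be > 0.")
  }
  log(arg)
}

clip_exp <- function(eta, warn = FALSE) {
  if (any(abs(eta) > 700)) {
    if (warn) warn("Exponent clipped to +-700 to avoid overflow.")
    eta <- pmin(pmax(eta, -700), 700)
  }
  exp(eta)
}

#' Allele-sharing relative risks from model parameters
#'
#' Computes `(lambda0, lambda1, lambda2)` with `lambda0 = 1` and
#' log-linear (multiplicative) covariate effects:
#' `lambda1 = exp(beta1 + sum_j delta_j x_j)`. In two-parameter models
#' `lambda2 = exp(beta2)`; in one-parameter (minmax) models `beta2` is not
#' free and `lambda2 = 3.634 lambda1 - 2.634` is applied to the
#' covariate-adjusted `lambda1`.
#'
#' @inheritParams minmax_beta2
#' @param beta2 Log relative risk for sharing two alleles IBD, or `NULL`
#'   to tie it by the minmax relation.
#' @param deltas Covariate coefficients (one-parameter models only).
#' @param x Pair-level covariate values, same length as `deltas`.
#' @return Named numeric vector `c(lambda0, lambda1, lambda2)`.
#' @export
relative_risks <- function(beta1, beta2 = NULL, deltas = numeric(0),
                           x = numeric(0)) {
  if (length(deltas) != length(x)) {
    abort("`deltas` and `x` must have the same length.")
  }
  if (!is.null(beta2) && length(deltas) > 0) {
    abort("Covariates are not allowed in the two-parameter model.")
  }
  l1 <- clip_exp(beta1 + sum(deltas * x), warn = TRUE)
  l2 <- if (is.null(beta2)) {
    v <- (minmax_pi + 1) * l1 - minmax_pi
    if (v <= 0) abort("Covariate-adjusted lambda2 is nonpositive.")
    v
  } else {
    clip_exp(beta2, warn = TRUE)
  }
  c(lambda0 = 1, lambda1 = unname(l1), lambda2 = unname(l2))
}

#' Likelihood-ratio contribution of one pair
#'
#' `LR = sum_i lambda_i ghat_i / sum_i lambda_i f_i`, where `ghat` is the
#' marker-conditional IBD distribution and `f` the prior.
#'
#' @param posterior Length-3 IBD posterior `(g0, g1, g2)`.
#' @param lambda Length-3 relative risks `(lambda0, lambda1, lambda2)`.
#' @param prior Length-3 IBD prior, default the full-sib prior.
#' @return Positive likelihood ratio.
#' @export
pair_likelihood_ratio <- function(posterior, lambda,
                                  prior = ibd_prior_asp()) {
  if (any(lambda <= 0)) abort("Relative risks must be strictly positive.")
  sum(lambda * posterior) / sum(lambda * prior)
}

# ---- pair data --------------------------------------------------------------

covariate_columns <- function(pairs) {
  nm <- names(pairs)
  if ("x" %in% nm && !("x1" %in% nm)) return("x")
  sort(grep("^x[0-9]+$", nm, value = TRUE))
}

pairs_data <- function(pairs, model, prior) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0) {
    abort("`pairs` must be a nonempty data frame.")
  }
  need <- c("g0", "g1", "g2")
  if (!all(need %in% names(pairs))) {
    abort("`pairs` needs posterior columns g0, g1, g2.")
  }
  G <- as.matrix(pairs[need])
  if (any(G < 0) || any(abs(rowSums(G) - 1) > 1e-8)) {
    abort("Each posterior row must be nonnegative and sum to 1.")
  }
  xc <- covariate_columns(pairs)
  if (is_covariate_model(model)) {
    if (length(xc) == 0) {
      abort("Covariate models need covariate column(s) x (or x1, x2, ...).")
    }
    X <- as.matrix(pairs[xc])
  } else {
    X <- NULL
  }
  # collapse identical (posterior, covariate) rows: the LOD is additive,
  # so duplicated rows only scale the same term
  key <- cbind(G, X)
  id <- match(
    apply(key, 1L, paste, collapse = "\r"),
    apply(key, 1L, paste, collapse = "\r")
  )
  first <- !duplicated(id)
  w <- tabulate(match(id, id[first]), nbins = sum(first))
  list(G = G[first, , drop = FALSE],
       X = if (is.null(X)) NULL else X[first, , drop = FALSE],
       w = w, n = nrow(G), prior = prior)
}

# log-likelihood-ratio (natural log) at given lambdas; l1, l2 may be
# scalars (no covariates) or per-row vectors (covariate models)
llr_value <- function(d, l1, l2) {
  num <- d$G[, 1] + l1 * d$G[, 2] + l2 * d$G[, 3]
  den <- d$prior[1] + l1 * d$prior[2] + l2 * d$prior[3]
  if (any(num <= 0) || any(den <= 0)) return(-Inf)
  sum(d$w * (log(num) - log(den)))
}

#' Sample LOD score at fixed parameters
#'
#' Sums the base-10 logarithms of the pair-specific likelihood ratios.
#' Covariates (columns `x` or `x1..xK` of `pairs`, already adjusted) enter
#' the relative risks per pair.
#'
#' @param pairs Data frame with posterior columns `g0, g1, g2` and, for
#'   covariate models, covariate column(s).
#' @inheritParams relative_risks
#' @param prior IBD prior of the pairs.
#' @return The LOD score (base-10).
#' @export
cl_lod <- function(pairs, beta1, beta2 = NULL, deltas = numeric(0),
                   prior = ibd_prior_asp()) {
  prior <- check_prior(prior)
  model <- if (length(deltas) > 0) "unconstrained_covariate"
           else "unconstrained_2p"
  d <- pairs_data(pairs, model, prior)
  if (length(deltas) > 0) {
    if (ncol(d$X) != length(deltas)) {
      abort("Length of `deltas` must match the number of covariate columns.")
    }
    eta <- beta1 + as.vector(d$X %*% deltas)
    l1 <- clip_exp(eta)
    l2 <- (minmax_pi + 1) * l1 - minmax_pi
    if (any(l2 <= 0)) abort("Covariate-adjusted lambda2 is nonpositive.")
  } else {
    l1 <- clip_exp(beta1)
    l2 <- if (is.null(beta2)) {
      v <- (minmax_pi + 1) * l1 - minmax_pi
      if (v <= 0) abort("minmax lambda2 is nonpositive at this beta1.")
      v
    } else clip_exp(beta2)
  }
  llr_value(d, l1, l2) / ln10
}

# ---- maximisation engine ----------------------------------------------------

beta_bound <- 10

# objective over free parameters for each model; returns function(par) lod*ln10
model_objective <- function(model, d) {
  switch(model,
    unconstrained_2p = function(par) {
      llr_value(d, clip_exp(par[1]), clip_exp(par[2]))
    },
    constrained_2p = function(par) {
      b1 <- par[1]^2
      b2 <- constraint_boundary_beta2(b1) + par[2]^2
      llr_value(d, exp(b1), clip_exp(b2))
    },
    unconstrained_1p = ,
    constrained_1p = function(par) {
      l1 <- clip_exp(par[1])
      l2 <- (minmax_pi + 1) * l1 - minmax_pi
      if (l2 <= 0) return(-Inf)
      llr_value(d, l1, l2)
    },
    unconstrained_covariate = function(par) {
      eta <- par[1] + as.vector(d$X %*% par[-1])
      l1 <- clip_exp(eta)
      l2 <- (minmax_pi + 1) * l1 - minmax_pi
      if (any(l2 <= 0)) {
        # smooth pull back into the feasible region
        return(-1e6 * (1 + (log(minmax_pi / (minmax_pi + 1)) - min(eta))^2))
      }
      llr_value(d, l1, l2)
    },
    constrained_covariate = function(par) {
      # par = (a, b) with beta1 = a^2, delta = b^2 - a^2 / xmax (K = 1);
      # built in fit_engine via closure, unused here
      abort("internal: constrained_covariate objective is built in fit_engine.")
    }
  )
}

optim_box <- function(fn, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-9), upper - 1e-9)
    res <- tryCatch(
      optim(s, fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = 500, factr = 1e3)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      res <- optim(s, fn, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 2000,
                                  reltol = 1e-14))
    }
    if (is.null(best) || res$value > best$value) best <- res
  }
  best
}

jitters_2d <- list(c(0.4, 0.4), c(-0.4, 0.4), c(0.4, -0.4))

moment_lambdas <- function(d) {
  zbar <- colSums(d$w * d$G) / sum(d$w)
  zbar <- pmax(zbar, 1e-6)
  c(l1 = zbar[2] * d$prior[1] / (d$prior[2] * zbar[1]),
    l2 = zbar[3] * d$prior[1] / (d$prior[3] * zbar[1]))
}

fit_engine <- function(d, model) {
  obj <- model_objective(model, d)
  lam <- moment_lambdas(d)
  bm <- pmin(pmax(log(lam), -beta_bound + 1e-6), beta_bound - 1e-6)

  if (model %in% c("unconstrained_1p", "constrained_1p")) {
    lo <- if (model == "constrained_1p") 0 else log(minmax_pi / (minmax_pi + 1)) + 1e-8
    op <- optimize(function(b) obj(b), c(lo, beta_bound),
                   maximum = TRUE, tol = 1e-10)
    cand_b <- c(op$maximum, lo, 0)
    cand_v <- c(op$objective, obj(lo), 0)
    i <- which.max(cand_v)
    b1 <- cand_b[i]
    return(list(beta1 = b1, beta2 = minmax_beta2(b1), deltas = numeric(0),
                value = cand_v[i], converged = TRUE, n_starts = 1L))
  }

  if (model == "unconstrained_2p") {
    starts <- c(list(c(0, 0), bm), lapply(jitters_2d, function(j) bm + j))
    best <- optim_box(obj, starts, rep(-beta_bound, 2), rep(beta_bound, 2))
    return(list(beta1 = best$par[1], beta2 = best$par[2],
                deltas = numeric(0), value = max(best$value, 0),
                converged = best$convergence == 0,
                n_starts = length(starts)))
  }

  if (model == "constrained_2p") {
    b1s <- max(bm[1], 0)
    u2s <- sqrt(max(bm[2] - constraint_boundary_beta2(b1s), 0))
    us <- c(sqrt(b1s), u2s)
    starts <- c(list(c(0, 0), us), lapply(jitters_2d, function(j) us + j))
    ub <- sqrt(beta_bound)
    best <- optim_box(obj, starts, rep(-ub, 2), rep(ub, 2))
    b1 <- best$par[1]^2
    return(list(beta1 = b1,
                beta2 = constraint_boundary_beta2(b1) + best$par[2]^2,
                deltas = numeric(0), value = max(best$value, 0),
                converged = best$convergence == 0,
                n_starts = length(starts)))
  }

  # covariate models: par = (beta1, delta_1..K)
  K <- ncol(d$X)
  if (model == "unconstrained_covariate") {
    b1s <- max(bm[1], 0)
    starts <- c(
      list(c(0, rep(0, K)), c(b1s, rep(0, K))),
      lapply(c(0.4, -0.4, 0.8, -0.8), function(j) c(b1s, rep(j, K))),
      lapply(c(0.4, -0.4), function(j) c(0, rep(j, K))))
    best <- optim_box(obj, starts, c(0, rep(-beta_bound, K)),
                      rep(beta_bound, K + 1))
    # Nelder-Mead polish: the feasibility penalty kinks the surface
    pol <- optim(best$par, function(p) obj(c(max(p[1], 0), p[-1])),
                 method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = 2000,
                                reltol = 1e-13))
    if (pol$value > best$value) {
      best <- pol
      best$par[1] <- max(best$par[1], 0)
    }
    return(list(beta1 = best$par[1], beta2 = minmax_beta2(best$par[1]),
                deltas = best$par[-1], value = max(best$value, 0),
                converged = best$convergence == 0,
                n_starts = length(starts)))
  }

  # constrained_covariate
  xpos <- d$X[d$X > 0]
  if (K == 1 && length(xpos) > 0) {
    xmax <- max(xpos)
    # exact smooth reparameterisation of {beta1 >= 0, beta1 + xmax*delta >= 0}
    objc <- function(par) {
      b1 <- par[1]^2
      delta <- par[2]^2 - b1 / xmax
      eta <- b1 + as.vector(d$X) * delta
      l1 <- clip_exp(eta)
      l2 <- (minmax_pi + 1) * l1 - minmax_pi
      if (any(l2 <= 0)) {
        return(-1e6 * (1 + (log(minmax_pi / (minmax_pi + 1)) - min(eta))^2))
      }
      llr_value(d, l1, l2)
    }
    b1s <- max(bm[1], 0)
    us <- c(sqrt(b1s), sqrt(b1s / xmax))
    starts <- c(list(c(0, 0), us, c(0, 0.5), c(0.5, 0)),
                lapply(jitters_2d, function(j) us + j))
    ub <- sqrt(beta_bound)
    best <- optim_box(objc, starts, c(-ub, -ub), c(ub, ub))
    pol <- optim(best$par, objc, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = 2000,
                                reltol = 1e-13))
    if (pol$value > best$value) best <- pol
    b1 <- best$par[1]^2
    return(list(beta1 = b1, beta2 = minmax_beta2(b1),
                deltas = best$par[2]^2 - b1 / xmax,
                value = max(best$value, 0),
                converged = best$convergence == 0,
                n_starts = length(starts)))
  }
  # K > 1 (or no positive covariate values): quadratic-penalty Nelder-Mead
  penalty <- 1e8
  objp <- function(par) {
    b1 <- par[1]
    if (b1 < 0) return(-penalty * (1 + b1^2))
    s <- as.vector(d$X %*% par[-1])
    active <- apply(d$X > 0, 1L, any)
    viol <- if (any(active)) pmax(0, -(b1 + s[active])) else 0
    base <- model_objective("unconstrained_covariate", d)(par)
    base - penalty * sum(viol^2)
  }
  s0 <- c(0, rep(0, K))
  starts <- list(s0, c(max(bm[1], 0), rep(0, K)),
                 c(max(bm[1], 0), rep(0.3, K)))
  best <- NULL
  for (s in starts) {
    res <- optim(s, objp, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = 5000, reltol = 1e-14))
    if (is.null(best) || res$value > best$value) best <- res
  }
  list(beta1 = max(best$par[1], 0), beta2 = minmax_beta2(max(best$par[1], 0)),
       deltas = best$par[-1], value = max(best$value, 0),
       converged = best$convergence == 0, n_starts = length(starts))
}

new_cl_fit <- function(eng, model, n_pairs, prior) {
  lod <- eng$value / ln10
  if (lod < 0 && lod > -1e-8) lod <- 0
  structure(
    list(model = model, beta1 = eng$beta1, beta2 = eng$beta2,
         deltas = eng$deltas, lod = lod, lr = 2 * ln10 * lod,
         converged = eng$converged, n_starts_used = eng$n_starts,
         n_pairs = n_pairs, prior = prior),
    class = "cl_fit"
  )
}

#' Maximise the conditional-logistic LOD score
#'
#' Maximises the sample LOD over the feasible parameter set of the chosen
#' analysis model (see [cl_models]). Constrained regions are handled by
#' exact smooth reparameterisations; optimisation is multi-start (null
#' point, a moment-based start from the pooled posterior, and fixed
#' jittered starts), with parameters kept in `[-10, 10]` for numerical
#' safety. The null is always feasible, so the maximised LOD is >= 0.
#'
#' @inheritParams cl_lod
#' @param model One of [cl_models].
#' @return A `cl_fit` object with elements `beta1`, `beta2`, `deltas`,
#'   `lod`, `lr = 2 ln(10) lod`, `converged`, `n_starts_used`, `n_pairs`.
#'   [tidy()] and [glance()] methods are available.
#' @examples
#' pairs <- tibble::tibble(g0 = c(1, 0, 0), g1 = c(0, 1, 0),
#'                         g2 = c(0, 0, 1))
#' cl_fit(pairs[c(rep(1, 10), rep(2, 50), rep(3, 40)), ],
#'        model = "unconstrained_2p")
#' @export
cl_fit <- function(pairs, model = "constrained_2p",
                   prior = ibd_prior_asp()) {
  model <- check_model(model)
  prior <- check_prior(prior)
  d <- pairs_data(pairs, model, prior)
  eng <- fit_engine(d, model)
  new_cl_fit(eng, model, d$n, prior)
}

#' Maximise the LOD from IBD counts (fully informative fast path)
#'
#' At a fully informative marker every posterior is an indicator, so a
#' sample of pairs collapses to counts `(n0, n1, n2)` of pairs sharing 0,
#' 1, 2 alleles IBD. Covariate models are not available on counts.
#'
#' @param n0,n1,n2 Pair counts by IBD sharing.
#' @inheritParams cl_fit
#' @return A `cl_fit` object (see [cl_fit()]).
#' @export
cl_fit_counts <- function(n0, n1, n2, model = "constrained_2p",
                          prior = ibd_prior_asp()) {
  model <- check_model(model)
  if (is_covariate_model(model)) {
    abort("Covariate models need per-pair data; use cl_fit().")
  }
  prior <- check_prior(prior)
  if (n0 < 0 || n1 < 0 || n2 < 0 || n0 + n1 + n2 == 0) {
    abort("Counts must be nonnegative with a positive total.")
  }
  d <- list(G = diag(3), w = c(n0, n1, n2), X = NULL,
            n = n0 + n1 + n2, prior = prior)
  keep <- d$w > 0
  d$G <- d$G[keep, , drop = FALSE]
  d$w <- d$w[keep]
  eng <- fit_engine(d, model)
  new_cl_fit(eng, model, d$n, prior)
}

#' CL-LR statistic of a fit
#'
#' The likelihood-ratio statistic on the chi-square scale,
#' `2 ln(10) * LOD`.
#'
#' @param fit A `cl_fit` object, or a numeric LOD score.
#' @return Nonnegative numeric.
#' @export
lr_statistic <- function(fit) {
  lod <- if (inherits(fit, "cl_fit")) fit$lod else fit
  if (any(lod < 0)) abort("LOD must be nonnegative.")
  2 * ln10 * lod
}

#' @export
print.cl_fit <- function(x, ...) {
  cat("Conditional-logistic ASP fit (", x$model, ")\n", sep = "")
  cat(sprintf("  pairs: %d   LOD: %.4f   CL-LR: %.4f\n",
              x$n_pairs, x$lod, x$lr))
  cat(sprintf("  beta1: %.4f   beta2: %.4f", x$beta1, x$beta2))
  if (length(x$deltas) > 0) {
    cat("   delta:", paste(sprintf("%.4f", x$deltas), collapse = " "))
  }
  cat(sprintf("\n  converged: %s (%d starts)\n",
              x$converged, x$n_starts_used))
  invisible(x)
}

#' @rdname cl_fit
#' @param x A `cl_fit` object.
#' @param ... Unused.
#' @method tidy cl_fit
#' @export
tidy.cl_fit <- function(x, ...) {
  terms <- c("beta1", "beta2",
             if (length(x$deltas) > 0) paste0("delta", seq_along(x$deltas)))
  tibble::tibble(term = terms,
                 estimate = c(x$beta1, x$beta2, x$deltas))
}

#' @rdname cl_fit
#' @method glance cl_fit
#' @export
glance.cl_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lod = x$lod, lr = x$lr,
                 converged = x$converged,
                 n_starts_used = x$n_starts_used, n_pairs = x$n_pairs)
}
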