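#' Per-pair Fisher information of the CL model at the null
#'
#' Under complete marker information the score of the two-parameter CL
#' likelihood at the null is built from the IBD-sharing indicators
#' `(1{IBD=1}, 1{IBD=2})`, whose covariance under the full-sib prior
#' (1/4, 1/2, 1/4) is the per-pair information
#' `I = [[1/4, -1/8], [-1/8, 3/16]]`, with inverse (the parameter
#' covariance) `[[6, 4], [4, 8]]`.
#'
#' @return A list with `information` and `covariance` (2x2 matrices).
#' @export
asp_information_null <- function() {
  info <- matrix(c(1 / 4, -1 / 8, -1 / 8, 3 / 16), 2, 2)
  list(information = info, covariance = solve(info))
}

#' Constraint-cone triangles for the mixing-proportion geometry
#'
#' Builds the vertices `N` (null), `A` (additive point, on the
#' no-dominance boundary `beta2 = log(2 exp(beta1) - 1)`) and `D`
#' (dominant point, on the `beta2` axis at the same height) used to
#' approximate the constraint cone in the `(beta1, beta2)` plane:
#'
#' * `"A1"`: `A = (1/2, log(2 e^{1/2} - 1))` (upper value 1/2 for beta1);
#' * `"A2"`: the tangent line at the null, `beta2 = 2 beta1`, giving ray
#'   directions `A - N = (1, 2)` and `D - N = (0, 1)` (upper bound
#'   irrelevant);
#' * `"A3"`: `A = (1, log(2e - 1))` (offspring relative risk up to
#'   `e ~ 2.718`);
#' * `"custom"`: the exact boundary at `beta1 = beta1_max`.
#'
#' Explicit `A` and `D` (points on the two cone rays) may be given
#' instead, e.g. for the allele-sharing (RH) cone.
#'
#' @param assumption One of `"A1"`, `"A2"`, `"A3"`, `"custom"`.
#' @param beta1_max Positive upper value for `beta1` (required for
#'   `"custom"`).
#' @param A,D Optional explicit ray points, overriding `assumption`.
#' @return A `cl_triangle` list with `N`, `A`, `D`, `assumption`.
#' @export
cl_triangle <- function(assumption = c("A1", "A2", "A3", "custom"),
                        beta1_max = NULL, A = NULL, D = NULL) {
  if (!is.null(A) || !is.null(D)) {
    if (is.null(A) || is.null(D)) abort("Give both `A` and `D` or neither.")
    tri <- list(N = c(0, 0), A = as.numeric(A), D = as.numeric(D),
                assumption = "explicit")
    return(structure(tri, class = "cl_triangle"))
  }
  assumption <- match.arg(assumption)
  tri <- switch(assumption,
    A1 = {
      h <- constraint_boundary_beta2(0.5)
      list(A = c(0.5, h), D = c(0, h))
    },
    A2 = list(A = c(1, 2), D = c(0, 1)),
    A3 = {
      h <- constraint_boundary_beta2(1)
      list(A = c(1, h), D = c(0, h))
    },
    custom = {
      if (is.null(beta1_max) || beta1_max <= 0) {
        abort("`beta1_max` must be a positive number for a custom triangle.")
      }
      h <- constraint_boundary_beta2(beta1_max)
      list(A = c(beta1_max, h), D = c(0, h))
    }
  )
  structure(list(N = c(0, 0), A = tri$A, D = tri$D,
                 assumption = assumption),
            class = "cl_triangle")
}

# spectral decomposition with a fixed convention: eigenvalues descending,
# leading entry of the first eigenvector positive, det(P) = +1 (a proper
# rotation), so intermediate vertices are reproducible
fixed_eigen <- function(covariance) {
  if (max(abs(covariance - t(covariance))) > 1e-12) {
    abort("Covariance matrix must be symmetric.")
  }
  ev <- eigen(covariance, symmetric = TRUE)
  if (any(ev$values <= 0)) abort("Covariance matrix must be positive definite.")
  P <- ev$vectors
  if (abs(ev$values[1] - ev$values[2]) < 1e-12 * abs(ev$values[1])) {
    P <- diag(2) # wholly degenerate decomposition: canonical basis
  }
  if (P[1, 1] < 0) P[, 1] <- -P[, 1]
  if (det(P) < 0) P[, 2] <- -P[, 2]
  list(values = ev$values, P = P)
}

#' Transform and rotate a constraint triangle
#'
#' Implements the Self-Liang construction for the mixing proportion of
#' the boundary-constrained LR statistic: spectrally decompose the
#' parameter covariance `cov = P Lambda P^T`, map the triangle vertices
#' by `Lambda^{1/2} P^T` (convention `"paper"`) or by the sphering map
#' `Lambda^{-1/2} P^T` (convention `"whiten"`), then rotate rigidly so
#' the image of `A` lies on the positive horizontal axis with the image
#' of `D` in the upper half-plane. The angle `theta` between the rotated
#' rays `N->A` and `N->D` gives the mixing proportion
#' `c = theta / (2 pi)`.
#'
#' The two conventions genuinely differ: `"paper"` reproduces the CL
#' triangle values reported for this model, while `"whiten"` is the
#' standard sphering that reproduces the classical allele-sharing (RH)
#' value `c ~ 0.098` (see [rh_mixing_proportion()]).
#'
#' @param triangle A [cl_triangle()].
#' @param covariance Parameter covariance matrix (2x2, positive
#'   definite); default the null ASP covariance `[[6,4],[4,8]]`.
#' @param convention `"paper"` or `"whiten"`.
#' @return A `cl_geometry` list with the transformed vertices `Y_A`,
#'   `Y_D`, rotated vertices `y_A`, `y_D`, the angle `theta` (radians)
#'   and mixing proportion `c`, plus the decomposition used.
#' @examples
#' g <- cl_geometry(cl_triangle("A1"))
#' round(g$theta, 3) # 0.316
#' round(g$c, 3)     # 0.050
#' @export
cl_geometry <- function(triangle = cl_triangle("A1"),
                        covariance = asp_information_null()$covariance,
                        convention = c("paper", "whiten")) {
  convention <- match.arg(convention)
  if (!inherits(triangle, "cl_triangle")) {
    abort("`triangle` must be built with cl_triangle().")
  }
  dec <- fixed_eigen(covariance)
  pw <- if (convention == "paper") 0.5 else -0.5
  S <- diag(dec$values^pw)
  tr <- function(v) as.vector(S %*% t(dec$P) %*% (v - triangle$N))
  YA <- tr(triangle$A)
  YD <- tr(triangle$D)
  if (sqrt(sum(YA^2)) < 1e-12 || sqrt(sum(YD^2)) < 1e-12) {
    abort("Degenerate triangle: A or D coincides with N.")
  }
  ang <- atan2(YA[2], YA[1])
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  yA <- as.vector(R %*% YA)
  yD <- as.vector(R %*% YD)
  yA[2] <- 0 # exact by construction
  if (yD[2] < 0) yD[2] <- -yD[2] # reflect D into the upper half-plane
  theta <- atan2(yD[2], yD[1])
  structure(
    list(triangle = triangle, convention = convention,
         eigenvalues = dec$values, P = dec$P,
         Y_A = YA, Y_D = YD, y_A = yA, y_D = yD,
         theta = theta, c = theta / (2 * pi)),
    class = "cl_geometry"
  )
}

#' @export
print.cl_geometry <- function(x, ...) {
  cat("Self-Liang cone geometry (", x$triangle$assumption, ", ",
      x$convention, " convention)\n", sep = "")
  cat(sprintf("  Y_A = (%.3f, %.3f)   Y_D = (%.3f, %.3f)\n",
              x$Y_A[1], x$Y_A[2], x$Y_D[1], x$Y_D[2]))
  cat(sprintf("  y_A = (%.3f, %.3f)   y_D = (%.3f, %.3f)\n",
              x$y_A[1], x$y_A[2], x$y_D[1], x$y_D[2]))
  cat(sprintf("  theta = %.4f rad   c = %.4f\n", x$theta, x$c))
  invisible(x)
}

#' @rdname cl_geometry
#' @param x A `cl_geometry` object.
#' @param ... Unused.
#' @method tidy cl_geometry
#' @export
tidy.cl_geometry <- function(x, ...) {
  tibble::tibble(
    vertex = c("N", "A", "D"),
    beta1 = c(x$triangle$N[1], x$triangle$A[1], x$triangle$D[1]),
    beta2 = c(x$triangle$N[2], x$triangle$A[2], x$triangle$D[2]),
    Y1 = c(0, x$Y_A[1], x$Y_D[1]),
    Y2 = c(0, x$Y_A[2], x$Y_D[2]),
    y1 = c(0, x$y_A[1], x$y_D[1]),
    y2 = c(0, x$y_A[2], x$y_D[2])
  )
}

#' Mixing proportion of the constrained two-parameter null mixture
#'
#' The weight `c` on the 2-df chi-square component of the
#' `(1/2 - c) chi2_0 + 1/2 chi2_1 + c chi2_2` null mixture, computed as
#' `theta / (2 pi)` from the Self-Liang geometry (see [cl_geometry()]).
#'
#' @inheritParams cl_geometry
#' @return The mixing proportion, in (0, 1/2).
#' @examples
#' round(mixing_proportion(cl_triangle("A1")), 3) # 0.050
#' round(mixing_proportion(cl_triangle("A2")), 3) # 0.044
#' round(mixing_proportion(cl_triangle("A3")), 3) # 0.054
#' @export
mixing_proportion <- function(triangle = cl_triangle("A1"),
                              covariance = asp_information_null()$covariance,
                              convention = c("paper", "whiten")) {
  cl_geometry(triangle, covariance, convention)$c
}

#' Mixing proportion as a function of the upper value of beta1
#'
#' Evaluates `c` for exact-boundary triangles truncated at each value of
#' `beta1_grid`. The curve is non-decreasing and approaches the limit
#' given by the boundary's asymptote direction (1, 1) (about 0.070 under
#' the `"paper"` convention); see [mixing_proportion_limit()].
#'
#' @param beta1_grid Increasing positive values for the upper bound.
#' @inheritParams cl_geometry
#' @return A tibble with columns `beta1_max` and `c`.
#' @export
mixing_proportion_curve <- function(beta1_grid,
                                    covariance = asp_information_null()$covariance,
                                    convention = c("paper", "whiten")) {
  if (any(beta1_grid <= 0) || is.unsorted(beta1_grid, strictly = FALSE)) {
    abort("`beta1_grid` must be positive and increasing.")
  }
  convention <- match.arg(convention)
  tibble::tibble(
    beta1_max = as.numeric(beta1_grid),
    c = purrr::map_dbl(beta1_grid, function(b) {
      mixing_proportion(cl_triangle("custom", beta1_max = b),
                        covariance, convention)
    })
  )
}

#' @rdname mixing_proportion_curve
#' @details `mixing_proportion_limit()` evaluates the large-`beta1`
#'   limit directly from the asymptote: as `beta1` grows the boundary
#'   `beta2 = log(2 exp(beta1) - 1)` approaches `beta2 = beta1 + log 2`,
#'   so the cone rays tend to directions (1, 1) and (0, 1).
#' @export
mixing_proportion_limit <- function(covariance = asp_information_null()$covariance,
                                    convention = c("paper", "whiten")) {
  mixing_proportion(cl_triangle(A = c(1, 1), D = c(0, 1)),
                    covariance, convention)
}

#' Mixing proportion of the allele-sharing (RH) model
#'
#' For the two-parameter model in allele-sharing probabilities
#' `(z1, z2)` with null `(1/2, 1/4)`, the possible-triangle cone has
#' boundary ray directions (0, 1) and (-2, 3), and the per-pair
#' information at the null is `[[6, 4], [4, 8]]`. Sphering
#' (`"whiten"`) the cone by the parameter covariance gives the classical
#' mixing proportion `c ~ 0.098` of `Holmans' possible-triangle test`.
#'
#' @return The RH mixing proportion (about 0.098).
#' @export
rh_mixing_proportion <- function() {
  info_z <- matrix(c(6, 4, 4, 8), 2, 2)
  mixing_proportion(cl_triangle(A = c(0, 1), D = c(-2, 3)),
                    covariance = solve(info_z), convention = "whiten")
}
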