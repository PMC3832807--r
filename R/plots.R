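#' QQ plot of an empirical null study
#'
#' Plots -log10(empirical p) against -log10(asymptotic p) for every
#' replicate, with the identity line and a pointwise confidence band for
#' the order statistics (beta quantiles of the uniform ranks).
#'
#' @param object A `cl_null` object (see [run_null_replicates()]).
#' @param mix The asymptotic null [chisq_mixture()] to compare with.
#' @param band Pointwise band level (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cl_null
#' @export
autoplot.cl_null <- function(object, mix, band = 0.95, ...) {
  qq <- qq_table(object, mix)
  n <- nrow(qq)
  i <- seq_len(n)
  a <- (1 - band) / 2
  band_tb <- tibble::tibble(
    expected = -log10(i / (n + 1)),
    lo = -log10(qbeta(1 - a, i, n + 1 - i)),
    hi = -log10(qbeta(a, i, n + 1 - i))
  )
  ggplot2::ggplot(qq, ggplot2::aes(x = .data$neglog10_asymptotic,
                                   y = .data$neglog10_empirical)) +
    ggplot2::geom_ribbon(
      data = band_tb,
      ggplot2::aes(x = .data$expected, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "red") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = expression(-log[10] * "(asymptotic p-value)"),
      y = expression(-log[10] * "(empirical p-value)"),
      title = sprintf("Null CL-LR, %s: %d replicates x %d ASPs",
                      object$model, object$n_replicates,
                      object$n_families)) +
    ggplot2::theme_minimal()
}

#' Plot the constraint triangle before and after transformation
#'
#' Shows the original triangle in the `(beta1, beta2)` plane, the
#' orthogonally transformed triangle, and the rotated triangle whose
#' apex angle is the mixing proportion times `2 pi`.
#'
#' @param object A `cl_geometry` object (see [cl_geometry()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cl_geometry
#' @export
autoplot.cl_geometry <- function(object, ...) {
  tri <- function(a, d, stage) {
    tibble::tibble(stage = stage,
                   x = c(0, a[1], d[1], 0),
                   y = c(0, a[2], d[2], 0))
  }
  df <- dplyr::bind_rows(
    tri(object$triangle$A, object$triangle$D, "original"),
    tri(object$Y_A, object$Y_D, "transformed"),
    tri(object$y_A, object$y_D, "rotated")
  )
  df$stage <- factor(df$stage, c("original", "transformed", "rotated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$stage)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(beta[1]), y = expression(beta[2]),
      title = sprintf("Constraint cone (%s): theta = %.3f, c = %.3f",
                      object$triangle$assumption, object$theta, object$c)) +
    ggplot2::theme_minimal()
}

#' Plot a mixing-proportion curve
#'
#' @param curve Output of [mixing_proportion_curve()].
#' @return A ggplot object showing `c` against the upper value of
#'   `beta1`, with the asymptote [mixing_proportion_limit()] as a dashed
#'   line.
#' @export
plot_mixing_curve <- function(curve) {
  stopifnot(all(c("beta1_max", "c") %in% names(curve)))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$beta1_max, y = .data$c)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = mixing_proportion_limit(),
                        linetype = 2) +
    ggplot2::labs(x = expression("upper value of " * beta[1]),
                  y = "mixing proportion c") +
    ggplot2::theme_minimal()
}
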