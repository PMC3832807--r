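# Independent oracles used across the suite. These never call the code
# paths they check.

# Brute-force sib-pair IBD posterior with untyped parents: sum over all
# ordered parental genotype pairs (HWE weights) and the 16 equiprobable
# ordered transmission patterns.
brute_force_untyped_posterior <- function(s1, s2, p) {
  s1 <- sort(s1); s2 <- sort(s2)
  k <- length(p)
  acc <- c(0, 0, 0)
  for (f1 in 1:k) for (f2 in 1:k) for (m1 in 1:k) for (m2 in 1:k) {
    wpar <- p[f1] * p[f2] * p[m1] * p[m2]
    fg <- c(f1, f2); mg <- c(m1, m2)
    for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (d in 1:2) {
      g1 <- sort(c(fg[a], mg[b])); g2 <- sort(c(fg[cc], mg[d]))
      if (all(g1 == s1) && all(g2 == s2)) {
        ibd <- (a == cc) + (b == d)
        acc[ibd + 1] <- acc[ibd + 1] + wpar / 16
      }
    }
  }
  acc / sum(acc)
}

# Count-data LOD at given relative risks (closed form used as oracle).
count_lod_at <- function(n, l1, l2, prior = c(0.25, 0.5, 0.25)) {
  den <- prior[1] + l1 * prior[2] + l2 * prior[3]
  lam <- c(1, l1, l2)
  sum(ifelse(n > 0, n * log10(lam / den), 0))
}

# Dense two-stage grid search for the constrained two-parameter maximum
# on count data, parameterised as beta1 = a, beta2 = boundary(a) + b.
grid_lod_constrained_2p <- function(n, a_max = 2, b_max = 3) {
  eval_grid <- function(a_seq, b_seq) {
    g <- expand.grid(a = a_seq, b = b_seq)
    l1 <- exp(g$a)
    l2 <- (2 * l1 - 1) * exp(g$b)
    den <- 0.25 + 0.5 * l1 + 0.25 * l2
    v <- (if (n[1] > 0) n[1] * log10(1 / den) else 0) +
      (if (n[2] > 0) n[2] * log10(l1 / den) else 0) +
      (if (n[3] > 0) n[3] * log10(l2 / den) else 0)
    g$v <- v
    g[which.max(v), ]
  }
  best <- eval_grid(seq(0, a_max, by = 5e-3), seq(0, b_max, by = 5e-3))
  for (h in c(1e-2, 5e-4)) {
    best <- eval_grid(
      seq(max(0, best$a - h * 10), best$a + h * 10, by = h / 10),
      seq(max(0, best$b - h * 10), best$b + h * 10, by = h / 10))
  }
  max(best$v, 0)
}

# 1-D dense grid for the minmax one-parameter models on count data.
grid_lod_1p <- function(n, lo, hi = 3, step = 1e-5) {
  b1 <- seq(lo, hi, by = step)
  l1 <- exp(b1)
  l2 <- 3.634 * l1 - 2.634
  ok <- l2 > 0
  b1 <- b1[ok]; l1 <- l1[ok]; l2 <- l2[ok]
  den <- 0.25 + 0.5 * l1 + 0.25 * l2
  v <- (if (n[1] > 0) n[1] * log10(1 / den) else 0) +
    (if (n[2] > 0) n[2] * log10(l1 / den) else 0) +
    (if (n[3] > 0) n[3] * log10(l2 / den) else 0)
  max(v, 0)
}

# Dense two-stage grid for the one-parameter covariate models (K = 1).
# Feasibility: beta1 >= 0; constrained adds beta1 + xmax * delta >= 0.
grid_lod_covariate <- function(G, x, constrained,
                               b_max = 2, d_rng = c(-2, 2)) {
  xmax <- if (any(x > 0)) max(x[x > 0]) else Inf
  eval_grid <- function(b_seq, d_seq) {
    g <- expand.grid(b = b_seq, d = d_seq)
    g <- g[g$b >= 0, , drop = FALSE]
    if (constrained && is.finite(xmax)) {
      g <- g[g$b + xmax * g$d >= 0, , drop = FALSE]
    }
    g$v <- vapply(seq_len(nrow(g)), function(i) {
      eta <- g$b[i] + x * g$d[i]
      l1 <- exp(eta)
      l2 <- 3.634 * l1 - 2.634
      if (any(l2 <= 0)) return(-Inf)
      num <- G[, 1] + l1 * G[, 2] + l2 * G[, 3]
      den <- 0.25 + 0.5 * l1 + 0.25 * l2
      sum(log10(num / den))
    }, numeric(1))
    g[which.max(g$v), ]
  }
  best <- eval_grid(seq(0, b_max, by = 0.01),
                    seq(d_rng[1], d_rng[2], by = 0.01))
  # the surface is a narrow diagonal ridge: refine in shrinking windows
  for (h in c(0.05, 0.005, 5e-4)) {
    best <- eval_grid(seq(max(0, best$b - h), best$b + h, by = h / 25),
                      seq(best$d - h, best$d + h, by = h / 25))
  }
  max(best$v, 0)
}

# Exact boundary mass P(maximised LOD = 0) of the constrained minmax
# one-parameter model on n fully-informative ASPs: the maximum sits at
# beta1 = 0 iff the score there is <= 0, i.e. n1 + 3.634 n2 <= 1.4085 n.
exact_zero_mass_c1p <- function(n) {
  n0 <- 0:n
  total <- 0
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  for (a in n0) {
    b <- 0:(n - a)
    cc <- n - a - b
    keep <- b + 3.634 * cc <= n * (0.5 + 0.25 * 3.634)
    if (any(keep)) {
      lp <- lchoose2(n, a) + lchoose2(n - a, b[keep]) +
        a * log(0.25) + b[keep] * log(0.5) + cc[keep] * log(0.25)
      total <- total + sum(exp(lp))
    }
  }
  total
}

# Inverse-transform sampler from a chi-square mixture (on the LOD scale).
sample_mixture_lods <- function(n, weights, dfs) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  x <- ifelse(dfs[comp] == 0, 0, stats::rchisq(n, pmax(dfs[comp], 1e-9)))
  x[dfs[comp] == 0] <- 0
  x / (2 * log(10))
}

# Simplex sampler for random soft posteriors.
random_posteriors <- function(n) {
  m <- matrix(stats::rexp(3 * n), n, 3)
  m / rowSums(m)
}
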