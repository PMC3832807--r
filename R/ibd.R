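#' Allele frequency specifications
#'
#' A marker is described by its allele frequencies: a numeric vector of
#' strictly positive values summing to one, with at least two alleles.
#' `equal_allele_freqs(k)` is the common shorthand for a marker with `k`
#' equally frequent alleles.
#'
#' @param freqs Numeric vector of per-allele frequencies.
#' @param k Number of equally frequent alleles (at least 2).
#' @return A validated numeric vector of allele frequencies.
#' @examples
#' allele_freqs(c(0.7, 0.3))
#' equal_allele_freqs(4)
#' @export
allele_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) < 2) {
    abort("`freqs` must be a numeric vector with at least 2 alleles.")
  }
  if (any(freqs <= 0)) {
    abort("All allele frequencies must be strictly positive.")
  }
  if (abs(sum(freqs) - 1) > 1e-12) {
    abort("Allele frequencies must sum to 1 (within 1e-12).")
  }
  as.numeric(freqs)
}

#' @rdname allele_freqs
#' @export
equal_allele_freqs <- function(k) {
  if (k < 2) abort("An informative marker needs at least 2 alleles.")
  allele_freqs(rep(1 / k, k))
}

#' Prior IBD distribution of an affected sib pair
#'
#' Under Mendelian segregation a full-sib pair shares 0, 1, or 2 alleles
#' identical by descent (IBD) with prior probabilities (1/4, 1/2, 1/4),
#' corresponding to the null allele-sharing probabilities
#' (z1, z2) = (1/2, 1/4).
#'
#' @return A named numeric vector `c(f0 = 0.25, f1 = 0.5, f2 = 0.25)`.
#' @export
ibd_prior_asp <- function() {
  c(f0 = 0.25, f1 = 0.5, f2 = 0.25)
}

#' Polymorphism information content (PIC) of a marker
#'
#' @param freqs Allele frequencies (see [allele_freqs()]).
#' @return PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2, in \[0, 1).
#' @examples
#' pic(equal_allele_freqs(8)) # 0.861
#' @export
pic <- function(freqs) {
  p <- allele_freqs(freqs)
  p2 <- p^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2 # sum_{i<j} p_i^2 p_j^2
  1 - sum(p2) - 2 * cross
}

# ---- internal: exact posterior machinery ------------------------------------

# Hardy-Weinberg probability of an unordered genotype c(a, b), a <= b.
hwe_prob <- function(g, p) {
  if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
}

# Counts over IBD = 0,1,2 of the 16 equiprobable ordered transmission
# patterns from ordered parental genotypes that reproduce both (unordered)
# sib genotypes.
transmission_counts <- function(fg, mg, s1, s2) {
  counts <- c(0, 0, 0)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) for (d in 1:2) {
    g1 <- sort(c(fg[a], mg[b]))
    g2 <- sort(c(fg[cc], mg[d]))
    if (g1[1] == s1[1] && g1[2] == s1[2] && g2[1] == s2[1] && g2[2] == s2[2]) {
      ibd <- (a == cc) + (b == d)
      counts[ibd + 1] <- counts[ibd + 1] + 1
    }
  }
  counts
}

# P(G1 = g1, G2 = g2 | IBD = 1) for unordered genotypes under HWE:
# a shared allele s and independent non-shared alleles.
share_one_prob <- function(g1, g2, p) {
  i <- g1[1]; j <- g1[2]; k <- g2[1]; l <- g2[2]
  if (i == j) {
    if (k == l) {
      if (k == i) p[i]^3 else 0
    } else if (i == k) {
      p[i]^2 * p[l]
    } else if (i == l) {
      p[i]^2 * p[k]
    } else 0
  } else if (k == l) {
    # g1 = {i,j} het, g2 = {k,k} homo: shared allele must be k
    if (k == i) p[k]^2 * p[j] else if (k == j) p[k]^2 * p[i] else 0
  } else {
    if (i == k && j == l) {
      p[i] * p[j] * (p[i] + p[j])
    } else {
      shared <- intersect(c(i, j), c(k, l))
      if (length(shared) == 1) {
        s <- shared
        a <- setdiff(c(i, j), s)
        b <- setdiff(c(k, l), s)
        p[s] * p[a] * p[b]
      } else 0
    }
  }
}

# Posterior for one genotype configuration. Parent genotypes are length-2
# integer vectors or NULL when untyped; sib genotypes are sorted length-2.
posterior_one <- function(fg, mg, s1, s2, p, prior) {
  if (!is.null(fg) && !is.null(mg)) {
    s <- transmission_counts(fg, mg, s1, s2)
    if (sum(s) == 0) {
      abort("Sib genotypes are Mendelian-inconsistent with the typed parents.",
            class = "clasp_mendel_error")
    }
    g <- s / sum(s) # patterns are equiprobable; prior already uniform 1/16
    return(g)
  }
  if (is.null(fg) && is.null(mg)) {
    s0 <- hwe_prob(s1, p) * hwe_prob(s2, p)
    s1p <- share_one_prob(s1, s2, p)
    s2p <- if (all(s1 == s2)) hwe_prob(s1, p) else 0
    w <- prior * c(s0, s1p, s2p)
    if (sum(w) == 0) abort("Zero-probability sib genotype configuration.")
    return(w / sum(w))
  }
  # one parent typed: marginalise the missing parent over ordered HWE
  # genotypes, accumulating transmission counts weighted by p_i * p_j
  typed <- if (is.null(fg)) mg else fg
  k <- length(p)
  acc <- c(0, 0, 0)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    other <- c(i, j)
    cnt <- if (is.null(fg)) {
      transmission_counts(other, mg, s1, s2)
    } else {
      transmission_counts(fg, other, s1, s2)
    }
    acc <- acc + p[i] * p[j] * cnt
  }
  if (sum(acc) == 0) {
    abort("Sib genotypes are Mendelian-inconsistent with the typed parent.",
          class = "clasp_mendel_error")
  }
  acc / sum(acc)
}

fam_cols <- c("f_a1", "f_a2", "m_a1", "m_a2",
              "s1_a1", "s1_a2", "s2_a1", "s2_a2")

check_families <- function(families) {
  missing_cols <- setdiff(fam_cols, names(families))
  if (length(missing_cols) > 0) {
    abort(paste0("`families` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sib <- families[c("s1_a1", "s1_a2", "s2_a1", "s2_a2")]
  if (anyNA(sib)) abort("Both sib genotypes must be fully typed.")
  invisible(families)
}

#' Conditional IBD distribution of sib pairs given marker data
#'
#' Computes, for every family, the exact posterior probabilities
#' (g0, g1, g2) that the sib pair shares 0, 1, or 2 alleles IBD at the
#' marker, conditional on the observed genotypes. With both parents typed
#' the 16 equiprobable ordered transmission patterns are enumerated and
#' those reproducing the sib genotypes tallied by IBD count. With parents
#' untyped the parental genotypes are marginalised under Hardy-Weinberg
#' equilibrium (via the closed-form sib-pair genotype probabilities given
#' each IBD state); with exactly one parent typed only the missing parent
#' is marginalised.
#'
#' @param families A data frame with one row per family and integer allele
#'   columns `f_a1, f_a2, m_a1, m_a2, s1_a1, s1_a2, s2_a1, s2_a2`
#'   (father, mother, sib 1, sib 2). `NA` marks an untyped parent (both
#'   alleles of that parent must be `NA`); sibs must be typed.
#' @param freqs Allele frequencies (see [allele_freqs()]); allele indices
#'   in `families` must be valid for `freqs`.
#' @param prior Prior IBD distribution of the pair, default the full-sib
#'   prior (1/4, 1/2, 1/4).
#' @return The input as a tibble with posterior columns `g0`, `g1`, `g2`
#'   appended (rows sum to 1).
#' @examples
#' fam <- tibble::tibble(f_a1 = 1, f_a2 = 2, m_a1 = 1, m_a2 = 2,
#'                       s1_a1 = 1, s1_a2 = 2, s2_a1 = 1, s2_a2 = 2)
#' ibd_posterior(fam, equal_allele_freqs(2)) # g = (0.5, 0, 0.5)
#' @export
ibd_posterior <- function(families, freqs, prior = ibd_prior_asp()) {
  check_families(families)
  p <- allele_freqs(freqs)
  prior <- check_prior(prior)
  alleles <- unlist(families[fam_cols], use.names = FALSE)
  alleles <- alleles[!is.na(alleles)]
  if (any(alleles < 1 | alleles > length(p) | alleles != floor(alleles))) {
    abort("Allele indices must be integers in 1..length(freqs).")
  }
  fa_na <- is.na(families$f_a1) != is.na(families$f_a2)
  mo_na <- is.na(families$m_a1) != is.na(families$m_a2)
  if (any(fa_na) || any(mo_na)) {
    abort("A parent must have both alleles typed or both missing.")
  }

  cfg <- dplyr::distinct(dplyr::as_tibble(families[fam_cols]))
  post <- purrr::pmap(cfg, function(f_a1, f_a2, m_a1, m_a2,
                                    s1_a1, s1_a2, s2_a1, s2_a2) {
    fg <- if (is.na(f_a1)) NULL else c(f_a1, f_a2)
    mg <- if (is.na(m_a1)) NULL else c(m_a1, m_a2)
    posterior_one(fg, mg, sort(c(s1_a1, s1_a2)), sort(c(s2_a1, s2_a2)),
                  p, prior)
  })
  cfg$g0 <- purrr::map_dbl(post, 1)
  cfg$g1 <- purrr::map_dbl(post, 2)
  cfg$g2 <- purrr::map_dbl(post, 3)
  out <- dplyr::left_join(dplyr::as_tibble(families), cfg, by = fam_cols)
  out
}

check_prior <- function(prior) {
  if (length(prior) != 3 || any(prior < 0) || abs(sum(prior) - 1) > 1e-12) {
    abort("`prior` must be 3 nonnegative probabilities summing to 1.")
  }
  as.numeric(prior)
}

#' IBD count of sib pairs at a fully informative marker
#'
#' When the four parental alleles are pairwise distinct (a fully
#' informative marker), the IBD count of the pair is observed exactly: it
#' is the number of alleles the two sibs share, and the conditional IBD
#' posterior is the indicator of that count.
#'
#' @inheritParams ibd_posterior
#' @return Integer vector of IBD counts in `{0, 1, 2}`, one per family.
#' @export
ibd_count_fully_informative <- function(families) {
  check_families(families)
  par <- families[c("f_a1", "f_a2", "m_a1", "m_a2")]
  if (anyNA(par)) abort("Parents must be typed at a fully informative marker.")
  distinct4 <- apply(as.matrix(par), 1L, function(a) length(unique(a)) == 4)
  if (!all(distinct4)) {
    abort("The four parental alleles must be pairwise distinct.")
  }
  m <- as.matrix(families[c("s1_a1", "s1_a2", "s2_a1", "s2_a2")])
  as.integer((m[, 1] == m[, 3] | m[, 1] == m[, 4]) +
             (m[, 2] == m[, 3] | m[, 2] == m[, 4]))
}
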