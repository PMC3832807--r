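#' Read LINKAGE-style pedigree files
#'
#' Parses whitespace-delimited pre-makeped records with columns
#' family-id, individual-id, father-id, mother-id, sex, affection
#' (2 = affected), allele1, allele2 (0 = missing parent or allele), and
#' assembles nuclear families with two parents and two typed affected
#' sibs. Families with more than two affected typed sibs keep the first
#' two (with a warning); families failing the structure checks (not
#' exactly two parents, fewer than two typed affected sibs, or
#' inconsistent parent references) are skipped with a warning.
#'
#' @param path Path to the pedigree file.
#' @return A families tibble (see [ibd_posterior()]) with a `family`
#'   column carrying the pedigree family id.
#' @examples
#' ped <- system.file("extdata", "example_synthetic.ped", package = "clasp")
#' read_pedigrees(ped)
#' @export
read_pedigrees <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("Empty pedigree file.")
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 8 || anyNA(suppressWarnings(as.numeric(f)))) {
      abort(sprintf("Malformed pedigree record at line %d: '%s'",
                    i, lines[i]))
    }
    as.numeric(f)
  })
  ped <- do.call(rbind, recs)
  colnames(ped) <- c("fam", "id", "fa", "mo", "sex", "aff", "a1", "a2")
  ped <- tibble::as_tibble(ped)

  build_one <- function(df) {
    fam_id <- df$fam[1]
    kids <- df[df$fa != 0 & df$mo != 0, ]
    if (nrow(kids) == 0) {
      warn(sprintf("Family %g skipped: no offspring records.", fam_id))
      return(NULL)
    }
    par_ids <- unique(c(kids$fa, kids$mo))
    if (length(unique(kids$fa)) != 1 || length(unique(kids$mo)) != 1 ||
        length(par_ids) != 2 || !all(par_ids %in% df$id)) {
      warn(sprintf("Family %g skipped: does not have exactly two parents.",
                   fam_id))
      return(NULL)
    }
    father <- df[df$id == kids$fa[1], ][1, ]
    mother <- df[df$id == kids$mo[1], ][1, ]
    sibs <- kids[kids$aff == 2 & kids$a1 > 0 & kids$a2 > 0, ]
    if (nrow(sibs) < 2) {
      warn(sprintf(
        "Family %g skipped: fewer than two typed affected sibs.", fam_id))
      return(NULL)
    }
    if (nrow(sibs) > 2) {
      warn(sprintf(
        "Family %g has %d typed affected sibs; keeping the first two.",
        fam_id, nrow(sibs)))
      sibs <- sibs[1:2, ]
    }
    geno <- function(r) {
      if (r$a1 == 0 || r$a2 == 0) c(NA_integer_, NA_integer_)
      else as.integer(c(r$a1, r$a2))
    }
    fg <- geno(father); mg <- geno(mother)
    tibble::tibble(family = fam_id,
                   f_a1 = fg[1], f_a2 = fg[2], m_a1 = mg[1], m_a2 = mg[2],
                   s1_a1 = as.integer(sibs$a1[1]),
                   s1_a2 = as.integer(sibs$a2[1]),
                   s2_a1 = as.integer(sibs$a1[2]),
                   s2_a2 = as.integer(sibs$a2[2]))
  }
  fams <- dplyr::bind_rows(lapply(split(ped, ped$fam), build_one))
  if (nrow(fams) == 0) abort("No valid families in pedigree file.")
  fams
}

#' Write families in the LINKAGE pre-makeped layout
#'
#' Inverse of [read_pedigrees()] for simulated families: each family is
#' written as father (id 1), mother (id 2) and the two affected sibs
#' (ids 3, 4). Missing genotypes become `0 0`.
#'
#' @param families A families tibble (see [ibd_posterior()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigrees <- function(families, path) {
  check_families(families)
  fam_id <- if ("family" %in% names(families)) families$family
            else seq_len(nrow(families))
  z <- function(a) ifelse(is.na(a), 0, a)
  rows <- purrr::map(seq_len(nrow(families)), function(i) {
    f <- families[i, ]
    rbind(
      c(fam_id[i], 1, 0, 0, 1, 0, z(f$f_a1), z(f$f_a2)),
      c(fam_id[i], 2, 0, 0, 2, 0, z(f$m_a1), z(f$m_a2)),
      c(fam_id[i], 3, 1, 2, 1, 2, f$s1_a1, f$s1_a2),
      c(fam_id[i], 4, 1, 2, 1, 2, f$s2_a1, f$s2_a2)
    )
  })
  m <- do.call(rbind, rows)
  writeLines(apply(m, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' Analyse ASP families under a chosen model
#'
#' End-to-end analysis: IBD posteriors from the marker data, maximised
#' LOD under `model`, and the asymptotic p-value from the model's
#' mixture null (with the mixing proportion from the chosen triangle
#' geometry for the constrained two-parameter model). For covariate
#' models, individual covariate columns `x1`, `x2` of `families` are
#' summed to the pair level and adjusted (mean-centered for
#' `unconstrained_covariate`, minimum-adjusted for
#' `constrained_covariate`).
#'
#' @inheritParams ibd_posterior
#' @param model One of [cl_models].
#' @param assumption Triangle assumption for the constrained
#'   two-parameter mixing proportion (see [cl_triangle()]).
#' @param convention Transform convention (see [cl_geometry()]).
#' @return A one-row tibble: parameter estimates, `lod`, `lr`,
#'   `p_value`, the mixing proportion used (`c_used`, `NA` when not
#'   applicable), `assumption`, `converged`, `n_pairs`.
#' @export
analyze <- function(families, model = "constrained_2p", freqs = NULL,
                    assumption = "A1", convention = "paper",
                    prior = ibd_prior_asp()) {
  model <- check_model(model)
  if (nrow(families) == 0) abort("`families` is empty.")
  fully_typed <- !anyNA(families[c("f_a1", "f_a2", "m_a1", "m_a2")])
  all4 <- fully_typed &&
    all(apply(as.matrix(families[c("f_a1", "f_a2", "m_a1", "m_a2")]), 1L,
              function(a) length(unique(a)) == 4))
  if (all4) {
    ibd <- ibd_count_fully_informative(families)
    pairs <- tibble::tibble(g0 = as.numeric(ibd == 0),
                            g1 = as.numeric(ibd == 1),
                            g2 = as.numeric(ibd == 2))
  } else {
    if (is.null(freqs)) {
      abort("`freqs` is required unless the marker is fully informative.")
    }
    pairs <- ibd_posterior(families, freqs, prior)[c("g0", "g1", "g2")]
  }
  if (is_covariate_model(model)) {
    if (!all(c("x1", "x2") %in% names(families))) {
      abort("Covariate models need individual covariate columns x1, x2.")
    }
    adj <- if (model == "unconstrained_covariate") "mean_center"
           else "minimum_adjust"
    pairs$x1 <- adjust_covariate(families$x1 + families$x2, adj)
  }
  fit <- cl_fit(pairs, model = model, prior = prior)
  c_used <- NA_real_
  mix <- if (model == "constrained_2p") {
    c_used <- mixing_proportion(cl_triangle(assumption),
                                convention = convention)
    mixture_for_model(model, c = c_used)
  } else if (model == "constrained_covariate") {
    suppressWarnings(mixture_for_model(model))
  } else {
    mixture_for_model(model)
  }
  tibble::tibble(
    model = model, beta1 = fit$beta1, beta2 = fit$beta2,
    delta1 = if (length(fit$deltas) > 0) fit$deltas[1] else NA_real_,
    lod = fit$lod, lr = fit$lr,
    p_value = asymptotic_pvalue(fit$lod, mix),
    c_used = c_used,
    assumption = if (model == "constrained_2p") assumption else NA_character_,
    converged = fit$converged, n_pairs = fit$n_pairs
  )
}
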