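---
title: "Null distributions of the conditional-logistic ASP linkage statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null distributions of the conditional-logistic ASP linkage statistic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clasp)
```

## The model

Affected-sib-pair (ASP) linkage analysis asks whether two affected sibs
share more alleles identical by descent (IBD) at a marker than the
Mendelian prior $(f_0, f_1, f_2) = (\tfrac14, \tfrac12, \tfrac14)$
predicts. The conditional-logistic (CL) model parameterises excess
sharing through allele-sharing relative risks
$\lambda_i = e^{\beta_i}$ ($i = 0, 1, 2$; $\lambda_0 \equiv 1$): the
likelihood-ratio contribution of a pair with marker-conditional IBD
distribution $\hat f = (\hat f_0, \hat f_1, \hat f_2)$ is

$$
\mathrm{LR} \;=\;
\frac{\sum_i \lambda_i \hat f_i}{\sum_i \lambda_i f_i},
$$

and the sample LOD score sums $\log_{10} \mathrm{LR}$ over independent
pairs. The test statistic is $\mathrm{CL\text{-}LR} = 2\ln(10)\,
\mathrm{LOD}$, maximised over one of six feasible parameter sets
(`cl_models`): the free plane; the possible-triangle genetic
constraints $\beta_1 \ge 0$, $\beta_2 \ge \log(2e^{\beta_1} - 1)$
(single-locus inheritance); the one-parameter minmax tie
$\lambda_2 = 3.634\lambda_1 - 2.634$, free or with $\beta_1 \ge 0$; and
the constrained one-parameter model with pair-level covariates entering
log-linearly, $\lambda_1 = \exp(\beta_1 + \sum_j \delta_j x_j)$.

Because the null $(\beta_1, \beta_2) = (0, 0)$ sits on the boundary of
the constrained sets, the CL-LR statistic is not chi-square but a
chi-bar-square mixture. For the constrained two-parameter model it is

$$
\left(\tfrac12 - c\right)\chi^2_0 + \tfrac12 \chi^2_1 + c\,\chi^2_2,
$$

where the mixing proportion $c$ is the probability that the
unconstrained estimate falls inside the constraint cone.

## The cone geometry for c

`cl_geometry()` implements the Self–Liang construction. The per-pair
information at the null is the covariance of the IBD indicator pair
$(1\{IBD=1\}, 1\{IBD=2\})$, giving the parameter covariance
$I^{-1} = \bigl[\begin{smallmatrix}6 & 4\\ 4 & 8\end{smallmatrix}\bigr]$
(`asp_information_null()`). A triangle $N, A, D$ spans the cone: $N$ is
the null, $A$ sits on the no-dominance boundary
$\beta_2 = \log(2e^{\beta_1} - 1)$, and $D$ on the $\beta_2$ axis at
the same height. Because that boundary is curved, $c$ depends on the
upper value assumed for $\beta_1$; the three canonical choices are
built by `cl_triangle()`:

```{r}
tibble::tibble(
  assumption = c("A1", "A2", "A3"),
  c = c(mixing_proportion(cl_triangle("A1")),
        mixing_proportion(cl_triangle("A2")),
        mixing_proportion(cl_triangle("A3"))))
```

A2 linearises the boundary at the null ($\beta_2 = 2\beta_1$) and gives
the minimum $c$; `mixing_proportion_curve()` traces $c$ as the upper
value grows, approaching `mixing_proportion_limit()` (about 0.070, from
the boundary's asymptote direction $(1, 1)$).

Two numerical conventions are deliberately exposed. The `"paper"`
convention maps vertices by $\Lambda^{1/2}P^T$ (with
$P\Lambda P^T = I^{-1}$), which reproduces the published CL triangle
vertices and $c$ values. The `"whiten"` convention uses the standard
sphering $\Lambda^{-1/2}P^T$; applied to the allele-sharing
parameterisation of the same problem (cone rays $(0,1)$ and $(-2,3)$
at the null $(z_1, z_2) = (\tfrac12, \tfrac14)$, information
$\bigl[\begin{smallmatrix}6 & 4\\ 4 & 8\end{smallmatrix}\bigr]$), it
reproduces the classical possible-triangle value $c \approx 0.098$
(`rh_mixing_proportion()`). The two maps genuinely disagree on the CL
cone; the package defaults to `"paper"` for reproduction of the CL
values and keeps `"whiten"` available, surfacing rather than silently
resolving the discrepancy. One related choice: eigendecompositions are
sign- and order-ambiguous, so the package fixes eigenvalues descending
and $P$ a proper rotation ($\det P = +1$) with a positive leading
entry — the only convention that reproduces the published intermediate
vertices; when the two eigenvalues coincide the canonical basis is
used.

## Critical values and p-values

`mixture_for_model()` returns the asymptotic null of each model:
$\chi^2_2$ (free two-parameter), the $c$-mixture above (constrained),
$\chi^2_1$ (free minmax), a 50:50 point mass/$\chi^2_1$ (constrained
minmax), and a 50:50 $\chi^2_K$/$\chi^2_{K+1}$ for $K$ mean-centered
covariates. Tail probabilities use `stats::pchisq`; `critical_lod()`
root-finds the LOD whose mixture tail equals $\alpha$ on
$\mathrm{LOD} \in [0, 20]$ to $10^{-12}$. A point-mass component
contributes nothing to the tail for $x > 0$ and its full weight at
$x = 0$, the standard chi-bar-square convention.

```{r}
critical_lod_table(alphas = c(0.05, 0.001))
```

For the constrained covariate model no general asymptotic null exists:
with a minimum-adjusted covariate, the constraint
$\min_{x > 0} \sum_j x_j \delta_j \ge -\beta_1$ couples the feasible
region to the observed covariate values (with pair values
$\{0, 1, 2\}$ the feasible set is about a third of the plane rather
than a half). `mixture_for_model("constrained_covariate")` therefore
returns the empirically supported 50:50 point-mass/$\chi^2_1$
approximation with a loud warning, and simulation is the recommended
route.

## Maximisation

`cl_fit()` maximises the LOD by smooth exact reparameterisations of
the constrained sets: $\beta_1 = u_1^2$,
$\beta_2 = \log(2e^{\beta_1} - 1) + u_2^2$ for the triangle
constraints, and $\beta_1 = a^2$, $\delta = b^2 - a^2/x_{\max}$ for
the single-covariate constrained model (the boundary is reachable at
$u = 0$ and the null is always feasible, so the maximised LOD is
$\ge 0$). A general-purpose interior-point optimiser is unsuitable
here because the null itself lies on the boundary. Optimisation is
multi-start — the null point, a moment-based start from the pooled
posterior ($\hat\lambda_1 = \bar z_1 / 2\bar z_0$,
$\hat\lambda_2 = \bar z_2/\bar z_0$), and fixed jittered starts — with
parameters kept in $[-10, 10]$ (LOD contributions saturate far before
these bounds) and a Nelder–Mead polish where a feasibility penalty
kinks the surface (covariate models, where
$\lambda_2 = 3.634\lambda_1 - 2.634$ must stay positive for every
pair). Identical (posterior, covariate) rows are collapsed to weighted
terms, so fully informative samples reduce to the three IBD counts —
`cl_fit_counts()` exposes this fast path directly, which is what makes
$10^4$-replicate studies quick. In the one-parameter covariate models
$\delta$ enters $\lambda_1$ and $\lambda_2$ follows by applying the
minmax tie to the covariate-adjusted $\lambda_1$; this convention is
fixed and documented here because the alternative (a tied
$\delta_2$ inside $e^{\beta_2 + \delta_2 x}$) is not identifiable from
the published description.

Degenerate inputs: a LOD in $(-10^{-8}, 0)$ from floating point is
clipped to 0; empty pair sets and posteriors that do not sum to 1 are
errors; optimiser non-convergence is flagged on the `cl_fit` object,
never silently dropped.

## The gene-dropping simulator

`sim_families()` emulates the study design the null results are built
on: nuclear families with two parents and two affected sibs, one
unlinked marker, founder genotypes either unique per founder (fully
informative) or drawn under Hardy–Weinberg from $k$ equally frequent
alleles ($k \in \{2, 4, 8, 20\}$, PIC 0.38–0.95), each sib receiving
one uniformly random allele from each parent. Because pairs are
ascertained as affected and the marker is unlinked, no penetrance
model exists anywhere in the package — affection status is a constant
of the design, which is why the covariate `effect` offset (an
individual $N(0,1)$ shift, binary covariates dichotomised at the exact
population quantile for prevalence 0.2) defaults to 0: under the null
it can only shift location. Pair covariates are the sum of the two
sibs' values, mean-centered (continuous) or minimum-adjusted (binary)
per replicate over the sampled pairs, matching how they would enter a
real analysis.

What the simulator does **not** emulate: linkage (no power studies),
larger sibships or dependent pairs, genotyping error, or ascertainment
beyond "both sibs affected". Passing tests therefore show that the
statistic's null behaviour matches the stated mixtures under the
design above, not that the mixtures are accurate for arbitrary real
pedigrees.

`run_null_replicates()` derives one seed per replicate by a counter
scheme, so a study is a pure, order-independent function of its master
seed. Empirical p-values use the rank rule $p = (r+1)/(N+1)$ with $r$
counted from 0 at the largest LOD and ties broken by input order (the
rank origin is not fixed by the published description; this contract
is fixed here and documented).

## Problem sizes, tolerances, and finite-sample behaviour

The package's own validation studies use 10,000 replicates of 100
fully informative ASPs (the published studies used 100,000 replicates
of up to 500 families; the scaled-down design leaves Monte-Carlo error
well below the effects of interest for the boundary mass and tail
quantiles). Two finite-sample facts matter when interpreting them, and
are verified exactly by enumeration of count triples in the test
suite: at $n = 100$ pairs the multinomial LR of the free two-parameter
model has Kolmogorov distance 0.028 from $\chi^2_2$ (0.012 for the
minmax model from $\chi^2_1$), so bulk-sensitive tests against the
asymptotic law reject at this sample size even though tail critical
values agree closely — consistent with the published observation that
agreement holds on the critical-LOD scale while the covariate model
needs $n \ge 200$; and the exact boundary mass of the constrained
minmax model is 0.5100 at $n = 100$ and 0.5033 at $n = 500$,
converging to the asymptotic $\tfrac12$. Grid-search oracles in the
tests use two-stage refinement to resolve maximised LODs to about
$10^{-6}$, against which the optimiser is required to agree within
$10^{-4}$.

## Limitations

The mixing-proportion derivation assumes complete marker information;
under incomplete information the constrained two-parameter mixture is
an approximation (empirically a good one across PIC levels — the mean
null LOD is essentially flat in informativeness). Posterior
computation is sib-pair-specific (priors for other relative types can
be supplied, posteriors cannot); multipoint IBD over marker maps is
out of scope. Two-parameter models with covariates are deliberately
absent, matching the model family the null distributions are derived
for.
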