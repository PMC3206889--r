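---
title: "Genealogy-based mixed-model association mapping: models and methods"
author: "genmix package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogy-based mixed-model association mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In livestock and other deeply pedigreed populations, genome-wide
association scans face two coupled difficulties: individuals are related
at many levels, which inflates single-marker test statistics unless the
polygenic background is modelled; and a causative variant — especially a
rare one — is often tagged poorly by any single chip SNP but well by a
local haplotype. `genmix` implements a method that addresses both at once:
haplotypes are grouped by their position in locally inferred gene trees,
and those groups are tested as fixed effects inside a pedigree-based
linear mixed model (the GENMIX analysis). The standard single-SNP unified
mixed model (MMA) is provided as the comparator, and a gene-dropping
simulator plus power/ranking evaluation make the whole replicated study
design reproducible from one seed.

## Local gene trees and the seven haplotype factors

Any phenotype-affecting mutation must sit on an edge of the local
genealogy, so the clades of a local gene tree are a small, well-chosen
family of haplotype-grouping hypotheses. For a focal SNP:

1. **Segmentation.** The surrounding interval of sites is grown one site
   at a time, alternating right and left, accepting a site only while
   every pair of sites in the interval passes the four-gamete test (fewer
   than all four gametes 00, 01, 10, 11 observed). Once a side fails it
   stays closed — failing against a subset implies failing against any
   superset — so the result is maximal, deterministic, and roughly
   centred. The degenerate single-site interval is always valid.
2. **Perfect phylogeny.** Within a compatible interval every site's
   derived allele arose once, so derived-allele carriers form a clade. We
   take the derived allele to be the minor allele (ties: allele 1),
   collapse identical haplotype strings into single leaves, and build the
   rooted tree recursively from the laminar family of derived-carrier
   sets; the all-ancestral haplotype sits at the root side. Sites
   monomorphic within the interval's rows are ignored.
3. **Binarization.** Perfect phylogenies multifurcate; the cutting scheme
   below presumes binary nodes. Multifurcations are resolved by
   repeatedly joining the two children carrying the fewest haplotype
   copies (ties broken by the lexicographically smallest leaf haplotype
   string). This agglomerative rule is deterministic and keeps the major
   clades adjacent to the root, where the cuts below can reach them. We
   first used the simpler convention of ordering children by size and
   folding them into a ladder, but that resolves every multifurcation as
   "everything versus the smallest child": measured on a reference
   simulated dataset, the focal SNP's own carrier clade was then testable
   at only 64% of SNPs (84% under agglomeration, with mean testable
   factors per SNP rising from 2.9 to 3.9), which defeats the purpose of
   cutting the top of the tree.
4. **Cutting.** Cut 1 bisects at the root (two clusters). Cuts 2–3
   trisect at the two depth-1 nodes and cuts 4–7 at the four depth-2
   nodes; a trisection at node v yields {haplotypes outside v}, {under
   v's first child}, {under v's second child}. Nodes that do not exist or
   are leaves yield no factor, so a deep tree gives exactly seven factors
   and shallow trees fewer. Cutting deeper would produce small, unstable
   groups.

## The mixed model and the Wald tests

For one clustering, individual *i*'s two haplotypes give integer counts
of membership in each group. The model is

y_i = mu + b1 h1_i + b2 h2_i + a_i + e_i,

where h1, h2 are the counts of the two free groups (for a bisection b2 is
constrained to 0; for a trisection the *largest* group is the implied
baseline with count 2 − h1 − h2, a choice that maximizes the information
in the free coefficients), a ~ N(0, A sigma_a^2) is the additive
polygenic effect with A the pedigree numerator relationship matrix, and
e ~ N(0, sigma_e^2 I).

A is computed by the tabular method: founders have A_ii = 1 and unknown
parents contribute zero; for parents s, d, A_ii = 1 + A_sd/2 and
A_ij = (A_js + A_jd)/2. Inbreeding is F_i = A_ii − 1, exact under this
recursion. Unknown parents are treated as unique unrelated founders.

Variance components are estimated by REML for every test (matching a
per-analysis variance-component fit; a `p3d` option estimates the ratio
once under the null and reuses it, but is not the default). One spectral
decomposition A = U D U' is computed per dataset and shared across all
SNPs and factors; in rotated coordinates the restricted likelihood is
profiled over the ratio lambda = sigma_a^2/sigma_e^2 by golden-section
search on log(lambda) over [1e-6, 1e6] to relative tolerance 1e-8. With
identity kinship the profile is flat (only the variance sum is
identified); the fit flags this rather than reporting an arbitrary split.
GLS coefficient estimates and their covariance V_b come from the optimum;
the factor is tested by the Wald statistic b' V_b^{-1} b, asymptotically
chi-square with f = 1 (bisection, single SNP) or f = 2 (trisection)
degrees of freedom. No small-sample correction is applied — the test is
explicitly asymptotic. Groups with fewer than 4 haplotype copies
(configurable) are excluded from testing; a factor with fewer than two
informative groups is skipped and logged, and aliased count columns are
dropped with reduced degrees of freedom.

Per SNP, the smallest p-value among its performed tests measures QTL–SNP
association. Significance uses a Bonferroni correction at nominal 5% for
the *nominal* seven tests per SNP — with 1,694 SNPs that is 11,858 tests
and a per-test threshold of 0.05/11,858 ≈ 4.2e-6 — regardless of how many
tests a shallow tree actually allowed; the MMA comparator corrects for
1,694 tests (≈ 3.0e-5). Decisions always use the exact quotient; rounding
is display-only.

## The simulator

No public dataset carries the original genotypes, so the package
generates its own study conditions:

* **Pedigree.** Discrete generations with heavy sire reuse (default 25
  sires per generation over 1,500 offspring, 400 founders, 5
  generations), the mating design that gives dairy pedigrees their strong
  relatedness; the final generation is the genotyped subset (default
  1,400).
* **Founder haplotypes.** A pool of 30 haplotypes built by sequential
  copying from a random ancestor. Each new member is a recombinant of two
  random earlier members, with each copying step carrying ten
  generations' worth of Haldane crossovers; every SNP arises from a
  single mutation event assigned to one step, biased toward older steps
  so variants tend to be common, and allele labels are randomized per
  site. The pool is therefore homoplasy-free and locally tree-like —
  recombination is the only source of four-gamete incompatibility, as in
  real sequence ancestry — while long-range associations are shuffled
  away. Under the defaults this yields a chip-like site-frequency
  spectrum and r² decaying from ≈0.15 (< 200 kb) to ≈0.06 (> 8 Mb).
  Simpler pools were rejected on realism grounds: independent per-site
  flip mutations produce pervasive homoplasy (compatible intervals of ~2
  sites), and mutation-on-copy-tree without recombination produces exact
  duplicate marker patterns at arbitrary distances (long-range r² of 1),
  neither of which genome data shows.
* **Gene dropping.** Founders draw pool haplotypes with replacement; each
  meiosis recombines the parent's two haplotypes with Poisson crossovers
  at 1 cM/Mbp (Haldane). The default map is 1,695 sites at 72 kbp
  spacing (~122 Mbp); sites below 5% MAF in the genotyped sample are
  removed before analysis.
* **Phenotypes.** Founder polygenic values are N(0, 1); an offspring gets
  the parent average plus a Mendelian term with inbreeding-adjusted
  variance (1 − (F_s + F_d)/2)/2 (an unknown parent contributes founder
  variance), making Var(a) = A exactly with sigma_a^2 = 1. Residuals are
  N(0, sigma_e^2) with sigma_e^2 = (1 − h²)/h², so h² is the *polygenic*
  heritability excluding the QTL. The allele substitution effect is
  alpha = effect × sigma_p with sigma_p^2 = sigma_a^2 + sigma_e^2 — the
  "phenotypic SD" excludes the QTL's own contribution, avoiding the
  circularity of a definition in which alpha depends on a variance that
  depends on alpha. The QTL adds variance 2p(1 − p)alpha². Phenotype =
  alpha·x + a + e exactly, with all components stored.
* **Study driver.** One genetic base (pedigree, haplotypes, A) per master
  seed; phenotypes are redrawn per replicate from deterministically
  derived seeds, mirroring a design in which the real genotypes are fixed
  and phenotypes simulated. The SNP assigned as QTL is removed from the
  analyzed marker set. The full factorial grid is 3 heritabilities
  (0.21, 0.34, 0.64) × 7 QTL MAFs (0.05–0.45) × 5 effects (0.1–1.0 SD) ×
  25 replicates = 105 scenarios, 2,625 analyses.

## Evaluation

A QTL counts as detected when any test at a SNP within a 2.5 Mbp radius
(inclusive) is significant after Bonferroni correction. Ranking sorts
SNPs by ascending per-SNP minimum p, breaking exact ties by a seeded
uniform draw (ranks are always a permutation; NA p-values rank last), and
records the best rank within a 1 Mbp radius of the QTL — on a 72 kbp map
that radius holds 27 markers. Radii are interpreted as radii, not total
spans, and comparisons are inclusive.

## Problem sizes and numerical choices used by the test suite

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the effects being verified: the relationship-matrix oracle
sweeps random pedigrees up to 8 members (and 200 for spectral checks);
tree oracles sweep random compatible matrices up to 8 sites × 16
haplotypes; the REML optimizer is compared against 100 × 100 dense
restricted-likelihood grids at up to 30 individuals; Wald type-I error
uses 1,000 null fits at 200 genotyped individuals (binomial 99% bounds);
heritability recovery uses 200 replicates at 500 genotyped; polygenic
covariance is checked against A over 10,000 replicates of a 20-member
pedigree. The reference method comparison uses a 5-generation pedigree
with 500 genotyped individuals, 300 simulated sites at 72 kbp spacing,
QTL MAF 0.10 (matching tolerance 0.02 on the simulated map), effects 0.2
and 0.5 SD at h² = 0.34, and 25 replicates per effect.

## What the synthetic study does and does not show

On the reference comparison the implementation reproduces the method's
qualitative localization advantage: GENMIX's top-ranked marker falls
within 1 Mbp of the QTL in a substantially larger fraction of replicates
than MMA's. It does *not* reproduce a GENMIX power advantage: GENMIX's
best p-value near the QTL is frequently one to two orders of magnitude
smaller than MMA's, but under this generator's LD the sevenfold stricter
Bonferroni threshold costs more detections than the haplotype clustering
gains, and GENMIX's best-rank distribution has a heavier tail (when the
clustering misses, it misses badly). Whether the trade-off favours GENMIX
depends on the fine structure of LD between causal variants and
marker haplotypes — a property of the non-public genotypes the simulator
only emulates — so power comparisons on these synthetic data should be
read as properties of the generator as much as of the methods.

Other known limitations: the generator models no selection, assortative
mating, genotyping error, or chromosome-specific recombination maps; the
mixed model fits a single trait with one random polygenic effect (no
population-structure covariates — appropriate for a single closed
population); trees are cut only to depth 3, so variants private to deeper
clades are tested only through their enclosing clusters; and phasing is
assumed known (phased input is required, unphased VCF genotypes are
rejected).
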