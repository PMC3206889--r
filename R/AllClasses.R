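#' @import methods
#' @importFrom stats pchisq rbinom rnorm rpois runif sd var optimize setNames
#' @importFrom utils read.table write.table head tail
#' @useDynLib genmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Pedigree of individuals with sire/dam links
#'
#' Holds one record per individual in topological order: every parent
#' precedes its offspring.  Unknown parents are `NA`.  Built by
#' [readPedigree()] or [simulatePedigree()]; consumed by [computeA()].
#'
#' @slot id character vector of unique individual ids.
#' @slot sire character vector of sire ids (`NA` = unknown), parallel to `id`.
#' @slot dam character vector of dam ids (`NA` = unknown), parallel to `id`.
#'
#' @export
setClass("Pedigree", representation(
  id = "character",
  sire = "character",
  dam = "character"
))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  if (length(object@sire) != n || length(object@dam) != n)
    return("id, sire and dam must have equal length")
  if (anyDuplicated(object@id))
    return(sprintf("duplicate individual id: %s",
                   object@id[duplicated(object@id)][1L]))
  pos <- seq_len(n)
  names(pos) <- object@id
  for (p in list(object@sire, object@dam)) {
    known <- !is.na(p)
    ppos <- pos[p[known]]
    if (anyNA(ppos))
      return(sprintf("parent not in pedigree: %s",
                     p[known][is.na(ppos)][1L]))
    if (any(ppos >= pos[known]))
      return(sprintf("pedigree not topologically sorted at individual %s",
                     object@id[known][which(ppos >= pos[known])[1L]]))
  }
  TRUE
})

#' Phased biallelic haplotypes for one chromosome
#'
#' A binary matrix with one row per phased haplotype (two consecutive rows
#' per individual) and one column per SNP, plus the marker map.
#'
#' @slot alleles integer matrix in {0,1}; `2k - 1` and `2k` are the two
#'   haplotypes of individual `k`.
#' @slot positions numeric, strictly increasing bp positions per site.
#' @slot snpIds character SNP ids per site.
#' @slot individualIds character ids, one per individual (`nrow(alleles)/2`).
#'
#' @export
setClass("HaplotypeData", representation(
  alleles = "matrix",
  positions = "numeric",
  snpIds = "character",
  individualIds = "character"
))

setValidity("HaplotypeData", function(object) {
  a <- object@alleles
  if (!is.integer(a)) return("alleles must be an integer matrix")
  if (nrow(a) %% 2L != 0L) return("alleles must have an even number of rows")
  if (length(object@individualIds) != nrow(a) / 2L)
    return("need one individual id per pair of haplotype rows")
  if (length(object@positions) != ncol(a) ||
      length(object@snpIds) != ncol(a))
    return("positions and snpIds must match the number of sites")
  if (length(a) && !all(a == 0L | a == 1L))
    return("alleles must be 0/1")
  if (ncol(a) > 1L && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  TRUE
})

#' Rooted binary gene tree over distinct region haplotypes
#'
#' Produced by [buildPerfectPhylogeny()].  Nodes are numbered 1..nNodes with
#' node 1 the root; leaves carry the haplotype rows matching their haplotype
#' string over the region.
#'
#' @slot children integer matrix nNodes x 2; 0 marks a leaf.
#' @slot leafRows list, per node: for leaves the integer haplotype row
#'   indices collapsing onto that leaf, otherwise `integer(0)`.
#' @slot hapStrings character per node; haplotype string for leaves, `NA`
#'   for internal nodes.
#' @slot nRows total number of haplotype rows covered by the leaves.
#' @slot interval integer length-2, the (left, right) site indices spanned.
#'
#' @export
setClass("GeneTree", representation(
  children = "matrix",
  leafRows = "list",
  hapStrings = "character",
  nRows = "integer",
  interval = "integer"
))

setValidity("GeneTree", function(object) {
  ch <- object@children
  if (ncol(ch) != 2L) return("children must have two columns")
  leaf <- ch[, 1L] == 0L
  if (any(xor(ch[, 1L] == 0L, ch[, 2L] == 0L)))
    return("internal nodes must have exactly two children")
  rows <- sort(unlist(object@leafRows[leaf]))
  if (!identical(rows, seq_len(object@nRows)))
    return("leaf row sets must partition 1..nRows")
  hs <- object@hapStrings[leaf]
  if (anyDuplicated(hs)) return("leaf haplotype strings must be distinct")
  TRUE
})

#' Haplotype clustering from one tree cut
#'
#' One bi- or trisection of a [GeneTree-class]: cut 1 bisects at the root
#' (2 groups); cuts 2-7 trisect at the depth-1 and depth-2 internal nodes
#' (3 groups: outside the node, and its two child clades).
#'
#' @slot cutId integer in 1..7.
#' @slot nGroups integer, 2 (cut 1) or 3 (cuts 2-7).
#' @slot groupOfRow integer vector mapping every haplotype row to its group.
#' @slot groupCopies integer, haplotype copies per group.
#'
#' @export
setClass("FactorClustering", representation(
  cutId = "integer",
  nGroups = "integer",
  groupOfRow = "integer",
  groupCopies = "integer"
))

setValidity("FactorClustering", function(object) {
  if (!object@nGroups %in% c(2L, 3L)) return("nGroups must be 2 or 3")
  if (object@nGroups == 2L && object@cutId != 1L)
    return("only cut 1 (root bisection) may have 2 groups")
  g <- object@groupOfRow
  if (anyNA(g) || any(g < 1L | g > object@nGroups))
    return("every haplotype row must be assigned to a valid group")
  if (!identical(as.integer(tabulate(g, object@nGroups)),
                 object@groupCopies))
    return("groupCopies inconsistent with groupOfRow")
  TRUE
})

#' REML fit of the pedigree-based linear mixed model
#'
#' @slot muHat intercept estimate.
#' @slot bHat named estimates of the free haplotype/SNP coefficients
#'   (length 0-2).
#' @slot Vb estimation variance-covariance matrix of the free coefficients.
#' @slot sigma2a additive polygenic variance estimate.
#' @slot sigma2e residual variance estimate.
#' @slot lambda variance ratio sigma2a/sigma2e at the REML optimum.
#' @slot restrictedLoglik restricted log-likelihood at the optimum.
#' @slot flatProfile TRUE when the restricted likelihood is flat in the
#'   variance ratio (e.g. identity kinship) and the ratio is unidentifiable.
#' @slot n number of phenotyped individuals used.
#'
#' @export
setClass("LMMFit", representation(
  muHat = "numeric",
  bHat = "numeric",
  Vb = "matrix",
  sigma2a = "numeric",
  sigma2e = "numeric",
  lambda = "numeric",
  restrictedLoglik = "numeric",
  flatProfile = "logical",
  n = "integer"
))

#' Genome-scan result
#'
#' Per-SNP per-test Wald statistics from [genmixScan()] (up to seven tests
#' per SNP) or [mmaScan()] (one), plus the per-SNP minimum p-value used for
#' QTL-SNP association calls.
#'
#' @slot method "genmix" or "mma".
#' @slot tests data.frame: snpId, bp, testId, df, statistic, p, note.
#' @slot snps data.frame: snpId, bp, minP, testsPerformed.
#'
#' @export
setClass("ScanResult", representation(
  method = "character",
  tests = "data.frame",
  snps = "data.frame"
))

#' One simulated dataset: pedigree, phased markers, QTL and phenotypes
#'
#' @slot pedigree the full [Pedigree-class].
#' @slot haplotypes [HaplotypeData-class] for the genotyped subset.
#' @slot qtlSite site index of the QTL in `haplotypes` (before removal).
#' @slot alpha allele substitution effect on the phenotype scale.
#' @slot phenotypes data.frame: id, y, trueA, trueE, qtlGeno.
#' @slot h2 polygenic heritability used.
#' @slot sigma2e residual variance used (sigma2a is fixed at 1).
#'
#' @export
setClass("SimulatedDataset", representation(
  pedigree = "Pedigree",
  haplotypes = "HaplotypeData",
  qtlSite = "integer",
  alpha = "numeric",
  phenotypes = "data.frame",
  h2 = "numeric",
  sigma2e = "numeric"
))

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@sire) & is.na(object@dam))
  cat(sprintf("Pedigree: %d individuals (%d founders)\n",
              length(object@id), nf))
})

setMethod("show", "HaplotypeData", function(object) {
  cat(sprintf(
    "HaplotypeData: %d haplotypes (%d individuals) x %d sites, %.1f Mbp\n",
    nrow(object@alleles), length(object@individualIds),
    ncol(object@alleles),
    if (ncol(object@alleles)) diff(range(object@positions)) / 1e6 else 0))
})

setMethod("show", "GeneTree", function(object) {
  cat(sprintf("GeneTree: %d leaves over sites [%d, %d], %d haplotype rows\n",
              sum(object@children[, 1L] == 0L),
              object@interval[1L], object@interval[2L], object@nRows))
})

setMethod("show", "FactorClustering", function(object) {
  cat(sprintf("FactorClustering: cut %d, %d groups, copies: %s\n",
              object@cutId, object@nGroups,
              paste(object@groupCopies, collapse = "/")))
})

setMethod("show", "LMMFit", function(object) {
  cat(sprintf(
    "LMMFit: n = %d, sigma2a = %.4g, sigma2e = %.4g, logLik(R) = %.4f%s\n",
    object@n, object@sigma2a, object@sigma2e, object@restrictedLoglik,
    if (object@flatProfile) " [flat variance-ratio profile]" else ""))
  if (length(object@bHat))
    cat("  b:", paste(sprintf("%s = %.4g", names(object@bHat), object@bHat),
                      collapse = ", "), "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d SNPs, %d tests, min p = %.3g\n",
              object@method, nrow(object@snps), nrow(object@tests),
              suppressWarnings(min(object@snps$minP, na.rm = TRUE))))
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf(
    "SimulatedDataset: %d pedigree members, %d genotyped, %d sites\n",
    length(object@pedigree@id), length(object@haplotypes@individualIds),
    ncol(object@haplotypes@alleles)))
  cat(sprintf("  QTL at site %d (alpha = %.3f, h2 = %.2f)\n",
              object@qtlSite, object@alpha, object@h2))
})

# ---- accessors ----

#' @describeIn Pedigree-class individual ids in pedigree order
#' @param object,x a `Pedigree`
#' @export
pedIds <- function(object) object@id

#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

#' Accessors for HaplotypeData
#'
#' @param object a [HaplotypeData-class]
#' @return `haplotypes()` the 0/1 haplotype matrix; `positions()` bp
#'   positions; `snpIds()` marker ids; `individuals()` individual ids;
#'   `mafs()` per-site minor allele frequencies.
#' @export
haplotypes <- function(object) object@alleles

#' @rdname haplotypes
#' @export
positions <- function(object) object@positions

#' @rdname haplotypes
#' @export
snpIds <- function(object) object@snpIds

#' @rdname haplotypes
#' @export
individuals <- function(object) object@individualIds

#' @rdname haplotypes
#' @export
mafs <- function(object) {
  f <- colMeans(object@alleles)
  pmin(f, 1 - f)
}

#' Per-SNP summary of a scan
#'
#' @param object a [ScanResult-class]
#' @return data.frame with snpId, bp, minP and testsPerformed.
#' @export
scanSummary <- function(object) object@snps

#' @rdname scanSummary
#' @export
scanTests <- function(object) object@tests
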