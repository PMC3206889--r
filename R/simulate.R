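#' Simulate a multi-generation dairy-like pedigree
#'
#' Discrete generations with heavy sire reuse (few sires, many dams per
#' generation), the mating design that gives livestock pedigrees their
#' strong relatedness.  Sexes are assigned at birth; each offspring draws a
#' sire from the previous generation's selected sire pool and a dam from
#' the previous generation's females.  Individuals of the final generation
#' form the genotyped subset.
#'
#' Randomness comes from the current RNG stream; call [set.seed()] first
#' for reproducibility.
#'
#' @param nGenerations number of offspring generations (>= 0); 1 founder
#'   generation is always present.
#' @param nFounders number of founders (>= 2).
#' @param nSires sires used per generation.
#' @param nOffspring offspring per generation.
#' @param nGenotyped genotyped individuals sampled from the last
#'   generation (capped at its size).
#' @return list(pedigree, generation, genotypedIds).
#' @export
simulatePedigree <- function(nGenerations = 5L, nFounders = 400L,
                             nSires = 25L, nOffspring = 1500L,
                             nGenotyped = 1400L) {
  stopifnot(nFounders >= 2L, nGenerations >= 0L, nSires >= 1L)
  id <- sprintf("F%04d", seq_len(nFounders))
  sire <- dam <- rep(NA_character_, nFounders)
  sex <- sample(rep_len(c("M", "F"), nFounders))
  gen <- rep(0L, nFounders)
  prev <- seq_len(nFounders)
  for (g in seq_len(nGenerations)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("impossible mating constraints: generation ", g - 1L,
           " lacks ", if (!length(males)) "males" else "females")
    sires <- if (length(males) <= nSires) males
             else sample(males, nSires)
    newIds <- sprintf("G%d_%04d", g, seq_len(nOffspring))
    s <- sample(sires, nOffspring, replace = TRUE)
    d <- sample(females, nOffspring, replace = TRUE)
    id <- c(id, newIds)
    sire <- c(sire, id[s])
    dam <- c(dam, id[d])
    sex <- c(sex, sample(c("M", "F"), nOffspring, replace = TRUE))
    gen <- c(gen, rep(g, nOffspring))
    prev <- seq.int(length(id) - nOffspring + 1L, length(id))
  }
  ped <- new("Pedigree", id = id, sire = sire, dam = dam)
  last <- id[gen == max(gen)]
  genotyped <- if (length(last) <= nGenotyped) last
               else sort(sample(last, nGenotyped))
  list(pedigree = ped, generation = setNames(gen, id),
       genotypedIds = genotyped)
}

#' Founder haplotype pool by sequential mutation on a recombining ancestry
#'
#' Builds a small pool of haplotypes by sequential copying from a random
#' ancestor: each new pool member is a recombinant copy of two random
#' earlier members, and every SNP arises from a single mutation event
#' assigned to one copying step (infinite-sites model; older steps are
#' weighted so variants tend to be common, as on an ascertained SNP chip).
#' Each copying step carries `ancestryDepth` generations' worth of
#' Haldane-model crossovers, so the pool is locally tree-like — only
#' recombination breaks four-gamete compatibility — while long-range
#' associations are shuffled away, giving the distance-decaying LD of real
#' chip data.  Allele labels are randomized per site so 0 is not always
#' ancestral.  A small pool (default 30) mimics the limited haplotype
#' diversity of a closed breed.
#'
#' @param nHaplotypes pool size.
#' @param nSites number of SNPs.
#' @param positionsBp bp positions of the sites (default 72 kbp spacing).
#' @param ancestryDepth generations of recombination compressed into each
#'   copying step.
#' @param cmPerMbp recombination rate.
#' @return 0/1 integer matrix nHaplotypes x nSites.
#' @export
makeFounderPool <- function(nHaplotypes = 30L, nSites,
                            positionsBp = seq_len(nSites) * 72000,
                            ancestryDepth = 10, cmPerMbp = 1) {
  n <- nHaplotypes
  stopifnot(n >= 2L, length(positionsBp) == nSites)
  pool <- matrix(0L, n, nSites)
  # one mutation event per site, biased toward the older copying steps
  origin <- sample(2:n, nSites, replace = TRUE,
                   prob = rev(seq_len(n - 1L)))
  morgans <- diff(range(positionsBp)) / 1e6 * cmPerMbp / 100 * ancestryDepth
  for (k in 2:n) {
    hap <- if (k == 2L) pool[1L, ]
           else recombineGamete(pool[sample.int(k - 1L, 2L), , drop = FALSE],
                                positionsBp, morgans)
    mut <- origin == k
    hap[mut] <- 1L - hap[mut]
    pool[k, ] <- hap
  }
  swap <- rbinom(nSites, 1L, 0.5) == 1L
  pool[, swap] <- 1L - pool[, swap, drop = FALSE]
  pool
}

# one recombined gamete from parent haplotype rows (2 x nSites) under the
# Haldane model: crossovers are a Poisson process along the genetic map
recombineGamete <- function(parentHaps, positions, morgans) {
  k <- rpois(1L, morgans)
  start <- sample.int(2L, 1L)
  if (k == 0L) return(parentHaps[start, ])
  xo <- sort(runif(k, min(positions), max(positions)))
  src <- (start - 1L + findInterval(positions, xo, left.open = TRUE)) %% 2L
  ifelse(src == 0L, parentHaps[1L, ], parentHaps[2L, ])
}

#' Gene-drop phased haplotypes down a pedigree
#'
#' Founders draw their two haplotypes from the founder pool (with
#' replacement); every non-founder inherits one recombined gamete per
#' parent, with crossovers from a Haldane (Poisson) model at
#' `cmPerMbp` cM/Mbp.  An unknown parent contributes a fresh pool
#' haplotype.  This recreates the pedigree-induced LD that real SNP-chip
#' data carries.
#'
#' @param ped a [Pedigree-class].
#' @param founderPool matrix from [makeFounderPool()].
#' @param positions bp positions (one per pool column).
#' @param genotypedIds individuals to return haplotypes for (default all).
#' @param cmPerMbp recombination rate (default 1 cM/Mbp).
#' @param snpIds optional marker ids.
#' @return [HaplotypeData-class] for the genotyped individuals.
#' @export
geneDrop <- function(ped, founderPool, positions, genotypedIds = ped@id,
                     cmPerMbp = 1, snpIds = NULL) {
  m <- ncol(founderPool)
  if (length(positions) != m)
    stop("map length (", length(positions), ") does not match founder ",
         "haplotypes (", m, " sites)")
  n <- length(ped@id)
  pi <- parentIndices(ped)
  morgans <- diff(range(positions)) / 1e6 * cmPerMbp / 100
  H <- matrix(0L, 2L * n, m)
  poolDraw <- function() founderPool[sample.int(nrow(founderPool), 1L), ]
  for (i in seq_len(n)) {
    for (w in 1:2) {
      p <- if (w == 1L) pi$s[i] else pi$d[i]
      H[2L * i - 2L + w, ] <- if (p == 0L) poolDraw()
        else recombineGamete(H[c(2L * p - 1L, 2L * p), , drop = FALSE],
                             positions, morgans)
    }
  }
  sel <- match(genotypedIds, ped@id)
  rowSel <- as.vector(rbind(2L * sel - 1L, 2L * sel))
  newHaplotypeData(H[rowSel, , drop = FALSE], positions,
                   if (is.null(snpIds)) paste0("snp", seq_len(m)) else snpIds,
                   genotypedIds)
}

#' Simulate residual polygenic values with covariance A * sigma2a
#'
#' Founders (unknown-parent individuals) are N(0, 1); an offspring is the
#' parent average plus a Mendelian sampling deviate with
#' inbreeding-adjusted variance `0.5 * (1 - (F_s + F_d) / 2)`, an unknown
#' parent contributing founder variance instead, so that
#' `Var(a) = A * sigma2a` holds exactly with sigma2a = 1.
#'
#' @param ped a [Pedigree-class].
#' @param F inbreeding coefficients from [inbreeding()] (computed if NULL).
#' @param n number of independent replicate vectors.
#' @return numeric matrix, pedigree members x n.
#' @export
simulatePolygenics <- function(ped, F = NULL, n = 1L) {
  if (is.null(F)) F <- inbreeding(ped)
  N <- length(ped@id)
  pi <- parentIndices(ped)
  a <- matrix(0, N, n, dimnames = list(ped@id, NULL))
  for (i in seq_len(N)) {
    s <- pi$s[i]; d <- pi$d[i]
    if (s == 0L && d == 0L) {
      a[i, ] <- rnorm(n)
    } else if (s > 0L && d > 0L) {
      v <- 0.5 * (1 - (F[s] + F[d]) / 2)
      a[i, ] <- 0.5 * (a[s, ] + a[d, ]) + rnorm(n, 0, sqrt(v))
    } else {
      p <- max(s, d)
      v <- 0.75 - 0.25 * F[p]
      a[i, ] <- 0.5 * a[p, ] + rnorm(n, 0, sqrt(v))
    }
  }
  a
}

#' Simulate phenotypes from a QTL + polygenic + residual model
#'
#' The phenotype of a genotyped individual is exactly
#' `y = alpha * x + a + e` with x the minor-allele count at the QTL site,
#' `a` the residual polygenic value (sigma2a = 1 by construction) and
#' `e ~ N(0, sigma2e)` where `sigma2e = (1 - h2) / h2` fixes the polygenic
#' heritability at h2.  The allele substitution effect is
#' `alpha = qtlEffect * sigma_p` with `sigma_p^2 = sigma2a + sigma2e`, i.e.
#' the effect is expressed in (QTL-exclusive) phenotypic SD units.  The
#' QTL contributes additional variance `2 p (1 - p) alpha^2`.
#'
#' @param ped a [Pedigree-class] containing the genotyped individuals.
#' @param hap [HaplotypeData-class] of the genotyped subset.
#' @param qtlSite site index of the QTL in `hap`.
#' @param h2 polygenic heritability (excluding the QTL) in (0, 1).
#' @param qtlEffect allele substitution effect in phenotypic SD units.
#' @param F optional precomputed inbreeding coefficients.
#' @return list(phenotypes = data.frame(id, y, trueA, trueE, qtlGeno),
#'   alpha, sigma2e, polygenics = full pedigree polygenic vector).
#' @export
simulatePhenotypes <- function(ped, hap, qtlSite, h2, qtlEffect, F = NULL) {
  stopifnot(h2 > 0, h2 < 1, qtlEffect >= 0)
  sigma2e <- (1 - h2) / h2
  alpha <- qtlEffect * sqrt(1 + sigma2e)
  a <- simulatePolygenics(ped, F = F, n = 1L)[, 1L]
  ids <- hap@individualIds
  if (!all(ids %in% ped@id))
    stop("genotyped individuals missing from pedigree")
  al <- hap@alleles[, qtlSite]
  if (all(al == al[1L])) stop("QTL site is monomorphic")
  if (mean(al) > 0.5) al <- 1L - al
  x <- al[seq(1L, length(al), 2L)] + al[seq(2L, length(al), 2L)]
  e <- rnorm(length(ids), 0, sqrt(sigma2e))
  y <- alpha * x + a[ids] + e
  list(phenotypes = data.frame(id = ids, y = y, trueA = unname(a[ids]),
                               trueE = e, qtlGeno = x),
       alpha = alpha, sigma2e = sigma2e, polygenics = a)
}

#' Additive genetic variance contributed by a biallelic QTL
#'
#' `2 p (1 - p) alpha^2` for minor allele frequency p and allele
#' substitution effect alpha.
#'
#' @param p minor allele frequency.
#' @param alpha allele substitution effect.
#' @return variance on the phenotype scale.
#' @export
qtlVariance <- function(p, alpha) 2 * p * (1 - p) * alpha^2

#' Pick QTL sites nearest to target minor allele frequencies
#'
#' One site per target: the site whose realized MAF is closest, ties
#' broken by the left-most position.  A target with no site within
#' `tolerance` is an error naming the MAF.
#'
#' @param hap a [HaplotypeData-class].
#' @param targetMafs numeric vector in (0, 0.5].
#' @param tolerance maximum |realized - target| accepted (default 0.01).
#' @return named integer site indices.
#' @export
selectQtlSites <- function(hap, targetMafs, tolerance = 0.01) {
  f <- mafs(hap)
  vapply(targetMafs, function(t) {
    d <- abs(f - t)
    if (min(d) > tolerance)
      stop("no site within ", tolerance, " of target MAF ", t,
           " (closest: ", format(f[which.min(d)]), ")")
    which(d == min(d))[1L]
  }, integer(1L), USE.NAMES = FALSE) |>
    setNames(paste0("maf", targetMafs))
}

#' Simulate the genetic base of a study: pedigree, markers, kinship
#'
#' One pedigree is simulated, founder haplotypes are gene-dropped to the
#' genotyped subset, sites below the MAF threshold are removed, and the
#' numerator relationship matrix is computed and subset to the genotyped
#' individuals.  Phenotype replicates are then drawn on top of this fixed
#' genetic base, mirroring a study in which real genotypes are fixed and
#' phenotypes are simulated.
#'
#' @inheritParams simulatePedigree
#' @param nSites markers before MAF filtering.
#' @param spacingBp marker spacing (default 72 kbp).
#' @param founderPoolSize distinct founder haplotypes.
#' @param mafThreshold MAF filter.
#' @param cmPerMbp recombination rate.
#' @return list(pedigree, genotypedIds, hap, A (genotyped subset),
#'   F (full pedigree), generation).
#' @export
simulateMarkerData <- function(nGenerations = 5L, nFounders = 400L,
                               nSires = 25L, nOffspring = 1500L,
                               nGenotyped = 1400L, nSites = 1695L,
                               spacingBp = 72000, founderPoolSize = 30L,
                               mafThreshold = 0.05, cmPerMbp = 1) {
  sp <- simulatePedigree(nGenerations, nFounders, nSires, nOffspring,
                         nGenotyped)
  positions <- seq_len(nSites) * spacingBp
  pool <- makeFounderPool(founderPoolSize, nSites, positions,
                          cmPerMbp = cmPerMbp)
  hap <- geneDrop(sp$pedigree, pool, positions, sp$genotypedIds, cmPerMbp)
  hap <- filterMAF(hap, mafThreshold)
  Afull <- computeA(sp$pedigree)
  list(pedigree = sp$pedigree, genotypedIds = sp$genotypedIds, hap = hap,
       A = Afull[sp$genotypedIds, sp$genotypedIds],
       F = diag(Afull) - 1, generation = sp$generation)
}

#' Simulate one complete dataset
#'
#' Convenience wrapper producing a [SimulatedDataset-class] for a single
#' (h2, QTL MAF, effect) condition.
#'
#' @inheritParams simulateMarkerData
#' @param h2 polygenic heritability.
#' @param qtlMaf target QTL minor allele frequency.
#' @param qtlEffect allele substitution effect in phenotypic SD units.
#' @param seed RNG seed.
#' @param qtlTolerance MAF matching tolerance.
#' @return a [SimulatedDataset-class].
#' @export
simulateDataset <- function(h2 = 0.34, qtlMaf = 0.10, qtlEffect = 0.5,
                            seed = 1L, nGenerations = 5L, nFounders = 400L,
                            nSires = 25L, nOffspring = 1500L,
                            nGenotyped = 1400L, nSites = 1695L,
                            spacingBp = 72000, founderPoolSize = 30L,
                            mafThreshold = 0.05, cmPerMbp = 1,
                            qtlTolerance = 0.01) {
  set.seed(seed)
  base <- simulateMarkerData(nGenerations, nFounders, nSires, nOffspring,
                             nGenotyped, nSites, spacingBp, founderPoolSize,
                             mafThreshold, cmPerMbp)
  qtl <- selectQtlSites(base$hap, qtlMaf, tolerance = qtlTolerance)
  sim <- simulatePhenotypes(base$pedigree, base$hap, qtl, h2, qtlEffect,
                            F = base$F)
  new("SimulatedDataset", pedigree = base$pedigree, haplotypes = base$hap,
      qtlSite = as.integer(qtl), alpha = sim$alpha,
      phenotypes = sim$phenotypes, h2 = h2, sigma2e = sim$sigma2e)
}

#' Drop one site from a haplotype matrix
#'
#' Used to remove the SNP assigned as QTL from the analyzed marker set.
#'
#' @param hap a [HaplotypeData-class].
#' @param site site index to remove.
#' @return [HaplotypeData-class] without that site.
#' @export
dropSite <- function(hap, site) {
  keep <- setdiff(seq_len(ncol(hap@alleles)), site)
  new("HaplotypeData", alleles = hap@alleles[, keep, drop = FALSE],
      positions = hap@positions[keep], snpIds = hap@snpIds[keep],
      individualIds = hap@individualIds)
}
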