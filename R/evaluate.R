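#' Bonferroni per-test significance threshold
#'
#' The nominal level divided by the total number of tests:
#' `n_snps x tests_per_snp` (7 tests per SNP for GENMIX — one bisection and
#' six trisections — and 1 for the single-SNP model).  The exact quotient
#' is used for every significance decision; rounding to two significant
#' digits happens only when displaying.
#'
#' @param alpha nominal level (default 0.05).
#' @param nSnps number of SNPs tested.
#' @param testsPerSnp tests per SNP (7 GENMIX, 1 MMA).
#' @return list(threshold, nTests, alpha).
#' @export
bonferroniThreshold <- function(alpha = 0.05, nSnps, testsPerSnp = 1L) {
  stopifnot(alpha > 0, nSnps > 0, testsPerSnp > 0)
  nTests <- nSnps * testsPerSnp
  list(threshold = alpha / nTests, nTests = nTests, alpha = alpha)
}

#' Power criterion: any significant test near the QTL
#'
#' TRUE iff any performed test at a SNP within `windowBp` (inclusive
#' radius) of the QTL position has p below the threshold.
#'
#' @param scan a [ScanResult-class].
#' @param qtlBp QTL position in bp.
#' @param threshold per-test significance threshold.
#' @param windowBp window radius (default 2.5 Mbp).
#' @return logical; FALSE with a warning when no SNP lies in the window.
#' @export
powerCriterion <- function(scan, qtlBp, threshold, windowBp = 2.5e6) {
  t <- scan@tests
  inWin <- abs(t$bp - qtlBp) <= windowBp
  if (!any(inWin)) {
    warning("no SNP within ", windowBp, " bp of the QTL")
    return(FALSE)
  }
  any(t$p[inWin] < threshold, na.rm = TRUE)
}

#' Rank SNPs by ascending per-SNP minimum p
#'
#' Rank 1 is the most significant SNP; exact ties are broken by a seeded
#' uniform draw so that tied markers are ranked in random order; NA
#' p-values rank after all numeric ones.  Ranks are a permutation of
#' 1..n_snps.
#'
#' @param scan a [ScanResult-class] (or numeric vector of p-values).
#' @param seed tie-break seed (typically the replicate seed).
#' @return integer ranks parallel to the scan's SNPs.
#' @export
rankMarkers <- function(scan, seed = 1L) {
  p <- if (is(scan, "ScanResult")) scan@snps$minP else as.numeric(scan)
  n <- length(p)
  tie <- withr_seed(seed, runif(n))
  ord <- order(p, tie, na.last = TRUE)
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  ranks
}

# evaluate expr under a temporary seed, restoring the RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Best marker rank within a window of the QTL
#'
#' The minimum rank among SNPs within `windowBp` (radius) of the QTL.
#'
#' @param ranks integer ranks from [rankMarkers()].
#' @param positions bp positions parallel to `ranks`.
#' @param qtlBp QTL position.
#' @param windowBp window radius (default 1 Mbp).
#' @return list(bestRank, nMarkers); bestRank is NA when the window is
#'   empty.
#' @export
bestRankWithinWindow <- function(ranks, positions, qtlBp, windowBp = 1e6) {
  inWin <- abs(positions - qtlBp) <= windowBp
  if (!any(inWin)) return(list(bestRank = NA_integer_, nMarkers = 0L))
  list(bestRank = min(ranks[inWin]), nMarkers = sum(inWin))
}

#' Aggregate a study manifest into power and ranking tables
#'
#' Power per (h2, MAF, effect, method) is the fraction of replicates in
#' which the QTL was detected; the ranking distribution pools the best
#' rank within 1 Mbp over replicates per (MAF, method), as when pooling
#' heritabilities and effect sizes at one MAF.
#'
#' @param manifest the list returned by [runStudy()].
#' @return list(power, ranking) data.frames.
#' @export
aggregateStudy <- function(manifest) {
  r <- manifest$results
  pow <- do.call(rbind, lapply(
    split(r, list(r$h2, r$maf, r$effect, r$method), drop = TRUE),
    function(d) data.frame(h2 = d$h2[1L], maf = d$maf[1L],
                           effect = d$effect[1L], method = d$method[1L],
                           nDetected = sum(d$detected),
                           nReplicates = nrow(d),
                           power = mean(d$detected))))
  pow <- pow[order(pow$method, pow$h2, pow$maf, pow$effect), ]
  rownames(pow) <- NULL
  rank <- r[, c("h2", "maf", "effect", "replicate", "method",
                "bestRank", "nMarkersInWindow")]
  list(power = pow, ranking = rank)
}

#' Reference synthetic comparison of GENMIX and MMA
#'
#' A fixed-size replicated study used to compare the two methods on
#' simulated data: a 5-generation dairy-like pedigree with 500 genotyped
#' individuals, 300 chip-like SNP sites at 72 kbp spacing, QTL at minor
#' allele frequency 0.10, allele substitution effects 0.2 and 0.5
#' phenotypic SDs, polygenic heritability 0.34, 25 replicates per effect
#' level.  All randomness derives from `seed`.
#'
#' @param seed master seed.
#' @param nReplicates replicates per effect level.
#' @return a [runStudy()] manifest.
#' @export
comparisonStudy <- function(seed = 1L, nReplicates = 25L) {
  runStudy(h2 = 0.34, mafs = 0.10, effects = c(0.2, 0.5),
           nReplicates = nReplicates, seed = seed,
           nGenerations = 5L, nFounders = 150L, nSires = 15L,
           nOffspring = 550L, nGenotyped = 500L, nSites = 300L,
           qtlTolerance = 0.02)
}

#' Run a replicated simulation study of GENMIX versus MMA
#'
#' Simulates one genetic base (pedigree, gene-dropped phased markers,
#' relationship matrix) from the master seed, then for every combination
#' of heritability, QTL MAF and effect size and every replicate draws
#' phenotypes, removes the SNP assigned as QTL from the analyzed marker
#' set, runs both the GENMIX and the single-SNP mixed-model scans, and
#' evaluates Bonferroni-corrected power (2.5 Mbp window) and the best
#' marker rank within 1 Mbp.  Local-tree factors are computed once per
#' marker set and reused across replicates.  Per-replicate seeds are
#' derived deterministically from the master seed.
#'
#' The default grid is the full 3 heritabilities x 7 MAFs x 5 effects x 25
#' replicates design (105 scenarios, 2,625 analyses); `planOnly = TRUE`
#' enumerates it without computing.
#'
#' @param h2 heritability levels.
#' @param mafs QTL minor-allele-frequency levels.
#' @param effects QTL effects in phenotypic SD units.
#' @param nReplicates replicates per scenario.
#' @param seed master seed; all randomness derives from it.
#' @param alpha nominal significance level.
#' @param planOnly only enumerate the grid.
#' @param outDir optional directory for per-replicate TSVs; completed
#'   replicates found there are reused (resumable runs).
#' @param minGroupCopies GENMIX group-size threshold.
#' @param qtlTolerance QTL MAF matching tolerance.
#' @param verbose print per-replicate progress.
#' @inheritParams simulateMarkerData
#' @return manifest list: config, seed, grid, nScenarios, nAnalyses,
#'   qtlSites, results (one row per analysis per method), failures.
#' @export
runStudy <- function(h2 = c(0.21, 0.34, 0.64),
                     mafs = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.35, 0.45),
                     effects = c(0.1, 0.2, 0.5, 0.7, 1.0),
                     nReplicates = 25L, seed = 1L, alpha = 0.05,
                     planOnly = FALSE, outDir = NULL,
                     minGroupCopies = 4L, qtlTolerance = 0.01,
                     nGenerations = 5L, nFounders = 400L, nSires = 25L,
                     nOffspring = 1500L, nGenotyped = 1400L,
                     nSites = 1695L, spacingBp = 72000,
                     founderPoolSize = 30L, mafThreshold = 0.05,
                     cmPerMbp = 1, verbose = FALSE) {
  scen <- expand.grid(h2 = h2, maf = mafs, effect = effects,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- merge(scen, data.frame(replicate = seq_len(nReplicates)))
  manifest <- list(
    config = list(h2 = h2, mafs = mafs, effects = effects,
                  nReplicates = nReplicates, alpha = alpha,
                  nGenerations = nGenerations, nFounders = nFounders,
                  nSires = nSires, nOffspring = nOffspring,
                  nGenotyped = nGenotyped, nSites = nSites,
                  spacingBp = spacingBp, founderPoolSize = founderPoolSize,
                  mafThreshold = mafThreshold, cmPerMbp = cmPerMbp,
                  minGroupCopies = minGroupCopies),
    seed = seed, grid = grid,
    nScenarios = nrow(scen),
    nAnalyses = nrow(grid))
  if (planOnly) return(manifest)

  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  base <- simulateMarkerData(nGenerations, nFounders, nSires, nOffspring,
                             nGenotyped, nSites, spacingBp,
                             founderPoolSize, mafThreshold, cmPerMbp)
  qtlSites <- selectQtlSites(base$hap, mafs, tolerance = qtlTolerance)
  hap <- base$hap
  # one analyzed marker set (QTL removed) and factor set per MAF level
  perMaf <- lapply(seq_along(mafs), function(k) {
    hm <- dropSite(hap, qtlSites[k])
    list(hap = hm, qtlBp = hap@positions[qtlSites[k]],
         factors = genmixFactors(hm),
         thrG = bonferroniThreshold(alpha, ncol(hm@alleles), 7L)$threshold,
         thrM = bonferroniThreshold(alpha, ncol(hm@alleles), 1L)$threshold)
  })
  names(perMaf) <- as.character(mafs)

  res <- vector("list", nrow(grid))
  failures <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tag <- sprintf("h2%.2f_maf%.2f_eff%.1f_rep%d",
                   g$h2, g$maf, g$effect, g$replicate)
    cache <- if (!is.null(outDir)) file.path(outDir, paste0(tag, ".tsv"))
    if (!is.null(outDir) && file.exists(cache)) {
      res[[i]] <- read.table(cache, header = TRUE,
                             colClasses = c(method = "character"))
      next
    }
    pm <- perMaf[[as.character(g$maf)]]
    out <- tryCatch({
      set.seed(repSeeds[i])
      sim <- simulatePhenotypes(base$pedigree, hap,
                                qtlSites[[as.character(paste0("maf", g$maf))]],
                                g$h2, g$effect, F = base$F)
      y <- sim$phenotypes[, c("id", "y")]
      sg <- genmixScan(pm$hap, y, base$A, minGroupCopies = minGroupCopies,
                       factors = pm$factors)
      sm <- mmaScan(pm$hap, y, base$A)
      evalOne <- function(scan, thr) {
        rk <- rankMarkers(scan, seed = repSeeds[i])
        bw <- bestRankWithinWindow(rk, scan@snps$bp, pm$qtlBp, 1e6)
        data.frame(h2 = g$h2, maf = g$maf, effect = g$effect,
                   replicate = g$replicate, method = scan@method,
                   detected = powerCriterion(scan, pm$qtlBp, thr, 2.5e6),
                   bestRank = bw$bestRank,
                   nMarkersInWindow = bw$nMarkers,
                   minP = suppressWarnings(min(scan@snps$minP, na.rm = TRUE)))
      }
      rbind(evalOne(sg, pm$thrG), evalOne(sm, pm$thrM))
    }, error = function(e) {
      failures <<- c(failures, paste0(tag, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(out) && !is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      write.table(out, cache, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res[[i]] <- out
    if (verbose) message(tag, " done")
  }
  manifest$repSeeds <- repSeeds
  manifest$qtlSites <- qtlSites
  manifest$qtlBp <- vapply(perMaf, `[[`, numeric(1L), "qtlBp")
  manifest$nSnpsAnalyzed <- ncol(perMaf[[1L]]$hap@alleles)
  manifest$results <- do.call(rbind, res)
  manifest$failures <- failures
  manifest
}
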