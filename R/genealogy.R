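#' Four-gamete test between two sites
#'
#' Two biallelic sites are compatible with a single tree topology (no
#' recurrent mutation or recombination between them) iff fewer than all
#' four gametes 00, 01, 10, 11 are observed across the haplotype rows.
#'
#' @param hap a [HaplotypeData-class].
#' @param siteA,siteB site (column) indices; both must be polymorphic.
#' @return TRUE iff the pair passes the four-gamete test.
#' @export
fourGameteCompatible <- function(hap, siteA, siteB) {
  a <- hap@alleles[, siteA]
  b <- hap@alleles[, siteB]
  if (all(a == a[1L])) stop("site ", siteA, " is monomorphic")
  if (all(b == b[1L])) stop("site ", siteB, " is monomorphic")
  gameteCount(a, b) < 4L
}

# number of distinct gametes over two 0/1 columns
gameteCount <- function(a, b) {
  sum(tabulate(2L * a + b + 1L, 4L) > 0L)
}

# candidate site is compatible with every site of the interval; sites
# monomorphic across the rows impose no constraint
compatibleWithAll <- function(alleles, cand, sites) {
  a <- alleles[, cand]
  if (all(a == a[1L])) return(TRUE)
  for (s in sites) {
    b <- alleles[, s]
    if (all(b == b[1L])) next
    if (gameteCount(a, b) == 4L) return(FALSE)
  }
  TRUE
}

#' Maximal four-gamete-compatible interval around a focal SNP
#'
#' Grows an interval of sites around `focalSite` by alternating single-site
#' extensions right, left, right, ... ; an extension is accepted only if
#' the new site is pairwise four-gamete compatible with every site already
#' in the interval.  Once a side fails it stays closed (pairwise
#' compatibility with a superset can only be harder).  The result is
#' pairwise compatible and cannot be extended by one site on either side.
#'
#' @param hap a [HaplotypeData-class].
#' @param focalSite polymorphic site index.
#' @return integer c(left, right), inclusive site indices.
#' @export
maximalCompatibleInterval <- function(hap, focalSite) {
  al <- hap@alleles
  m <- ncol(al)
  stopifnot(focalSite >= 1L, focalSite <= m)
  left <- right <- as.integer(focalSite)
  openR <- right < m
  openL <- left > 1L
  side <- "R"
  while (openR || openL) {
    if (side == "R" && openR) {
      if (compatibleWithAll(al, right + 1L, left:right)) right <- right + 1L
      else openR <- FALSE
      openR <- openR && right < m
    } else if (side == "L" && openL) {
      if (compatibleWithAll(al, left - 1L, left:right)) left <- left - 1L
      else openL <- FALSE
      openL <- openL && left > 1L
    }
    side <- if (side == "R") "L" else "R"
  }
  c(left = left, right = right)
}

#' Build the rooted binary perfect-phylogeny gene tree of a region
#'
#' Over a pairwise four-gamete-compatible interval, each site's derived
#' allele (taken as the minor allele; ties treated as allele 1 derived)
#' arose once, so derived-allele carriers form a clade.  Identical
#' haplotype strings collapse to a single leaf carrying all matching rows.
#' The root is the all-ancestral haplotype; multifurcations are resolved
#' deterministically by repeatedly joining the two children carrying the
#' fewest haplotype copies (ties by smallest leaf haplotype string).  This
#' agglomerative resolution keeps the major clades within the top tree
#' levels where [extractFactors()] cuts.
#'
#' @param hap a [HaplotypeData-class].
#' @param interval integer c(left, right) from [maximalCompatibleInterval()].
#' @return a [GeneTree-class].
#' @export
buildPerfectPhylogeny <- function(hap, interval) {
  al <- hap@alleles[, interval[1L]:interval[2L], drop = FALSE]
  nr <- nrow(al)

  # derived = minor allele within the rows; tie -> allele 1
  ones <- colSums(al)
  derived <- al
  flip <- ones > nr / 2
  if (any(flip)) derived[, flip] <- 1L - al[, flip, drop = FALSE]
  poly <- colSums(derived) > 0L & colSums(derived) < nr
  derived <- derived[, poly, drop = FALSE]

  key <- apply(al, 1L, paste, collapse = "")
  uk <- unique(key)
  leafRows <- lapply(uk, function(k) which(key == k))
  L <- length(uk)
  D <- derived[match(uk, key), , drop = FALSE]  # distinct haplotypes x sites

  nodes <- new.env()
  nodes$children <- matrix(0L, 0L, 2L)
  nodes$leafRows <- list()
  nodes$hapStr <- character(0)
  nodes$minStr <- character(0)   # smallest leaf string in subtree
  nodes$nCopies <- integer(0)    # haplotype copies in subtree

  addNode <- function(ch, rows, hs, minStr, nc) {
    nodes$children <- rbind(nodes$children, ch)
    nodes$leafRows[[length(nodes$leafRows) + 1L]] <- rows
    nodes$hapStr <- c(nodes$hapStr, hs)
    nodes$minStr <- c(nodes$minStr, minStr)
    nodes$nCopies <- c(nodes$nCopies, nc)
    nrow(nodes$children)
  }

  combine <- function(i, j) {
    addNode(c(i, j), integer(0), NA_character_,
            min(nodes$minStr[i], nodes$minStr[j]),
            nodes$nCopies[i] + nodes$nCopies[j])
  }

  agglomerate <- function(ids) {
    # repeatedly join the two smallest children (by haplotype copies,
    # ties by smallest leaf string); deterministic and balance-preserving
    while (length(ids) > 1L) {
      o <- order(nodes$nCopies[ids], nodes$minStr[ids])
      ids <- c(ids[-o[1:2]], combine(ids[o[1L]], ids[o[2L]]))
    }
    ids
  }

  build <- function(leafIdx, siteIdx) {
    if (length(leafIdx) == 1L) {
      i <- leafIdx
      return(addNode(c(0L, 0L), leafRows[[i]], uk[i], uk[i],
                     length(leafRows[[i]])))
    }
    sub <- D[leafIdx, siteIdx, drop = FALSE]
    cs <- colSums(sub)
    active <- siteIdx[cs > 0L & cs < length(leafIdx)]
    # derived-carrier sets among these leaves; laminar by compatibility
    sets <- lapply(active, function(s) leafIdx[D[leafIdx, s] == 1L])
    sets <- unique(sets)
    maximal <- sets[!vapply(sets, function(x)
      any(vapply(sets, function(y)
        length(y) > length(x) && all(x %in% y), logical(1L))), logical(1L))]
    covered <- unlist(maximal)
    kids <- c(
      lapply(maximal, function(M) build(M, active)),
      lapply(leafIdx[!leafIdx %in% covered], function(i) build(i, active))
    )
    agglomerate(unlist(kids))
  }

  root <- build(seq_len(L), seq_len(ncol(D)))

  # re-root so node 1 is the root: renumber by preorder from root
  n <- nrow(nodes$children)
  perm <- integer(n); cnt <- 0L
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    cnt <- cnt + 1L; perm[v] <- cnt
    ch <- nodes$children[v, ]
    if (ch[1L] > 0L) stack <- c(stack, ch[2L], ch[1L])
  }
  ch <- nodes$children
  ch[ch > 0L] <- perm[ch[ch > 0L]]
  ord <- order(perm)
  new("GeneTree",
      children = ch[ord, , drop = FALSE],
      leafRows = nodes$leafRows[ord],
      hapStrings = nodes$hapStr[ord],
      nRows = nr,
      interval = as.integer(interval))
}

subtreeRows <- function(tree, v) {
  rows <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ch <- tree@children[u, ]
    if (ch[1L] == 0L) rows <- c(rows, tree@leafRows[[u]])
    else stack <- c(stack, ch)
  }
  rows
}

#' Cut a gene tree into up to seven haplotype clusterings
#'
#' Cut 1 bisects at the root: the two clusters are the haplotypes under
#' each root child.  Cuts 2-3 trisect at the two depth-1 internal nodes and
#' cuts 4-7 at the four depth-2 internal nodes; a trisection at node v
#' yields the haplotypes outside v, those under v's first child and those
#' under v's second child.  Nodes that do not exist or are leaves yield no
#' clustering, so a deep tree yields exactly seven factors and a shallow
#' one fewer.
#'
#' @param tree a [GeneTree-class].
#' @return list of [FactorClustering-class] (length 0-7; empty for a
#'   single-leaf tree).
#' @export
extractFactors <- function(tree) {
  ch <- tree@children
  if (ch[1L, 1L] == 0L) return(list())  # single leaf
  out <- list()
  asF <- function(cutId, groups) {
    g <- integer(tree@nRows)
    for (k in seq_along(groups)) g[groups[[k]]] <- k
    new("FactorClustering", cutId = as.integer(cutId),
        nGroups = length(groups), groupOfRow = g,
        groupCopies = as.integer(tabulate(g, length(groups))))
  }
  rootKids <- ch[1L, ]
  out[[1L]] <- asF(1L, list(subtreeRows(tree, rootKids[1L]),
                            subtreeRows(tree, rootKids[2L])))
  cutId <- 1L
  depth2 <- integer(0)
  all_rows <- seq_len(tree@nRows)
  for (v in rootKids) {
    cutId <- cutId + 1L
    if (ch[v, 1L] > 0L) {
      kids <- ch[v, ]
      inside1 <- subtreeRows(tree, kids[1L])
      inside2 <- subtreeRows(tree, kids[2L])
      outside <- setdiff(all_rows, c(inside1, inside2))
      out[[length(out) + 1L]] <- asF(cutId, list(outside, inside1, inside2))
      depth2 <- c(depth2, kids)
    } else depth2 <- c(depth2, NA_integer_, NA_integer_)
  }
  for (v in depth2) {
    cutId <- cutId + 1L
    if (!is.na(v) && ch[v, 1L] > 0L) {
      kids <- ch[v, ]
      inside1 <- subtreeRows(tree, kids[1L])
      inside2 <- subtreeRows(tree, kids[2L])
      outside <- setdiff(all_rows, c(inside1, inside2))
      out[[length(out) + 1L]] <- asF(cutId, list(outside, inside1, inside2))
    }
  }
  out
}

#' Diploid haplotype-count design from a clustering
#'
#' Per individual, counts how many of its two haplotypes fall in each
#' group of the clustering; each row sums to 2, so the counts of the first
#' one or two groups determine the rest (`c1 + c2 <= 2`, third-group count
#' `2 - c1 - c2`).
#'
#' @param clustering a [FactorClustering-class].
#' @param hap the [HaplotypeData-class] the clustering's rows refer to.
#' @return integer matrix, individuals x groups.
#' @export
countsMatrix <- function(clustering, hap) {
  g <- clustering@groupOfRow
  nInd <- length(hap@individualIds)
  if (length(g) != 2L * nInd)
    stop("clustering covers ", length(g), " haplotype rows but data has ",
         2L * nInd)
  ng <- clustering@nGroups
  ind <- rep(seq_len(nInd), each = 2L)
  cnt <- tabulate((ind - 1L) * ng + g, nInd * ng)
  matrix(as.integer(cnt), nInd, ng, byrow = TRUE,
         dimnames = list(hap@individualIds, paste0("g", seq_len(ng))))
}

#' Local tree and clusterings for every SNP
#'
#' Convenience wrapper running [maximalCompatibleInterval()],
#' [buildPerfectPhylogeny()] and [extractFactors()] for each site.  Local
#' trees depend only on the haplotypes, so over replicated phenotype
#' simulations the factors can be computed once and passed to
#' [genmixScan()].
#'
#' @param hap a [HaplotypeData-class].
#' @return list, per SNP: list(interval, factors, counts) where counts is a
#'   list of per-clustering count matrices.
#' @export
genmixFactors <- function(hap) {
  m <- ncol(hap@alleles)
  lapply(seq_len(m), function(j) {
    iv <- maximalCompatibleInterval(hap, j)
    tr <- buildPerfectPhylogeny(hap, iv)
    fs <- extractFactors(tr)
    list(interval = iv, factors = fs,
         counts = lapply(fs, countsMatrix, hap = hap))
  })
}
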