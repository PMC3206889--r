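# Independent oracles used across the suite.  These deliberately take
# different algorithmic routes than the package implementation.

# Additive relationship by the coancestry (kinship) recursion: A = 2 * phi,
# phi(i,i) = (1 + phi(s_i, d_i)) / 2, phi(i,j) recursing on the parents of
# the later-born individual.  Pairwise and memoized, unlike the tabular fill.
coancestryA <- function(ped) {
  n <- length(pedIds(ped))
  pos <- seq_len(n)
  names(pos) <- pedIds(ped)
  s <- ifelse(is.na(ped@sire), 0L, pos[ped@sire])
  d <- ifelse(is.na(ped@dam), 0L, pos[ped@dam])
  memo <- matrix(NA_real_, n, n)
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    a <- min(i, j); b <- max(i, j)
    if (!is.na(memo[a, b])) return(memo[a, b])
    v <- if (i == j) 0.5 * (1 + phi(s[i], d[i]))
         else 0.5 * (phi(a, s[b]) + phi(a, d[b]))
    memo[a, b] <<- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(pedIds(ped), pedIds(ped)))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# random valid pedigree: each non-founder draws parents among earlier ids
randomPedigree <- function(n, pFounder = 0.4) {
  id <- sprintf("i%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i >= 3L && runif(1) > pFounder) {
      pr <- sample(i - 1L, 2L)
      sire[i] <- id[pr[1L]]; dam[i] <- id[pr[2L]]
    }
  }
  newPedigree(id, sire, dam)
}

# brute-force gamete enumeration for the four-gamete test
gameteSetOracle <- function(a, b) {
  length(unique(paste0(a, b))) >= 4L
}

# all-pairs four-gamete compatibility of a site range, by enumeration
allPairsCompatible <- function(alleles, sites) {
  for (i in sites) for (j in sites) {
    if (i >= j) next
    a <- alleles[, i]; b <- alleles[, j]
    if (all(a == a[1L]) || all(b == b[1L])) next
    if (gameteSetOracle(a, b)) return(FALSE)
  }
  TRUE
}

# random perfect-phylogeny-compatible haplotype matrix: sites are clades of
# one random binary tree (derived below a random edge), rows expand leaves
# with random multiplicities
randomCompatibleMatrix <- function(nLeaves, nSites, maxCopies = 3L) {
  below <- vector("list", 2L * nLeaves - 1L)
  for (l in seq_len(nLeaves)) below[[l]] <- l
  avail <- seq_len(nLeaves)  # roots of current forest
  nodeId <- nLeaves
  while (length(avail) > 1L) {
    pick <- sample(length(avail), 2L)
    nodeId <- nodeId + 1L
    below[[nodeId]] <- c(below[[avail[pick[1L]]]], below[[avail[pick[2L]]]])
    avail <- c(avail[-pick], nodeId)
  }
  edges <- seq_len(nodeId - 1L)  # every non-root node subtends an edge
  leafAlleles <- matrix(0L, nLeaves, nSites)
  for (s in seq_len(nSites)) {
    e <- sample(edges, 1L)
    leafAlleles[below[[e]], s] <- 1L
  }
  copies <- sample(maxCopies, nLeaves, replace = TRUE)
  if (sum(copies) %% 2L == 1L) copies[1L] <- copies[1L] + 1L
  leafAlleles[rep(seq_len(nLeaves), copies), , drop = FALSE]
}

# all clades (leaf-row sets under each node) of a GeneTree
treeClades <- function(tree) {
  n <- nrow(tree@children)
  lapply(seq_len(n), function(v) sort(genmix:::subtreeRows(tree, v)))
}

# dense restricted log-likelihood, written from the definition with base
# solve/determinant (independent of the package's spectral profile path)
denseREMLLoglik <- function(y, X, A, s2a, s2e) {
  n <- length(y); p <- ncol(X)
  V <- s2a * A + s2e * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            as.numeric(t(r) %*% Vi %*% r) + (n - p) * log(2 * pi))
}

# haplotype data with independent random sites (no LD), for null checks
randomHapData <- function(nInd, nSites, freqRange = c(0.1, 0.5)) {
  f <- runif(nSites, freqRange[1L], freqRange[2L])
  al <- vapply(f, function(p) rbinom(2L * nInd, 1L, p), integer(2L * nInd))
  # guarantee polymorphism
  al[1L, al[1L, ] == al[2L, ] & colSums(al) %in% c(0L, 2L * nInd)] <- 1L
  for (j in seq_len(nSites)) if (all(al[, j] == al[1L, j]))
    al[1L:2L, j] <- c(0L, 1L)
  newHaplotypeData(al, seq_len(nSites) * 72000)
}

# small study base shared by mixed-model tests (built once per test file)
smallStudyBase <- function(seed = 7L, nGenerations = 3L, nFounders = 60L,
                           nSires = 6L, nOffspring = 120L,
                           nGenotyped = 100L, nSites = 60L) {
  set.seed(seed)
  simulateMarkerData(nGenerations, nFounders, nSires, nOffspring,
                     nGenotyped, nSites)
}
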