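hapFromMatrix <- function(m) newHaplotypeData(m, seq_len(ncol(m)) * 1000)

test_that("four-gamete test detects exactly the four-gamete configurations", {
  h <- hapFromMatrix(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  expect_false(fourGameteCompatible(h, 1, 2))
  h2 <- hapFromMatrix(rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L), c(1L, 1L)))
  expect_true(fourGameteCompatible(h2, 1, 2))
  mono <- hapFromMatrix(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L)))
  expect_error(fourGameteCompatible(mono, 1, 2), "monomorphic")
})

test_that("four-gamete test agrees with exhaustive gamete enumeration", {
  set.seed(21)
  for (k in 1:200) {
    m <- matrix(rbinom(40, 1L, runif(1, 0.2, 0.8)), 20, 2)
    if (any(apply(m, 2, function(x) all(x == x[1L])))) next
    expect_identical(fourGameteCompatible(hapFromMatrix(m), 1, 2),
                     !gameteSetOracle(m[, 1L], m[, 2L]))
  }
})

test_that("maximal interval spans copies of one site and collapses between incompatible flanks", {
  one <- rbinom(12, 1L, 0.5); one[1:2] <- c(0L, 1L)
  h <- hapFromMatrix(matrix(one, 12, 9))
  expect_identical(unname(maximalCompatibleInterval(h, 5)), c(1L, 9L))

  # focal flanked by sites incompatible with it
  a <- c(0L, 0L, 1L, 1L)
  b <- c(0L, 1L, 0L, 1L)
  h2 <- hapFromMatrix(cbind(b, a, b))
  expect_identical(unname(maximalCompatibleInterval(h2, 2)), c(2L, 2L))
})

test_that("maximal interval is all-pairs compatible and not extendable", {
  set.seed(22)
  for (k in 1:30) {
    m <- matrix(rbinom(16 * 30, 1L, 0.4), 16, 30)
    poly <- which(apply(m, 2, function(x) !all(x == x[1L])))
    if (!length(poly)) next
    h <- hapFromMatrix(m)
    focal <- sample(poly, 1L)
    iv <- maximalCompatibleInterval(h, focal)
    sites <- iv[1L]:iv[2L]
    expect_true(allPairsCompatible(m, sites))
    if (iv[1L] > 1L)
      expect_false(allPairsCompatible(m, c(iv[1L] - 1L, sites)))
    if (iv[2L] < 30L)
      expect_false(allPairsCompatible(m, c(sites, iv[2L] + 1L)))
  }
})

test_that("single-site tree bisects carriers from non-carriers", {
  h <- hapFromMatrix(matrix(c(0L, 0L, 1L, 0L), 4, 1))
  tr <- buildPerfectPhylogeny(h, c(1L, 1L))
  expect_identical(sum(tr@children[, 1L] == 0L), 2L)
  fs <- extractFactors(tr)
  expect_length(fs, 1L)
  g <- fs[[1L]]@groupOfRow
  expect_identical(g[3L] == g[1L], FALSE)
  expect_true(g[1L] == g[2L] && g[2L] == g[4L])
})

test_that("three-haplotype region yields the caterpillar with the ancestral haplotype at the root", {
  # 00 x4, 10, 11: the minor (derived) allele is 1 at both sites, so the
  # derived sets {10,11} and {11} nest and the tree is ((10,11),00)
  m <- rbind(matrix(0L, 4, 2), c(1L, 0L), c(1L, 1L))
  tr <- buildPerfectPhylogeny(hapFromMatrix(m), c(1L, 2L))
  clades <- treeClades(tr)
  expect_true(list(sort(c(5L, 6L))) %in% clades)  # carriers of site-1 derived
  expect_true(list(6L) %in% clades)               # carrier of site-2 derived
  expect_true(list(1:4) %in% clades)              # ancestral haplotype leaf
})

test_that("derived-allele carriers form clades on random compatible matrices", {
  set.seed(23)
  for (k in 1:40) {
    m <- randomCompatibleMatrix(sample(3:6, 1L), sample(2:8, 1L))
    if (nrow(m) > 16L) m <- m[1:16, , drop = FALSE]
    h <- hapFromMatrix(m)
    iv <- c(1L, ncol(m))
    if (!allPairsCompatible(m, 1:ncol(m))) next  # multiplicity truncation
    tr <- buildPerfectPhylogeny(h, iv)
    clades <- treeClades(tr)
    for (s in seq_len(ncol(m))) {
      x <- m[, s]
      if (all(x == x[1L])) next
      derived <- if (sum(x) > nrow(m) / 2) which(x == 0L) else which(x == 1L)
      expect_true(list(sort(derived)) %in% clades,
                  label = sprintf("site %d of case %d is a clade", s, k))
    }
  }
})

test_that("a depth-3 complete tree yields exactly seven factors", {
  # 8 haplotypes; one site per clade of the complete depth-3 tree (the two
  # depth-1 clades, the four depth-2 pairs) plus singletons to separate the
  # leaves within each pair
  clades <- list(1:4, 5:8, 1:2, 3:4, 5:6, 7:8, 1L, 3L, 5L, 7L)
  sites <- vapply(clades, function(cl) as.integer(1:8 %in% cl),
                  integer(8L))
  h <- hapFromMatrix(sites)
  tr <- buildPerfectPhylogeny(h, c(1L, 10L))
  expect_identical(sum(tr@children[, 1L] == 0L), 8L)
  fs <- extractFactors(tr)
  expect_length(fs, 7L)
  expect_identical(fs[[1L]]@nGroups, 2L)
  expect_true(all(vapply(fs[-1L], slot, integer(1L), "nGroups") == 3L))
  expect_identical(vapply(fs, slot, integer(1L), "cutId"), 1:7)
})

test_that("shallow trees yield fewer factors, with groups matching manual clades", {
  # two leaves: bisection only
  h2 <- hapFromMatrix(matrix(c(0L, 0L, 1L, 0L), 4, 1))
  expect_length(extractFactors(buildPerfectPhylogeny(h2, c(1L, 1L))), 1L)

  # caterpillar of 4 distinct haplotypes: ladder (((d,c),b),a)
  m <- rbind(rep(0L, 3),
             c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 0L, 0L),
             c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  tr <- buildPerfectPhylogeny(hapFromMatrix(m), c(1L, 3L))
  fs <- extractFactors(tr)
  # agglomeration joins the two smallest children first, so the majority
  # haplotype b sits alone under the root: root = ((a, (d, c)), b);
  # factors at the root, the 3-leaf node, and its {c, d} child
  expect_length(fs, 3L)
  expect_identical(vapply(fs, slot, integer(1L), "cutId"), c(1L, 2L, 5L))
  bis <- fs[[1L]]@groupOfRow          # {a,c,d} vs {b}
  expect_identical(length(unique(bis[c(1L, 6:8)])), 1L)
  expect_identical(length(unique(bis[2:5])), 1L)
  expect_false(bis[1L] == bis[2L])
  tri <- fs[[2L]]@groupOfRow          # outside {b}; clades {c,d} and {a}
  expect_identical(length(unique(tri)), 3L)
  expect_true(all(tri[2:5] == tri[2L]))
  expect_true(all(tri[6:8] == tri[6L]))
  expect_false(tri[1L] %in% tri[2:8])
  tri2 <- fs[[3L]]@groupOfRow         # outside {a,b}; clades {c} and {d}
  expect_true(tri2[1L] == tri2[2L])
  expect_false(tri2[8L] %in% tri2[1:7])

  # single-leaf tree: no factors
  h1 <- hapFromMatrix(matrix(0L, 4, 2))
  # all-monomorphic region collapses to one leaf
  tr1 <- buildPerfectPhylogeny(h1, c(1L, 2L))
  expect_length(extractFactors(tr1), 0L)
})

test_that("every clustering partitions all haplotype rows", {
  set.seed(24)
  for (k in 1:20) {
    m <- randomCompatibleMatrix(sample(3:8, 1L), sample(3:8, 1L))
    h <- hapFromMatrix(m)
    tr <- buildPerfectPhylogeny(h, c(1L, ncol(m)))
    fs <- extractFactors(tr)
    nl <- sum(tr@children[, 1L] == 0L)
    if (nl >= 2L) expect_gte(length(fs), 1L)
    expect_lte(length(fs), 7L)
    for (f in fs) {
      expect_length(f@groupOfRow, nrow(m))
      expect_true(all(f@groupOfRow %in% seq_len(f@nGroups)))
      expect_true(all(f@groupCopies > 0L))
    }
  }
})

test_that("counts matrices count haplotype membership and conserve copies", {
  g <- new("FactorClustering", cutId = 2L, nGroups = 3L,
           groupOfRow = c(1L, 1L, 1L, 3L, 2L, 3L),
           groupCopies = c(3L, 1L, 2L))
  h <- newHaplotypeData(matrix(0:1, 6, 2), c(1, 2) * 1000,
                        individualIds = c("a", "b", "c"))
  cm <- countsMatrix(g, h)
  expect_identical(cm["a", ], c(g1 = 2L, g2 = 0L, g3 = 0L))
  expect_identical(cm["b", ], c(g1 = 1L, g2 = 0L, g3 = 1L))  # het across 1/3
  expect_identical(cm["c", ], c(g1 = 0L, g2 = 1L, g3 = 1L))
  expect_true(all(rowSums(cm) == 2L))

  set.seed(25)
  for (k in 1:20) {
    m <- randomCompatibleMatrix(4L, 5L)
    h <- hapFromMatrix(m)
    tr <- buildPerfectPhylogeny(h, c(1L, 5L))
    for (f in extractFactors(tr)) {
      cm <- countsMatrix(f, h)
      # column sums equal group haplotype totals (direct recount)
      expect_identical(as.integer(colSums(cm)),
                       vapply(seq_len(f@nGroups), function(gp)
                         sum(f@groupOfRow == gp), integer(1L)))
      expect_identical(sum(cm), nrow(m))
    }
  }
})
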