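# shared small genetic base: 3-generation pedigree, 100 genotyped, 60 SNPs
base <- smallStudyBase()
Ag <- base$A
decomp <- kinshipDecomposition(Ag)

test_that("identity kinship gives the closed-form split and a flat ratio profile", {
  set.seed(31)
  y <- rnorm(60, mean = 3, sd = 2)
  fit <- remlFit(y, matrix(1, 60, 1, dimnames = list(NULL, "mu")),
                 A = diag(60))
  expect_true(fit@flatProfile)
  expect_equal(unname(fit@muHat), mean(y), tolerance = 1e-6)
  expect_equal(fit@sigma2a + fit@sigma2e, var(y), tolerance = 1e-5)
})

test_that("REML optimum beats a dense likelihood grid on a small dataset", {
  set.seed(32)
  ped <- randomPedigree(10, pFounder = 0.3)
  A <- computeA(ped)
  a <- simulatePolygenics(ped)[, 1L]
  x <- rbinom(10, 2L, 0.4)
  y <- 1 + 0.5 * x + a + rnorm(10, 0, 1)
  X <- cbind(mu = 1, x = x)
  fit <- remlFit(y, X, A = A)
  grid <- expand.grid(s2a = seq(0.05, 5, length.out = 100),
                      s2e = seq(0.05, 5, length.out = 100))
  gll <- mapply(function(a2, e2) denseREMLLoglik(y, X, A, a2, e2),
                grid$s2a, grid$s2e)
  expect_gte(fit@restrictedLoglik, max(gll) - 1e-6)
  # spectral-path likelihood agrees with the dense formula at the optimum
  expect_equal(fit@restrictedLoglik,
               denseREMLLoglik(y, X, A, max(fit@sigma2a, 1e-8),
                               fit@sigma2e),
               tolerance = 1e-4)
})

test_that("parameter recovery at moderate size is unbiased enough to use", {
  set.seed(33)
  h2hat <- replicate(30, {
    a <- simulatePolygenics(base$pedigree, F = base$F)[, 1L]
    ids <- individuals(base$hap)
    y <- 2 + a[ids] + rnorm(length(ids))
    fit <- remlFit(y, matrix(1, length(ids), 1), decomp = decomp)
    fit@sigma2a / (fit@sigma2a + fit@sigma2e)
  })
  expect_lt(abs(mean(h2hat) - 0.5), 3 * sd(h2hat) / sqrt(30))
})

test_that("Wald statistics follow the chi-square definition", {
  fit <- new("LMMFit", muHat = 0, bHat = c(h1 = 0),
             Vb = matrix(1, dimnames = list("h1", "h1")),
             sigma2a = 1, sigma2e = 1, lambda = 1, restrictedLoglik = 0,
             flatProfile = FALSE, n = 10L)
  w0 <- waldTest(fit)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)

  fit@bHat <- c(h1 = 2)
  w <- waldTest(fit)
  expect_equal(w$statistic, 4)
  expect_equal(w$df, 1L)
  expect_equal(w$p, 0.04550026, tolerance = 1e-6)  # chi2_1 upper tail at 4

  # singular covariance block is skipped with a reason
  fit2 <- new("LMMFit", muHat = 0, bHat = c(h1 = 1, h2 = 1),
              Vb = matrix(1, 2, 2, dimnames = list(c("h1", "h2"),
                                                   c("h1", "h2"))),
              sigma2a = 1, sigma2e = 1, lambda = 1, restrictedLoglik = 0,
              flatProfile = FALSE, n = 10L)
  ws <- waldTest(fit2)
  expect_true(is.na(ws$p))
  expect_match(ws$note, "singular")
})

test_that("a singular design errors naming the aliased columns", {
  set.seed(34)
  y <- rnorm(20)
  x <- rbinom(20, 2, 0.5)
  X <- cbind(mu = 1, h1 = x, h2 = x)
  expect_error(remlFit(y, X, A = diag(20)), "aliased.*h2")
  expect_error(remlFit(y, cbind(mu = 1, x = x), A = -diag(20)),
               "positive semi-definite")
})

test_that("with the ratio forced to zero the fit reduces to ordinary least squares", {
  set.seed(35)
  ids <- individuals(base$hap)
  n <- length(ids)
  x <- rbinom(n, 2, 0.3)
  y <- 1 + 0.3 * x + rnorm(n)
  fit <- remlFit(y, cbind(mu = 1, x = x), decomp = decomp, fixLambda = 0)
  ols <- summary(lm(y ~ x))
  expect_equal(unname(fit@bHat), unname(coef(ols)[2L, 1L]), tolerance = 1e-8)
  expect_equal(sqrt(fit@Vb[1L, 1L]), unname(coef(ols)[2L, 2L]),
               tolerance = 1e-8)
  w <- waldTest(fit)
  # Wald chi2_1 equals the squared OLS t statistic
  expect_equal(w$statistic, unname(coef(ols)[2L, 3L])^2, tolerance = 1e-8)
})

test_that("Wald results are invariant to relabelling the haplotype groups", {
  set.seed(36)
  hap <- base$hap
  n <- length(individuals(hap))
  facs <- genmixFactors(hap)
  # find a trisection with all groups informative
  cand <- NULL
  for (f in facs) for (k in seq_along(f$factors)) {
    cl <- f$factors[[k]]
    if (cl@nGroups == 3L && all(cl@groupCopies >= 4L)) { cand <- cl; break }
  }
  skip_if(is.null(cand), "no informative trisection in this base")
  a <- simulatePolygenics(base$pedigree, F = base$F)[, 1L]
  y <- a[individuals(hap)] + rnorm(n)
  run <- function(cl) {
    cm <- countsMatrix(cl, hap)
    des <- genmix:::clusteringDesign(cm, cl@groupCopies, cl@groupOfRow, 4L)
    fit <- remlFit(y, cbind(mu = 1, des$cols), decomp = decomp)
    waldTest(fit)
  }
  w1 <- run(cand)
  perm <- c(3L, 1L, 2L)
  cl2 <- new("FactorClustering", cutId = cand@cutId, nGroups = 3L,
             groupOfRow = perm[cand@groupOfRow],
             groupCopies = as.integer(tabulate(perm[cand@groupOfRow], 3L)))
  w2 <- run(cl2)
  expect_equal(w1$statistic, w2$statistic, tolerance = 1e-6)
  expect_identical(w1$df, w2$df)
})

test_that("genmix scan under the null shows no gross inflation and respects min-p bookkeeping", {
  set.seed(37)
  hap <- base$hap
  a <- simulatePolygenics(base$pedigree, F = base$F)[, 1L]
  ids <- individuals(hap)
  y <- data.frame(id = ids, y = a[ids] + rnorm(length(ids)))
  scan <- genmixScan(hap, y, Ag)
  s <- scanSummary(scan)
  t <- scanTests(scan)
  # min_p is the minimum over that SNP's performed tests
  for (snp in s$snpId[s$testsPerformed > 0]) {
    expect_equal(s$minP[s$snpId == snp],
                 min(t$p[t$snpId == snp], na.rm = TRUE))
  }
  # with up to 7 correlated tests per SNP the Sidak bound ~0.30 applies on
  # average; allow generous Monte-Carlo slack, reject only gross inflation
  frac <- mean(s$minP < 0.05, na.rm = TRUE)
  expect_lt(frac, 0.5)
})

test_that("a planted cluster effect puts the causal SNP at the genome-wide minimum p", {
  set.seed(38)
  hap <- base$hap
  facs <- genmixFactors(hap)
  j <- 30L
  cl <- facs[[j]]$factors[[1L]]          # root bisection at SNP 30
  cm <- facs[[j]]$counts[[1L]]
  target <- which.min(cl@groupCopies)    # dose of the rarer cluster
  y <- data.frame(id = individuals(hap),
                  y = 3 * cm[, target] + rnorm(nrow(cm), 0, 0.8))
  scan <- genmixScan(hap, y, Ag, factors = facs)
  s <- scanSummary(scan)
  expect_equal(s$minP[j], min(s$minP, na.rm = TRUE))
})

test_that("scans are deterministic and mma is invariant to allele coding", {
  set.seed(39)
  hap <- base$hap
  ids <- individuals(hap)
  a <- simulatePolygenics(base$pedigree, F = base$F)[, 1L]
  y <- data.frame(id = ids, y = a[ids] + rnorm(length(ids)))
  s1 <- mmaScan(hap, y, Ag)
  s2 <- mmaScan(hap, y, Ag)
  expect_identical(scanTests(s1), scanTests(s2))
  g1 <- genmixScan(hap, y, Ag)
  g2 <- genmixScan(hap, y, Ag)
  expect_identical(scanTests(g1), scanTests(g2))

  # flip alleles at one site: identical p
  hap2 <- hap
  hap2@alleles[, 5L] <- 1L - hap2@alleles[, 5L]
  s3 <- mmaScan(hap2, y, Ag)
  expect_equal(scanTests(s3)$p[5L], scanTests(s1)$p[5L], tolerance = 1e-8)
})

test_that("mma p-values are uniform under a permutation null", {
  set.seed(40)
  nInd <- 80L
  hap <- randomHapData(nInd, 1000L)
  ped <- newPedigree(individuals(hap), rep(NA, nInd), rep(NA, nInd))
  a <- rnorm(nInd)                       # founders only: A = I
  yperm <- sample(a + rnorm(nInd))       # permuted phenotypes
  scan <- mmaScan(hap, data.frame(id = individuals(hap), y = yperm),
                  diag(nInd))
  p <- scanTests(scan)$p
  expect_gte(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("individuals without genotypes are dropped and A is subset by id", {
  set.seed(41)
  hap <- base$hap
  ids <- individuals(hap)
  a <- simulatePolygenics(base$pedigree, F = base$F)[, 1L]
  y <- data.frame(id = c(ids, "ghost"), y = c(a[ids] + rnorm(length(ids)), 5))
  Afull <- computeA(base$pedigree)
  s1 <- mmaScan(hap, y, Afull)           # phenotyped-but-ungenotyped dropped
  s2 <- mmaScan(hap, y[y$id != "ghost", ], Ag)
  expect_equal(scanTests(s1)$p, scanTests(s2)$p, tolerance = 1e-10)
})
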