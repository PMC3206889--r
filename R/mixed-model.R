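#' Spectral decomposition of a relationship matrix
#'
#' One symmetric eigendecomposition of A (restricted to the analysis set)
#' is computed per dataset and reused across all SNP fits.  Small negative
#' eigenvalues within tolerance are clamped to zero; anything more negative
#' is a non-PSD error.
#'
#' @param A symmetric relationship matrix.
#' @param tol PSD tolerance relative to the largest eigenvalue.
#' @return list(U, d) with A = U diag(d) U'.
#' @export
kinshipDecomposition <- function(A, tol = 1e-8) {
  if (!isSymmetric(unname(A), tol = 1e-10))
    stop("relationship matrix is not symmetric")
  e <- eigen(A, symmetric = TRUE)
  lim <- -tol * max(abs(e$values), 1)
  if (any(e$values < lim))
    stop("relationship matrix is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(e$values)), ")")
  list(U = e$vectors, d = pmax(e$values, 0), ids = rownames(A))
}

#' REML fit of the pedigree-based linear mixed model
#'
#' Fits `y = mu + X b + a + e` with `Var(a) = A sigma2a` (A the numerator
#' relationship matrix over the phenotyped individuals) and
#' `Var(e) = sigma2e I` by restricted maximum likelihood.  The restricted
#' likelihood is profiled over the variance ratio
#' `lambda = sigma2a / sigma2e` after one spectral decomposition of A
#' (reusable across SNPs via `decomp`), using a bounded golden-section
#' search on log(lambda) to relative tolerance `tol`.  Fixed effects are
#' the GLS estimates at the optimum and `Vb` the corresponding block of the
#' inverse GLS information.
#'
#' @param y numeric phenotype vector.
#' @param X design matrix including the intercept as first column; 0-2
#'   further columns of haplotype/SNP counts.
#' @param A relationship matrix over the phenotyped individuals (ignored
#'   when `decomp` is given).
#' @param decomp optional precomputed [kinshipDecomposition()].
#' @param fixLambda optional non-negative value at which to fix the
#'   variance ratio (0 gives the ordinary least-squares limit).
#' @param tol relative tolerance of the ratio search.
#' @param bounds search range for lambda.
#' @return an [LMMFit-class]; `flatProfile` is set when the restricted
#'   likelihood does not depend on the ratio (e.g. identity kinship), in
#'   which case only `sigma2a + sigma2e` is identified.
#' @export
remlFit <- function(y, X, A = NULL, decomp = NULL, fixLambda = NULL,
                    tol = 1e-8, bounds = c(1e-6, 1e6)) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(is.finite(y)))
  if (is.null(decomp)) {
    if (is.null(A)) stop("either A or decomp must be supplied")
    stopifnot(nrow(A) == n)
    decomp <- kinshipDecomposition(A)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[-seq_len(q$rank)]]
    stop("design is singular; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  Xt <- crossprod(decomp$U, X)
  yt <- as.vector(crossprod(decomp$U, y))
  fit <- .reml_profile_cpp(Xt, yt, decomp$d,
                           if (is.null(fixLambda)) -1 else fixLambda,
                           bounds[1L], bounds[2L], tol)
  beta <- as.vector(fit$beta)
  names(beta) <- colnames(X)
  free <- setdiff(seq_along(beta), 1L)
  Vb <- fit$vb[free, free, drop = FALSE]
  dimnames(Vb) <- list(names(beta)[free], names(beta)[free])
  new("LMMFit",
      muHat = beta[1L],
      bHat = beta[free],
      Vb = Vb,
      sigma2a = fit$sigma2a,
      sigma2e = fit$sigma2e,
      lambda = fit$lambda,
      restrictedLoglik = fit$loglik,
      flatProfile = fit$flat,
      n = as.integer(n))
}

#' Restricted log-likelihood at given variance components
#'
#' Direct dense evaluation of the REML criterion
#' `-1/2 [log|V| + log|X'V^-1 X| + y'Py + (n-p) log 2 pi]` with
#' `V = sigma2a A + sigma2e I`; same constant convention as [remlFit()].
#' Mainly for diagnostics and likelihood-surface checks.
#'
#' @inheritParams remlFit
#' @param sigma2a,sigma2e variance components (> 0).
#' @return scalar restricted log-likelihood.
#' @export
remlLoglik <- function(y, X, A, sigma2a, sigma2e) {
  n <- length(y); p <- ncol(X)
  V <- sigma2a * A + diag(sigma2e, n)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(crossprod(y, P %*% y)) + (n - p) * log(2 * pi))
}

#' Wald chi-square test of haplotype or SNP coefficients
#'
#' Tests H0: b = 0 for the selected free coefficients of an [LMMFit-class]
#' via `W = b' Vb^-1 b`, asymptotically chi-square with f = number of
#' tested coefficients (f = 1 for a bisection or single SNP, f = 2 for a
#' trisection).
#'
#' @param fit an [LMMFit-class].
#' @param tested indices into `fit@bHat` (default: all free coefficients).
#' @return list(statistic, df, p, note); on a singular Vb block the test is
#'   skipped (`p = NA`) with the reason in `note`.
#' @export
waldTest <- function(fit, tested = seq_along(fit@bHat)) {
  b <- fit@bHat[tested]
  V <- fit@Vb[tested, tested, drop = FALSE]
  f <- length(b)
  if (f == 0L)
    return(list(statistic = NA_real_, df = 0L, p = NA_real_,
                note = "no free coefficients"))
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || !all(is.finite(Vi)))
    return(list(statistic = NA_real_, df = f, p = NA_real_,
                note = "singular coefficient covariance"))
  stat <- drop(crossprod(b, Vi %*% b))
  list(statistic = stat, df = f,
       p = pchisq(stat, df = f, lower.tail = FALSE), note = "")
}

# Free design columns for one clustering under the largest-baseline rule.
# Groups with fewer than minGroupCopies haplotype copies are dropped from
# testing; if < 2 informative groups remain the factor is skipped.  The
# baseline (implied) group is the informative group with the most copies,
# ties broken by the smallest member row index (label-invariant).
clusteringDesign <- function(counts, groupCopies, groupOfRow,
                             minGroupCopies = 4L) {
  informative <- which(groupCopies >= minGroupCopies)
  if (length(informative) < 2L)
    return(list(cols = NULL, note = "fewer than 2 informative groups"))
  minRow <- vapply(informative, function(g)
    min(which(groupOfRow == g)), integer(1L))
  base <- informative[order(-groupCopies[informative], minRow)][1L]
  free <- setdiff(informative, base)
  cols <- counts[, free, drop = FALSE]
  colnames(cols) <- paste0("h", seq_along(free))
  list(cols = cols, note = "")
}

#' GENMIX genome scan
#'
#' For each SNP: grow the maximal four-gamete-compatible interval, build
#' the perfect-phylogeny gene tree, cut it into up to seven haplotype
#' clusterings, and test each clustering as a fixed effect in the pedigree
#' mixed model.  For a bisection one group count enters the model (b2
#' constrained to 0, f = 1); for a trisection the counts of the two
#' non-baseline groups enter (f = 2).  Variance components are re-estimated
#' by full REML for every test unless `p3d = TRUE`, which estimates the
#' ratio once under the no-SNP null model and reuses it.  The per-SNP
#' minimum p over its performed tests is the QTL-SNP association measure.
#'
#' @param hap [HaplotypeData-class] of the analysis individuals.
#' @param y phenotype vector or data.frame(id, y); individuals with
#'   phenotype but no genotype are dropped.
#' @param A numerator relationship matrix covering at least the analysis
#'   individuals (subset, not re-derived).
#' @param minGroupCopies groups below this many haplotype copies are not
#'   tested (default 4).
#' @param p3d reuse the null-model variance ratio across SNPs.
#' @param factors optional precomputed [genmixFactors()] output.
#' @param tol REML ratio tolerance.
#' @return a [ScanResult-class] (method "genmix").
#' @export
genmixScan <- function(hap, y, A, minGroupCopies = 4L, p3d = FALSE,
                       factors = NULL, tol = 1e-8) {
  prep <- alignScanInputs(hap, y, A)
  hap <- prep$hap; yv <- prep$y; dec <- prep$decomp
  n <- length(yv)
  if (is.null(factors)) factors <- genmixFactors(hap)
  fixL <- NULL
  if (p3d) {
    null <- remlFit(yv, matrix(1, n, 1, dimnames = list(NULL, "mu")),
                    decomp = dec, tol = tol)
    fixL <- null@lambda
  }
  rows <- vector("list", ncol(hap@alleles))
  for (j in seq_along(factors)) {
    fj <- factors[[j]]
    recs <- lapply(seq_along(fj$factors), function(k) {
      cl <- fj$factors[[k]]
      des <- clusteringDesign(fj$counts[[k]], cl@groupCopies,
                              cl@groupOfRow, minGroupCopies)
      if (is.null(des$cols))
        return(data.frame(testId = cl@cutId, df = NA_integer_,
                          statistic = NA_real_, p = NA_real_,
                          note = des$note))
      X <- cbind(mu = 1, des$cols)
      keep <- c(TRUE, apply(des$cols, 2L, function(v) var(v) > 0))
      X <- X[, keep, drop = FALSE]
      if (ncol(X) < 2L)
        return(data.frame(testId = cl@cutId, df = NA_integer_,
                          statistic = NA_real_, p = NA_real_,
                          note = "no variation in group counts"))
      if (qr(X)$rank < ncol(X))
        return(data.frame(testId = cl@cutId, df = NA_integer_,
                          statistic = NA_real_, p = NA_real_,
                          note = "aliased group counts"))
      fit <- remlFit(yv, X, decomp = dec, fixLambda = fixL, tol = tol)
      w <- waldTest(fit)
      data.frame(testId = cl@cutId, df = w$df, statistic = w$statistic,
                 p = w$p, note = w$note)
    })
    if (!length(recs))
      recs <- list(data.frame(testId = NA_integer_, df = NA_integer_,
                              statistic = NA_real_, p = NA_real_,
                              note = "no valid clustering"))
    rows[[j]] <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
    rows[[j]]$snpId <- hap@snpIds[j]
    rows[[j]]$bp <- hap@positions[j]
  }
  assembleScan("genmix", rows, hap)
}

#' Unified mixed model (single-SNP) genome scan
#'
#' The comparator analysis: each SNP's minor-allele count (0/1/2) enters
#' the pedigree mixed model as one fixed covariate and is Wald-tested with
#' f = 1 against H0: alpha = 0.
#'
#' @inheritParams genmixScan
#' @return a [ScanResult-class] (method "mma").
#' @export
mmaScan <- function(hap, y, A, p3d = FALSE, tol = 1e-8) {
  prep <- alignScanInputs(hap, y, A)
  hap <- prep$hap; yv <- prep$y; dec <- prep$decomp
  n <- length(yv)
  fixL <- NULL
  if (p3d) {
    null <- remlFit(yv, matrix(1, n, 1, dimnames = list(NULL, "mu")),
                    decomp = dec, tol = tol)
    fixL <- null@lambda
  }
  al <- hap@alleles
  rows <- vector("list", ncol(al))
  for (j in seq_len(ncol(al))) {
    g <- al[seq(1L, 2L * n, 2L), j] + al[seq(2L, 2L * n, 2L), j]
    f <- mean(g) / 2
    if (f > 0.5) g <- 2L - g  # minor-allele coding
    if (var(g) == 0) {
      rows[[j]] <- data.frame(testId = "mma", df = NA_integer_,
                              statistic = NA_real_, p = NA_real_,
                              note = "monomorphic in analysis set",
                              snpId = hap@snpIds[j], bp = hap@positions[j])
      next
    }
    fit <- remlFit(yv, cbind(mu = 1, snp = g), decomp = dec,
                   fixLambda = fixL, tol = tol)
    w <- waldTest(fit)
    rows[[j]] <- data.frame(testId = "mma", df = w$df,
                            statistic = w$statistic, p = w$p, note = w$note,
                            snpId = hap@snpIds[j], bp = hap@positions[j])
  }
  assembleScan("mma", rows, hap)
}

# Align haplotypes, phenotypes and A to the common analysis set; one
# eigendecomposition for the whole scan.
alignScanInputs <- function(hap, y, A) {
  if (is.data.frame(y)) {
    ids <- as.character(y[[1L]])
    yv <- as.numeric(y[[2L]])
  } else {
    yv <- as.numeric(y)
    ids <- names(y)
    if (is.null(ids)) {
      if (length(yv) != length(hap@individualIds))
        stop("unnamed phenotype vector must match the genotyped individuals")
      ids <- hap@individualIds
    }
  }
  keep <- ids %in% hap@individualIds
  ids <- ids[keep]; yv <- yv[keep]
  if (!length(ids)) stop("no phenotyped individual has genotypes")
  sel <- match(ids, hap@individualIds)
  rowSel <- as.vector(rbind(2L * sel - 1L, 2L * sel))
  hap2 <- new("HaplotypeData", alleles = hap@alleles[rowSel, , drop = FALSE],
              positions = hap@positions, snpIds = hap@snpIds,
              individualIds = ids)
  if (is.null(rownames(A))) {
    if (nrow(A) != length(ids))
      stop("A has no dimnames and does not match the analysis set")
    Asub <- A
  } else {
    miss <- setdiff(ids, rownames(A))
    if (length(miss))
      stop("individuals missing from A: ",
           paste(head(miss, 5L), collapse = ", "))
    Asub <- A[ids, ids]
  }
  list(hap = hap2, y = yv, decomp = kinshipDecomposition(Asub))
}

assembleScan <- function(method, rows, hap) {
  tests <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tests <- tests[, c("snpId", "bp", "testId", "df", "statistic", "p",
                     "note")]
  snps <- do.call(rbind, lapply(split(tests, factor(tests$snpId,
                                                    levels = hap@snpIds)),
                                function(d) {
    ok <- !is.na(d$p)
    data.frame(snpId = d$snpId[1L], bp = d$bp[1L],
               minP = if (any(ok)) min(d$p[ok]) else NA_real_,
               testsPerformed = sum(ok))
  }))
  rownames(snps) <- NULL
  new("ScanResult", method = method, tests = tests, snps = snps)
}

#' Write scan results as TSV
#'
#' One row per test: snp_id, bp, test_id, statistic, df, p, min_p_flag,
#' tests_performed.
#'
#' @param scan a [ScanResult-class].
#' @param path output file.
#' @export
writeScanResult <- function(scan, path) {
  t <- scan@tests
  s <- scan@snps[match(t$snpId, scan@snps$snpId), ]
  out <- data.frame(snp_id = t$snpId, bp = t$bp, test_id = t$testId,
                    statistic = t$statistic, df = t$df, p = t$p,
                    min_p_flag = as.integer(!is.na(t$p) & t$p == s$minP),
                    tests_performed = s$testsPerformed)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
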