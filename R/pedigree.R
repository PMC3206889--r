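#' Construct a Pedigree from id/sire/dam vectors
#'
#' Records may arrive in any order; parents referenced but not listed are
#' inserted as founders, and the result is topologically sorted so every
#' parent precedes its offspring.  Input order is preserved as far as the
#' sort allows (stable Kahn ordering).
#'
#' @param id,sire,dam character vectors; `NA` marks an unknown parent.
#' @return a [Pedigree-class]
#' @export
newPedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  if (anyDuplicated(id))
    stop("duplicate individual id: ", id[duplicated(id)][1L])
  parents <- setdiff(c(sire, dam), c(id, NA_character_))
  if (length(parents)) {
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(id)
  pos <- seq_len(n); names(pos) <- id
  si <- ifelse(is.na(sire), 0L, pos[sire])
  di <- ifelse(is.na(dam), 0L, pos[dam])

  # stable Kahn topological sort; cycle detection
  nchild <- integer(n)
  childL <- vector("list", n)
  for (i in seq_len(n)) for (p in c(si[i], di[i])) if (p > 0L)
    childL[[p]] <- c(childL[[p]], i)
  indeg <- (si > 0L) + (di > 0L)
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    i <- ready[1L]; ready <- ready[-1L]
    order <- c(order, i)
    for (ch in childL[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- setdiff(seq_len(n), order)
    stop("cycle in parentage involving individual ", id[on_cycle[1L]])
  }
  new("Pedigree", id = id[order], sire = sire[order], dam = dam[order])
}

#' Read a pedigree file
#'
#' Whitespace- or tab-delimited text with at least three columns:
#' individual, sire, dam.  A header row is auto-detected (any field of the
#' first row matching id/individual/animal/sire/dam, case-insensitively)
#' unless `header` is given explicitly.
#'
#' @param path file path.
#' @param unknownCode string coding an unknown parent (default "0").
#' @param sep field separator passed to [read.table()] ("" = whitespace).
#' @param header TRUE/FALSE, or "auto".
#' @return a topologically sorted [Pedigree-class]; absent parents are
#'   inserted as founders.
#' @export
readPedigree <- function(path, unknownCode = "0", sep = "", header = "auto") {
  if (identical(header, "auto")) {
    first <- scan(path, what = character(), nlines = 1L, quiet = TRUE,
                  sep = if (nzchar(sep)) sep else "")
    header <- any(tolower(first) %in%
                    c("id", "individual", "animal", "sire", "dam", "father",
                      "mother"))
  }
  d <- read.table(path, header = header, sep = sep,
                  colClasses = "character", comment.char = "")
  if (ncol(d) < 3L) stop("pedigree file needs >= 3 columns (id, sire, dam)")
  unk <- function(x) ifelse(x == unknownCode, NA_character_, x)
  newPedigree(d[[1L]], unk(d[[2L]]), unk(d[[3L]]))
}

parentIndices <- function(ped) {
  pos <- seq_along(ped@id); names(pos) <- ped@id
  list(s = ifelse(is.na(ped@sire), 0L, pos[ped@sire]),
       d = ifelse(is.na(ped@dam), 0L, pos[ped@dam]))
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes the additive (numerator) relationship matrix A over all
#' pedigree members by the recursive tabular method: founders have
#' `A_ii = 1` and are unrelated to earlier individuals; for an individual
#' with parents s and d, `A_ii = 1 + A_sd / 2` and
#' `A_ij = (A_js + A_jd) / 2` for earlier j, an unknown parent contributing
#' zero.  `A` is the polygenic covariance structure of the mixed model:
#' `Var(a) = A * sigma2a`.
#'
#' @param ped a topologically sorted [Pedigree-class].
#' @return symmetric numeric matrix with dimnames = individual ids.
#' @export
computeA <- function(ped) {
  stopifnot(is(ped, "Pedigree"))
  validObject(ped)  # guarantees topological order
  n <- length(ped@id)
  pi <- parentIndices(ped)
  s <- pi$s; d <- pi$d
  A <- matrix(0, n, n, dimnames = list(ped@id, ped@id))
  for (i in seq_len(n)) {
    vs <- if (s[i] > 0L) A[seq_len(i - 1L), s[i]] else numeric(i - 1L)
    vd <- if (d[i] > 0L) A[seq_len(i - 1L), d[i]] else numeric(i - 1L)
    if (i > 1L) {
      v <- 0.5 * (vs + vd)
      A[seq_len(i - 1L), i] <- v
      A[i, seq_len(i - 1L)] <- v
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' `F_i = A_ii - 1` from the tabular-method relationship matrix; founders
#' have F = 0.
#'
#' @inheritParams computeA
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  diag(computeA(ped)) - 1
}

#' Export a relationship matrix as TSV
#'
#' Debug convenience: writes A with a leading id column and id header.
#'
#' @param A matrix from [computeA()].
#' @param path output file.
#' @export
writeA <- function(A, path) {
  d <- data.frame(id = rownames(A), A, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
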