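#' Construct HaplotypeData from components
#'
#' @param alleles 0/1 matrix, two consecutive rows per individual.
#' @param positions bp per site (strictly increasing).
#' @param snpIds marker ids (default snp1..snpM).
#' @param individualIds one id per individual.
#' @return a [HaplotypeData-class]
#' @export
newHaplotypeData <- function(alleles, positions,
                             snpIds = paste0("snp", seq_len(ncol(alleles))),
                             individualIds =
                               paste0("ind", seq_len(nrow(alleles) / 2))) {
  storage.mode(alleles) <- "integer"
  dimnames(alleles) <- NULL
  new("HaplotypeData", alleles = alleles, positions = as.numeric(positions),
      snpIds = as.character(snpIds),
      individualIds = as.character(individualIds))
}

#' Remove sites below a minor allele frequency threshold
#'
#' Applied at load time; sites with MAF below the threshold (default 0.05)
#' are omitted from all downstream analyses.
#'
#' @param hap a [HaplotypeData-class].
#' @param threshold minimum minor allele frequency kept.
#' @return filtered [HaplotypeData-class].
#' @export
filterMAF <- function(hap, threshold = 0.05) {
  keep <- mafs(hap) >= threshold
  new("HaplotypeData", alleles = hap@alleles[, keep, drop = FALSE],
      positions = hap@positions[keep], snpIds = hap@snpIds[keep],
      individualIds = hap@individualIds)
}

#' Read / write the simple hap/map text pair
#'
#' The hap file holds one row per phased haplotype (0/1 alleles, whitespace
#' separated), two consecutive rows per individual, with the individual id
#' in the first column.  The map file has columns snp id, chromosome, bp.
#'
#' @param hapPath,mapPath file paths.
#' @param mafThreshold minor-allele-frequency filter applied after loading
#'   (NULL disables).
#' @return [readHapMap()] a [HaplotypeData-class].
#' @export
readHapMap <- function(hapPath, mapPath, mafThreshold = 0.05) {
  map <- read.table(mapPath, header = FALSE,
                    col.names = c("snp", "chr", "bp"),
                    colClasses = c("character", "character", "numeric"))
  h <- read.table(hapPath, header = FALSE, colClasses = "character")
  ids <- h[[1L]]
  al <- as.matrix(h[, -1L])
  storage.mode(al) <- "integer"
  if (nrow(al) %% 2L != 0L) stop("hap file must have two rows per individual")
  odd <- ids[seq(1L, nrow(al), 2L)]
  if (!identical(odd, ids[seq(2L, nrow(al), 2L)]))
    stop("consecutive haplotype rows must share an individual id")
  hap <- newHaplotypeData(al, map$bp, map$snp, odd)
  if (!is.null(mafThreshold)) hap <- filterMAF(hap, mafThreshold)
  hap
}

#' @rdname readHapMap
#' @param hap a [HaplotypeData-class] to write.
#' @param chrom chromosome label for the map file.
#' @export
writeHapMap <- function(hap, hapPath, mapPath, chrom = "1") {
  ids <- rep(hap@individualIds, each = 2L)
  write.table(data.frame(ids, hap@alleles), hapPath, sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(hap@snpIds, chrom, format(hap@positions,
                                                   scientific = FALSE,
                                                   trim = TRUE)),
              mapPath, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(hapPath)
}

#' Read phased haplotypes from a VCF
#'
#' Requires phased genotypes (`|` separator); an unphased `/` call is an
#' error, as local genealogies need resolved linkage phase.
#'
#' @param path VCF path (uncompressed or gz).
#' @param mafThreshold minor-allele-frequency filter (NULL disables).
#' @return a [HaplotypeData-class].
#' @export
readPhasedVcf <- function(path, mafThreshold = 0.05) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotypes ('/') in VCF; phased input ('|') is required")
  if (!all(gt %in% c("0|0", "0|1", "1|0", "1|1")))
    stop("only biallelic phased diploid genotypes are supported")
  nInd <- ncol(gt); m <- nrow(gt)
  h1 <- matrix(as.integer(substr(gt, 1L, 1L)), m, nInd)
  h2 <- matrix(as.integer(substr(gt, 3L, 3L)), m, nInd)
  al <- matrix(0L, 2L * nInd, m)
  al[seq(1L, 2L * nInd, 2L), ] <- t(h1)
  al[seq(2L, 2L * nInd, 2L), ] <- t(h2)
  pos <- as.numeric(vcfR::getPOS(v))
  ids <- vcfR::getID(v)
  if (anyNA(ids)) ids <- paste0("snp", seq_len(m))
  o <- order(pos)
  hap <- newHaplotypeData(al[, o, drop = FALSE], pos[o], ids[o],
                          colnames(gt))
  if (!is.null(mafThreshold)) hap <- filterMAF(hap, mafThreshold)
  hap
}

#' Write phased haplotypes as a minimal VCF
#'
#' @param hap a [HaplotypeData-class].
#' @param path output path.
#' @param chrom chromosome label.
#' @export
writePhasedVcf <- function(hap, path, chrom = "1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", hap@individualIds),
                     collapse = "\t")), con)
  a1 <- hap@alleles[seq(1L, nrow(hap@alleles), 2L), , drop = FALSE]
  a2 <- hap@alleles[seq(2L, nrow(hap@alleles), 2L), , drop = FALSE]
  for (j in seq_len(ncol(hap@alleles))) {
    gt <- paste0(a1[, j], "|", a2[, j])
    writeLines(paste(c(chrom, format(hap@positions[j], scientific = FALSE),
                       hap@snpIds[j], "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Two or more tab/whitespace separated columns: individual id and trait
#' value; extra columns (true simulation components) are preserved.
#'
#' @param path file path.
#' @return data.frame with at least columns id and y.
#' @export
readPhenotypes <- function(path) {
  d <- read.table(path, header = TRUE)
  names(d)[1:2] <- c("id", "y")
  d$id <- as.character(d$id)
  d
}

#' @rdname readPhenotypes
#' @param phen data.frame(id, y, ...).
#' @export
writePhenotypes <- function(phen, path) {
  write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pedigree as 3-column TSV
#'
#' @param ped a [Pedigree-class].
#' @param path output file.
#' @param unknownCode code written for unknown parents.
#' @export
writePedigree <- function(ped, path, unknownCode = "0") {
  fill <- function(x) ifelse(is.na(x), unknownCode, x)
  write.table(data.frame(id = ped@id, sire = fill(ped@sire),
                         dam = fill(ped@dam)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
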