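## Genotype I/O: VCF through VariantAnnotation, PLINK bed/bim/fam through a
## small 2-bit codec (no PLINK reader ships with the imaging stack here).
## Internal genotype codes count copies of the a2 allele (ALT for VCF, the
## second .bim allele for PLINK); missing stays NA.

#' Read genotypes into the internal model
#'
#' @param path for `format = "vcf"` a VCF 4.x file; for `format = "plink"` the
#'   prefix of a bed/bim/fam trio (with or without the `.bed` extension).
#' @param format `"vcf"` or `"plink"`.
#' @param fam optional path to a PLINK-style fam file supplying pedigree IDs
#'   when reading VCF (column 1 = family ID, column 2 = sample ID). When
#'   absent, each VCF sample becomes its own singleton pedigree.
#' @param sort_positions sort SNPs by (chromosome, position) if the file is
#'   unsorted (`TRUE`, default) or reject it (`FALSE`).
#' @return A [genotype_matrix()]. Multi-allelic and non-SNP VCF records are
#'   dropped with a logged count.
#' @export
read_genotypes <- function(path, format = c("vcf", "plink"), fam = NULL,
                           sort_positions = TRUE) {
  format <- match.arg(format)
  switch(format,
         vcf = read_genotypes_vcf(path, fam = fam, sort_positions = sort_positions),
         plink = read_genotypes_plink(path, sort_positions = sort_positions))
}

read_genotypes_vcf <- function(path, fam = NULL, sort_positions = TRUE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stopf("VCF support needs the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    log_stage("read_genotypes", dropped_non_biallelic_snv = n_drop)
  vcf <- vcf[keep, ]
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stopf("VCF has no GT field")
  codes <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  gtc <- gsub("|", "/", gt, fixed = TRUE)
  codes[gtc %in% c("0/0")] <- 0L
  codes[gtc %in% c("0/1", "1/0")] <- 1L
  codes[gtc %in% c("1/1")] <- 2L
  snp_map <- data.frame(
    id = rownames(gt),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    a1 = as.character(rr$REF),
    a2 = vapply(rr$ALT, function(a) as.character(a)[1], ""),
    stringsAsFactors = FALSE)
  samples <- colnames(gt)
  if (!is.null(fam)) {
    fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
    ped <- setNames(as.character(fam_df[[1]]), as.character(fam_df[[2]]))
    miss <- setdiff(samples, names(ped))
    if (length(miss))
      stopf("samples absent from fam file: %s", paste(miss, collapse = ", "))
    pedigree <- unname(ped[samples])
  } else {
    pedigree <- samples
  }
  build_genotype_matrix(t(codes), snp_map, samples, pedigree, sort_positions)
}

## Shared tail of the readers: optional (chrom, pos) sort, then validation.
build_genotype_matrix <- function(geno, snp_map, samples, pedigree, sort_positions) {
  o <- order(snp_map$chrom, snp_map$pos)
  if (!identical(o, seq_len(nrow(snp_map)))) {
    if (!sort_positions) stopf("SNP positions not sorted; set sort_positions = TRUE")
    snp_map <- snp_map[o, , drop = FALSE]
    geno <- geno[, o, drop = FALSE]
    rownames(snp_map) <- NULL
  }
  dup <- duplicated(snp_map[c("chrom", "pos")])
  if (any(dup)) {
    log_stage("read_genotypes", dropped_duplicate_position = sum(dup))
    snp_map <- snp_map[!dup, , drop = FALSE]
    geno <- geno[, !dup, drop = FALSE]
  }
  genotype_matrix(geno, snp_map, samples, pedigree)
}

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_genotypes_plink <- function(path, sort_positions = TRUE) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stopf("no such file: %s", f)
  bim_df <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                       col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam_df <- read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n_snp <- nrow(bim_df)
  n_ind <- nrow(fam_df)
  con <- file(bed, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stopf("%s is not a SNP-major PLINK bed file", bed)
  bpp <- ceiling(n_ind / 4)
  raw <- readBin(con, "raw", bpp * n_snp)
  if (length(raw) < bpp * n_snp) stopf("truncated bed file: %s", bed)
  bits <- matrix(as.integer(rawToBits(raw)), nrow = 8)
  ## 2-bit pairs, sample-fastest within each SNP block; pair value
  ## low + 2*high: 0 = hom a1, 1 = missing, 2 = het, 3 = hom a2.
  pair <- bits[c(TRUE, FALSE), ] + 2L * bits[c(FALSE, TRUE), ]
  pair <- matrix(pair, nrow = 4 * bpp)[seq_len(n_ind), , drop = FALSE]
  decode <- c(0L, NA_integer_, 1L, 2L)
  geno <- matrix(decode[pair + 1L], nrow = n_ind, ncol = n_snp)
  snp_map <- bim_df[c("id", "chrom", "pos", "a1", "a2")]
  snp_map$chrom <- as.character(snp_map$chrom)
  build_genotype_matrix(geno, snp_map,
                        samples = as.character(fam_df[[2]]),
                        pedigree = as.character(fam_df[[1]]),
                        sort_positions = sort_positions)
}

#' Write a genotype matrix as a PLINK bed/bim/fam trio
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_ind <- length(gm$samples)
  n_snp <- nrow(gm$snp_map)
  fam <- data.frame(gm$pedigree, gm$samples, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$snp_map$chrom, gm$snp_map$id, 0L, gm$snp_map$pos,
                    gm$snp_map$a1 %||% "A", gm$snp_map$a2 %||% "B")
  write.table(bim, paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ## encode: code 0 -> bits 00, het -> 10, code 2 -> 11, NA -> 01
  enc_low <- c(0L, 0L, 1L)   # low bit by code+1
  enc_high <- c(0L, 1L, 1L)
  bpp <- ceiling(n_ind / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * bpp - n_ind
  for (j in seq_len(n_snp)) {
    g <- gm$genotypes[, j]
    low <- ifelse(is.na(g), 1L, enc_low[g + 1L])
    high <- ifelse(is.na(g), 0L, enc_high[g + 1L])
    bits <- rbind(c(low, rep(0L, pad)), c(high, rep(0L, pad)))
    writeBin(packBits(as.integer(bits), "raw"), con)
  }
  invisible(prefix)
}

#' Write a genotype matrix as a plain-text VCF 4.2 file
#'
#' Pedigree IDs are not representable in VCF; write them separately with
#' [write_plink()] or keep the fam sidecar.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hdscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  m <- gm$genotypes
  body <- vapply(seq_len(ncol(m)), function(j) {
    g <- m[, j]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(gm$snp_map$chrom[j], gm$snp_map$pos[j], gm$snp_map$id[j],
            gm$snp_map$a1[j] %||% "A", gm$snp_map$a2[j] %||% "C",
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}
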