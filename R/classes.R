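## Internal data model. Plain S3 containers in the style of classic genetics
## packages: a list with a validated structure and a class attribute.

#' Construct a genotype matrix container
#'
#' Bundles an individuals-by-SNP matrix of additive genotype codes with its
#' SNP map and sample/pedigree labels, validating the invariants every
#' downstream stage relies on.
#'
#' @param genotypes integer matrix, individuals in rows and SNPs in columns;
#'   entries in `{0, 1, 2, NA}` counting copies of the alternate (a2) allele.
#' @param snp_map data frame with columns `id`, `chrom`, `pos` (bp, 1-based),
#'   `a1`, `a2`; one row per genotype column, positions strictly increasing
#'   within each chromosome.
#' @param samples character vector of sample IDs (row names of `genotypes`).
#' @param pedigree character vector of pedigree/family IDs, one per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, snp_map, samples, pedigree) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (ncol(genotypes) != nrow(snp_map))
    stopf("genotype columns (%d) != snp_map rows (%d)", ncol(genotypes), nrow(snp_map))
  if (nrow(genotypes) != length(samples))
    stopf("genotype rows (%d) != number of samples (%d)", nrow(genotypes), length(samples))
  if (length(pedigree) != length(samples))
    stopf("every sample needs a pedigree ID (%d samples, %d IDs)",
          length(samples), length(pedigree))
  if (anyNA(pedigree)) stopf("missing pedigree IDs are not allowed")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stopf("genotype codes must be in {0,1,2,NA}")
  need <- c("id", "chrom", "pos")
  if (!all(need %in% names(snp_map)))
    stopf("snp_map must have columns %s", paste(need, collapse = ", "))
  for (ch in unique(snp_map$chrom)) {
    p <- snp_map$pos[snp_map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stopf("positions not strictly increasing on chromosome %s", ch)
  }
  rownames(genotypes) <- samples
  colnames(genotypes) <- snp_map$id
  structure(list(genotypes = genotypes,
                 snp_map = as.data.frame(snp_map),
                 samples = as.character(samples),
                 pedigree = as.character(pedigree)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs on %d chromosome(s), %d pedigrees\n",
              length(x$samples), nrow(x$snp_map),
              length(unique(x$snp_map$chrom)), length(unique(x$pedigree))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Validate and type a phenotype table
#'
#' @param df data frame with one row per sample and columns `sample`, `pedigree`,
#'   `tg1`..`tg4` (triglyceride mg/dL per visit; `NA` allowed), `sex`, `age`,
#'   `center`, `smoking`, `atp`, `idf`.
#' @return The validated data frame with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df) {
  need <- c("sample", "pedigree", paste0("tg", 1:4),
            "sex", "age", "center", "smoking", "atp", "idf")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("phenotype table missing columns: %s", paste(miss, collapse = ", "))
  for (v in paste0("tg", 1:4)) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(df[[v]] < 0, na.rm = TRUE)) stopf("negative TG in column %s", v)
  }
  for (v in c("sex", "smoking", "atp", "idf")) {
    bad <- setdiff(unique(df[[v]][!is.na(df[[v]])]), c(0, 1))
    if (length(bad)) stopf("column %s has levels outside {0,1}: %s", v,
                           paste(bad, collapse = ", "))
    df[[v]] <- as.integer(df[[v]])
  }
  df$age <- as.numeric(df$age)
  df$center <- as.character(df$center)
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stopf("duplicate sample IDs in phenotype table")
  class(df) <- c("phenotype_table", class(df))
  df
}

#' Construct a methylation set
#'
#' CpG-by-sample beta values at two visits plus the probe annotation needed by
#' normalization and cis/trans scans.
#'
#' @param beta named list of numeric matrices (CpGs x samples), one per visit,
#'   e.g. `list(v2 = ..., v4 = ...)`; values in `[0, 1]`.
#' @param annot data frame with columns `cpg`, `chrom`, `pos`, `type`
#'   (`"I"` or `"II"`), one row per beta row.
#' @param eps clamping bound: betas are moved into `[eps, 1 - eps]` so the
#'   logit (M-value) transform stays finite.
#' @return Object of class `methylation_set` with clamped betas.
#' @export
methylation_set <- function(beta, annot, eps = 1e-6) {
  stopifnot(is.list(beta), length(beta) >= 1)
  annot <- as.data.frame(annot)
  need <- c("cpg", "chrom", "pos", "type")
  if (!all(need %in% names(annot)))
    stopf("annotation must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(annot$cpg)) stopf("duplicate CpG IDs")
  if (!all(annot$type %in% c("I", "II")))
    stopf("probe type must be 'I' or 'II' for every CpG")
  for (v in names(beta)) {
    b <- as.matrix(beta[[v]])
    if (nrow(b) != nrow(annot))
      stopf("visit %s: %d beta rows but %d annotation rows", v, nrow(b), nrow(annot))
    rng <- range(b, na.rm = TRUE)
    if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
      stopf("visit %s: beta values outside [0,1]", v)
    b[] <- clamp(b, eps, 1 - eps)
    rownames(b) <- annot$cpg
    beta[[v]] <- b
  }
  structure(list(beta = beta, annot = annot, eps = eps),
            class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat(sprintf("methylation_set: %d CpGs (%d type I / %d type II) x %d samples, visits: %s\n",
              nrow(x$annot), sum(x$annot$type == "I"), sum(x$annot$type == "II"),
              ncol(x$beta[[1]]), paste(names(x$beta), collapse = ", ")))
  invisible(x)
}
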