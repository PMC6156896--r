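## Delimited-table I/O: phenotypes, methylation matrices, BED region export.

read_delim_auto <- function(path, header = TRUE, row_names = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
             row.names = row_names, check.names = FALSE)
}

#' Read a phenotype table
#'
#' @param path delimited file (TSV, or CSV by extension) with one row per
#'   sample. Expected columns: sample, pedigree, tg1..tg4, sex, age, center,
#'   smoking, atp, idf; `mapping` renames file columns onto this schema.
#' @param mapping named character vector, `c(internal = "file_column", ...)`,
#'   for files using different headers.
#' @return A [phenotype_table()]. Missing TG visits are preserved as `NA`.
#' @export
read_phenotypes <- function(path, mapping = NULL) {
  df <- read_delim_auto(path)
  if (!is.null(mapping)) {
    miss <- setdiff(unname(mapping), names(df))
    if (length(miss)) stopf("mapped columns absent from file: %s",
                            paste(miss, collapse = ", "))
    for (k in names(mapping)) names(df)[names(df) == mapping[[k]]] <- k
  }
  phenotype_table(df)
}

#' Read methylation beta matrices into a methylation set
#'
#' @param paths named character vector of delimited beta matrices (CpGs in
#'   rows with the CpG ID in the first column, samples in columns), one per
#'   visit, e.g. `c(v2 = "...", v4 = "...")`.
#' @param annot probe annotation: a data frame or file with columns
#'   `cpg`, `chrom`, `pos`, `type`. Probes present in the matrices but absent
#'   from the annotation are dropped with a logged count.
#' @param eps beta clamping bound, see [methylation_set()].
#' @return A [methylation_set()].
#' @export
read_methylation <- function(paths, annot, eps = 1e-6) {
  stopifnot(length(paths) >= 1, !is.null(names(paths)))
  if (is.character(annot)) annot <- read_delim_auto(annot)
  annot <- as.data.frame(annot)
  mats <- lapply(paths, function(p) {
    df <- read_delim_auto(p)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    if (anyDuplicated(rownames(m))) stopf("duplicate CpG IDs in %s", p)
    m
  })
  cpgs <- rownames(mats[[1]])
  for (m in mats) if (!identical(rownames(m), cpgs))
    stopf("visit matrices disagree on CpG rows")
  keep <- cpgs %in% annot$cpg
  if (any(!keep)) log_stage("read_methylation", dropped_unannotated = sum(!keep))
  cpgs <- cpgs[keep]
  mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
  annot <- annot[match(cpgs, annot$cpg), , drop = FALSE]
  rownames(annot) <- NULL
  methylation_set(mats, annot, eps = eps)
}

#' Export HD regions as BED6
#'
#' Internal coordinates are 1-based inclusive; BED uses 0-based half-open, so
#' a region `chrom:start-end` becomes `start-1 .. end`. The score column is
#' `round(1000 * mean_intensity)`.
#'
#' @param regions data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `mean_intensity` (as returned by [extract_hd_regions()]).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name="hd_regions" description="runs of homozygosity (intensity-based)"',
             con)
  if (nrow(regions)) {
    if (any(regions$end < regions$start)) stopf("region with end < start")
    bed <- data.frame(regions$chrom,
                      format(regions$start - 1L, scientific = FALSE, trim = TRUE),
                      format(regions$end, scientific = FALSE, trim = TRUE),
                      regions$sample,
                      round(1000 * regions$mean_intensity),
                      ".")
    writeLines(do.call(paste, c(unname(bed), sep = "\t")), con)
  }
  invisible(path)
}

## TSV writers shared by the pipeline: fixed formatting so identical inputs
## give byte-identical files.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.10g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
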