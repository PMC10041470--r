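# Plain-text writers/readers for every bundle component.  The dialects are
# deliberately simple: TSV with headers for tables and matrices, PLINK .raw
# for genotypes, one symbol per line for gene lists, JSON for the truth
# record.

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Time series go to `sub-<id>_task-<MID|SST>_wave-<1|2>.tsv` (parcels x
#' timepoints, header row of timepoint indices, first column the parcel
#' id); phenotypes to CSV; genotypes to PLINK .raw; the weight table,
#' parcel metadata, gene matrix and receptor maps to TSV; stress lists to
#' TXT; the truth record to JSON.
#'
#' @param bundle a [SyntheticBundle-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "SyntheticBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(bundle@time_series)) {
    for (lw in names(bundle@time_series[[sid]])) {
      task <- sub("_w[12]$", "", lw)
      wave <- sub("^.*_w", "", lw)
      writeTimeSeries(bundle@time_series[[sid]][[lw]],
                      file.path(dir, sprintf("sub-%s_task-%s_wave-%s.tsv",
                                             sid, task, wave)))
    }
  }
  utils::write.csv(bundle@phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  writeRaw(bundle@genotypes, file.path(dir, "genotypes.raw"))
  write.table(bundle@weights, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle@parcel_meta, file.path(dir, "parcel_meta.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeMatrixTsv(bundle@gene_matrix, file.path(dir, "gene_matrix.tsv"))
  writeMatrixTsv(bundle@receptor_maps, file.path(dir, "receptors.tsv"))
  writeLines(bundle@stress_low, file.path(dir, "stress_low.txt"))
  writeLines(bundle@stress_high, file.path(dir, "stress_high.txt"))
  jsonlite::write_json(bundle@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write / read one parcellated time-series matrix
#'
#' @param series parcels x timepoints matrix with parcel ids as rownames.
#' @param path file path.
#' @return `writeTimeSeries` returns `path` invisibly; `readTimeSeries` the
#'   matrix.
#' @export
writeTimeSeries <- function(series, path) {
  df <- data.frame(parcel_id = rownames(series), series,
                   check.names = FALSE)
  colnames(df) <- c("parcel_id", seq_len(ncol(series)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(as.character(df[[1]]), NULL)
  m
}

#' Write a genotype matrix in the PLINK .raw dialect
#'
#' @param genotypes subjects x SNPs matrix with a `counted_allele`
#'   attribute.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeRaw <- function(genotypes, path) {
  counted <- attr(genotypes, "counted_allele")
  snp_cols <- paste0(colnames(genotypes), "_",
                     counted[colnames(genotypes)])
  df <- data.frame(FID = rownames(genotypes), IID = rownames(genotypes),
                   PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                   genotypes, check.names = FALSE)
  colnames(df) <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                    snp_cols)
  write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a numeric matrix as TSV with row ids
#'
#' @param m matrix with rownames.
#' @param path file path.
#' @return `writeMatrixTsv` returns `path` invisibly; `readMatrixTsv` the
#'   matrix.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
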