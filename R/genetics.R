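#' Read a PLINK .raw additive genotype table
#'
#' Expects the header `FID IID PAT MAT SEX PHENOTYPE` followed by one
#' `<SNP>_<counted allele>` column per variant holding additive codes in
#' \{0, 1, 2\} (NA allowed).
#'
#' @param path file path.
#' @return numeric matrix subjects x SNPs; rownames are IIDs, colnames the
#'   SNP ids, with the counted allele in `attr(, "counted_allele")`.
#' @export
readRaw <- function(path) {
  df <- read.table(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)))
    stop("not a PLINK .raw dialect: missing ", paste(
      setdiff(meta, names(df)), collapse = ", "))
  snp_cols <- setdiff(names(df), meta)
  G <- as.matrix(df[, snp_cols, drop = FALSE])
  ids <- sub("_[ACGT]$", "", snp_cols)
  alleles <- sub(".*_([ACGT])$", "\\1", snp_cols)
  dimnames(G) <- list(as.character(df$IID), ids)
  attr(G, "counted_allele") <- setNames(alleles, ids)
  G
}

#' Read a GWAS weight table (TSV)
#'
#' Columns: `snp, chrom, pos, effect_allele, other_allele, beta, gwas_p`.
#'
#' @param path file path.
#' @return data.frame weight table.
#' @export
readWeights <- function(path) {
  w <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  validateWeights(w)
  w
}

validateWeights <- function(weights) {
  need <- c("snp", "chrom", "pos", "effect_allele", "other_allele",
            "beta", "gwas_p")
  if (!all(need %in% names(weights)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(weights$snp)) stop("duplicate SNP identifiers")
  if (!all(weights$effect_allele %in% c("A", "C", "G", "T")) ||
      !all(weights$other_allele %in% c("A", "C", "G", "T")))
    stop("alleles must be A, C, G or T")
  if (any(weights$gwas_p <= 0 | weights$gwas_p > 1))
    stop("gwas_p must lie in (0, 1]")
  invisible(weights)
}

# sample minor allele frequency of each genotype column (additive codes)
sample_maf <- function(G) {
  f <- colMeans(G, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "G" & a2 == "C") | (a1 == "C" & a2 == "G")
}

#' Filter a GWAS weight table for PRS computation
#'
#' Applies, in order: removal of SNPs absent from the genotypes (warned, not
#' fatal); exclusion of ambiguous allele pairs (A/T and G/C, whose strand
#' cannot be resolved); exclusion of SNPs with sample minor allele frequency
#' below `maf_threshold`; greedy clumping that walks SNPs by ascending GWAS
#' p-value, keeps the best SNP and eliminates any SNP within `window_bp` on
#' the same chromosome whose genotype r-squared with a kept SNP exceeds
#' `r2_threshold`; and finally the GWAS significance cut `gwas_p <=
#' p_threshold`.  Counts removed by each filter are recorded in
#' `attr(, "filter_log")`.
#'
#' @param weights weight table (see [readWeights()]).
#' @param genotypes subjects x SNPs additive-code matrix.
#' @param maf_threshold minimum sample MAF (default 0.05).
#' @param r2_threshold maximum pairwise genotype r^2 within the window
#'   (default 0.10).
#' @param window_bp clumping window in base pairs (default 500 kb).
#' @param p_threshold GWAS significance threshold (default 5e-8).
#' @return the filtered weight table with a `filter_log` attribute.
#' @export
filterSnps <- function(weights, genotypes, maf_threshold = 0.05,
                       r2_threshold = 0.10, window_bp = 5e5,
                       p_threshold = 5e-8) {
  validateWeights(weights)
  log <- c(missing_in_genotypes = 0, ambiguous = 0, low_maf = 0,
           clumped = 0, gwas_p = 0)

  present <- weights$snp %in% colnames(genotypes)
  if (any(!present)) {
    warning(sum(!present), " weight-table SNP(s) absent from genotypes; ",
            "skipped")
    log["missing_in_genotypes"] <- sum(!present)
    weights <- weights[present, , drop = FALSE]
  }

  amb <- ambiguous_pair(weights$effect_allele, weights$other_allele)
  log["ambiguous"] <- sum(amb)
  weights <- weights[!amb, , drop = FALSE]

  if (nrow(weights)) {
    maf <- sample_maf(genotypes[, weights$snp, drop = FALSE])
    low <- maf < maf_threshold
    log["low_maf"] <- sum(low)
    weights <- weights[!low, , drop = FALSE]
  }

  if (nrow(weights) > 1) {
    ord <- order(weights$gwas_p)
    keep <- logical(nrow(weights))
    alive <- rep(TRUE, nrow(weights))
    G <- genotypes[, weights$snp, drop = FALSE]
    for (i in ord) {
      if (!alive[i]) next
      keep[i] <- TRUE
      near <- which(alive & !keep &
                      weights$chrom == weights$chrom[i] &
                      abs(weights$pos - weights$pos[i]) <= window_bp)
      if (length(near)) {
        r2 <- suppressWarnings(
          cor(G[, i], G[, near, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        r2[is.na(r2)] <- 0
        drop <- near[r2 > r2_threshold]
        alive[drop] <- FALSE
      }
    }
    log["clumped"] <- sum(!keep & !alive)
    weights <- weights[keep, , drop = FALSE]
  }

  sig <- weights$gwas_p <= p_threshold
  log["gwas_p"] <- sum(!sig)
  weights <- weights[sig, , drop = FALSE]

  attr(weights, "filter_log") <- as.list(log)
  weights
}

#' Compute polygenic risk scores as a weighted sum of risk alleles
#'
#' For each subject, `score = sum_k beta_k x count_k` over the (already
#' filtered) weight table.  The counted allele of each genotype column is
#' resolved against the effect allele: when the .raw counted allele is the
#' non-effect allele the count is flipped (`c -> 2 - c`).  Missing genotypes
#' are imputed as twice the sample effect-allele frequency (logged per SNP);
#' all-missing SNPs are dropped with a warning.
#'
#' @param genotypes subjects x SNPs additive matrix (with optional
#'   `counted_allele` attribute, as from [readRaw()]).
#' @param weights filtered weight table.
#' @return a [PrsResult-class].
#' @export
computePrs <- function(genotypes, weights) {
  validateWeights(weights)
  counted <- attr(genotypes, "counted_allele")
  log <- list(flipped = character(0), imputed = list(),
              dropped_all_missing = character(0),
              unresolved_allele = character(0))
  scores <- setNames(numeric(nrow(genotypes)), rownames(genotypes))
  used <- 0L
  for (k in seq_len(nrow(weights))) {
    snp <- weights$snp[k]
    if (!snp %in% colnames(genotypes)) next
    g <- genotypes[, snp]
    if (all(is.na(g))) {
      warning("SNP ", snp, " has no observed genotypes; dropped")
      log$dropped_all_missing <- c(log$dropped_all_missing, snp)
      next
    }
    if (!is.null(counted) && !is.na(counted[snp])) {
      if (counted[snp] == weights$other_allele[k]) {
        g <- 2 - g
        log$flipped <- c(log$flipped, snp)
      } else if (counted[snp] != weights$effect_allele[k]) {
        warning("counted allele of ", snp,
                " matches neither weight-table allele; skipped")
        log$unresolved_allele <- c(log$unresolved_allele, snp)
        next
      }
    }
    if (anyNA(g)) {
      af <- mean(g, na.rm = TRUE) / 2
      log$imputed[[snp]] <- sum(is.na(g))
      g[is.na(g)] <- 2 * af
    }
    scores <- scores + weights$beta[k] * g
    used <- used + 1L
  }
  flog <- attr(weights, "filter_log")
  if (is.null(flog)) flog <- list()
  flog$imputation <- log
  new("PrsResult", scores = scores, n_snps_used = as.numeric(used),
      filter_log = flog)
}

#' Split a weight table into APOE-region and non-APOE SNPs
#'
#' The APOE region is taken as a closed interval on a chromosome (default
#' chr19:44.4-46.5 Mb); the two returned tables partition the input.
#'
#' @param weights weight table.
#' @param chrom chromosome label (default "19").
#' @param start_bp,end_bp closed interval bounds in base pairs.
#' @return list with `apoe` and `no_apoe` weight tables.
#' @export
splitApoeRegion <- function(weights, chrom = "19", start_bp = 44.4e6,
                            end_bp = 46.5e6) {
  validateWeights(weights)
  inside <- as.character(weights$chrom) == as.character(chrom) &
    weights$pos >= start_bp & weights$pos <= end_bp
  list(apoe = weights[inside, , drop = FALSE],
       no_apoe = weights[!inside, , drop = FALSE])
}
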