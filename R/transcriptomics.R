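# robust sigmoid of one vector: x_norm = 1 / (1 + exp(-(x - <x>) / IQRx))
# with <x> the median and IQRx the normalized interquartile range
# (IQR / 1.35, the consistency scaling that makes it comparable to an SD),
# followed by rescaling to the unit interval.
robust_sigmoid <- function(x, label = "sample") {
  med <- median(x)
  iqr <- IQR(x) / 1.35
  if (iqr <= 0) stop("zero IQR for ", label)
  xn <- 1 / (1 + exp(-(x - med) / iqr))
  xs <- (xn - min(xn)) / (max(xn) - min(xn))
  list(scaled = xs, median = med, iqr = iqr)
}

#' Robust sigmoid normalisation of expression values
#'
#' Applies the outlier-resistant scaling
#' \deqn{x_{norm} = 1 / (1 + \exp(-(x - \langle x\rangle)/IQR_x))}
#' with \eqn{\langle x\rangle} the median and \eqn{IQR_x} the normalized
#' interquartile range of a single tissue sample across genes, followed by
#' unit-interval rescaling
#' \eqn{x_{scaled} = (x_{norm} - \min)/( \max - \min)}; the identical
#' procedure is then applied across tissue samples (per gene).  The
#' transformation is monotone within each stage, so gene rank order per
#' sample is preserved by the first stage.
#'
#' @param raw samples x genes numeric matrix.
#' @return samples x genes matrix in [0, 1] with a `normalization_log`
#'   attribute (per-sample and per-gene medians and IQRs).
#' @export
robustSigmoidNormalize <- function(raw) {
  raw <- as.matrix(raw)
  smp <- rownames(raw); if (is.null(smp)) smp <- paste0("s", seq_len(nrow(raw)))
  gn <- colnames(raw); if (is.null(gn)) gn <- paste0("g", seq_len(ncol(raw)))
  log_s <- matrix(NA_real_, nrow(raw), 2,
                  dimnames = list(smp, c("median", "iqr")))
  out <- raw
  for (i in seq_len(nrow(raw))) {          # across genes, per sample
    rs <- robust_sigmoid(raw[i, ], paste("sample", smp[i]))
    out[i, ] <- rs$scaled
    log_s[i, ] <- c(rs$median, rs$iqr)
  }
  log_g <- matrix(NA_real_, ncol(raw), 2,
                  dimnames = list(gn, c("median", "iqr")))
  for (j in seq_len(ncol(out))) {          # across samples, per gene
    rs <- robust_sigmoid(out[, j], paste("gene", gn[j]))
    out[, j] <- rs$scaled
    log_g[j, ] <- c(rs$median, rs$iqr)
  }
  attr(out, "normalization_log") <- list(per_sample = log_s, per_gene = log_g)
  out
}

#' Aggregate tissue samples to parcels (within donor, then across donors)
#'
#' Samples assigned to the same parcel are averaged separately for each
#' donor and the donor means are then averaged, so donors with many samples
#' in a parcel do not dominate.  Parcels with no assigned sample are
#' excluded and listed in the normalization log.
#'
#' @param samples samples x genes matrix (normalized values).
#' @param parcel_assignment parcel id per sample (NA = unassigned,
#'   discarded).
#' @param donor_ids donor id per sample.
#' @param parcel_ids optional full parcel universe (to record exclusions).
#' @return a [GeneExpressionMatrix-class].
#' @export
aggregateSamplesToParcels <- function(samples, parcel_assignment, donor_ids,
                                      parcel_ids = NULL) {
  samples <- as.matrix(samples)
  keep <- !is.na(parcel_assignment)
  samples <- samples[keep, , drop = FALSE]
  parcel_assignment <- as.character(parcel_assignment[keep])
  donor_ids <- as.character(donor_ids[keep])
  if (is.null(parcel_ids)) parcel_ids <- sort(unique(parcel_assignment))
  gn <- colnames(samples)
  if (is.null(gn)) gn <- paste0("g", seq_len(ncol(samples)))
  present <- intersect(parcel_ids, unique(parcel_assignment))
  out <- matrix(NA_real_, length(present), ncol(samples),
                dimnames = list(present, gn))
  for (p in present) {
    rows <- parcel_assignment == p
    donor_means <- rowsum(samples[rows, , drop = FALSE], donor_ids[rows],
                          reorder = FALSE) /
      as.vector(table(factor(donor_ids[rows],
                             levels = unique(donor_ids[rows]))))
    out[p, ] <- colMeans(donor_means)
  }
  excluded <- setdiff(parcel_ids, present)
  norm_log <- attr(samples, "normalization_log")
  if (is.null(norm_log)) norm_log <- list()
  norm_log$excluded_parcels <- excluded
  # aggregation of [0,1] values stays in [0,1]
  new("GeneExpressionMatrix", values = out, gene_symbols = gn,
      parcel_ids = present, normalization_log = norm_log)
}

#' Construct directional stress-gene sets
#'
#' @param stress_low symbols whose risk alleles reduce expression.
#' @param stress_high symbols whose risk alleles increase expression.
#' @return a [StressGeneSets-class].
#' @export
stressGeneSets <- function(stress_low, stress_high) {
  new("StressGeneSets", stress_low = as.character(stress_low),
      stress_high = as.character(stress_high))
}

#' Stress-gene overlap permutation test
#'
#' Tests whether the transcriptomic profile of the brain map is enriched for
#' stress-susceptibility genes.  From the gene PLS result it takes the genes
#' robustly (99.9% CI) positively and negatively correlated with the gene LV
#' (counts `orig_pos`, `orig_neg`) and their overlap with the two
#' directional stress sets.  From each Procrustes-aligned null gene LV it
#' selects the `orig_pos` top-ranked and `orig_neg` bottom-ranked genes and
#' counts the same overlaps.  With a positive brain-gene LV correlation the
#' susceptibility conjunction is stress_high-among-positive plus
#' stress_low-among-negative (the inverse test swaps the directions); with a
#' negative correlation the roles flip.  P-values use a mid-p convention
#' over the null conjunction counts (ties between integer counts split in
#' half), with the usual `1/(n_null + 1)` floor.
#'
#' @param gene_pls a [PlsResult-class] from [genePls()].
#' @param sets a [StressGeneSets-class].
#' @param null_gene_lvs genes x n_null matrix of aligned null gene LVs
#'   (default: the attribute stored by [genePls()]).
#' @param direction sign of the brain-gene LV correlation; default taken
#'   from the observed statistic.
#' @return an [OverlapResult-class].
#' @export
overlapTest <- function(gene_pls, sets, null_gene_lvs = NULL,
                        direction = NULL) {
  stopifnot(is(gene_pls, "PlsResult"), is(sets, "StressGeneSets"))
  if (is.null(null_gene_lvs))
    null_gene_lvs <- attr(gene_pls, "null_gene_lvs")
  if (is.null(null_gene_lvs)) stop("null gene LVs required")
  if (is.null(direction)) direction <- sign(gene_pls@statistic)
  if (direction == 0) direction <- 1
  ld <- gene_pls@element_loadings
  genes <- ld$element
  rob_pos <- ld$element[ld$lower > 0]
  rob_neg <- ld$element[ld$upper < 0]
  orig_pos <- length(rob_pos); orig_neg <- length(rob_neg)
  if (orig_pos + orig_neg == 0)
    warning("no robust genes: overlap p-values are undefined")

  sh <- sets@stress_high; sl <- sets@stress_low
  obs <- c(high_pos = sum(rob_pos %in% sh), low_pos = sum(rob_pos %in% sl),
           high_neg = sum(rob_neg %in% sh), low_neg = sum(rob_neg %in% sl))

  n_null <- ncol(null_gene_lvs)
  null_counts <- matrix(0L, n_null, 4,
                        dimnames = list(NULL, names(obs)))
  is_high <- genes %in% sh
  is_low <- genes %in% sl
  for (k in seq_len(n_null)) {
    o <- order(null_gene_lvs[, k], decreasing = TRUE)
    top <- if (orig_pos) o[seq_len(orig_pos)] else integer(0)
    bot <- if (orig_neg) rev(o)[seq_len(orig_neg)] else integer(0)
    null_counts[k, ] <- c(sum(is_high[top]), sum(is_low[top]),
                          sum(is_high[bot]), sum(is_low[bot]))
  }

  conj <- function(counts, hp, ln) counts[, hp] + counts[, ln]
  if (direction > 0) {
    susc_obs <- obs["high_pos"] + obs["low_neg"]
    susc_null <- conj(null_counts, "high_pos", "low_neg")
    inv_obs <- obs["low_pos"] + obs["high_neg"]
    inv_null <- conj(null_counts, "low_pos", "high_neg")
  } else {
    susc_obs <- obs["low_pos"] + obs["high_neg"]
    susc_null <- conj(null_counts, "low_pos", "high_neg")
    inv_obs <- obs["high_pos"] + obs["low_neg"]
    inv_null <- conj(null_counts, "high_pos", "low_neg")
  }
  p_susc <- if (orig_pos + orig_neg == 0) NA_real_ else
    perm_pvalue(susc_null, as.numeric(susc_obs), mid = TRUE)
  p_inv <- if (orig_pos + orig_neg == 0) NA_real_ else
    perm_pvalue(inv_null, as.numeric(inv_obs), mid = TRUE)

  new("OverlapResult", orig_pos = orig_pos, orig_neg = orig_neg,
      stress_high_pos = as.numeric(obs["high_pos"]),
      stress_low_pos = as.numeric(obs["low_pos"]),
      stress_high_neg = as.numeric(obs["high_neg"]),
      stress_low_neg = as.numeric(obs["low_neg"]),
      p_susceptibility = unname(p_susc), p_inverse = unname(p_inv),
      direction = direction)
}

#' Read stress-gene lists from plain text
#'
#' One symbol per line, one file per direction.
#'
#' @param low_path,high_path file paths.
#' @return a [StressGeneSets-class].
#' @export
readStressGeneSets <- function(low_path, high_path) {
  stressGeneSets(readLines(low_path), readLines(high_path))
}
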