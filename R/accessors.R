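# Accessors and show methods for the core containers.

#' @export
setGeneric("parcelIds", function(x) standardGeneric("parcelIds"))
#' Parcel identifiers of an object
#' @param x a package object indexed by parcels.
#' @return character vector of parcel ids.
#' @describeIn parcelIds connectivity matrix
#' @export
setMethod("parcelIds", "ConnectivityMatrix", function(x) x@parcel_ids)
#' @describeIn parcelIds multilayer network (shared across layers)
#' @export
setMethod("parcelIds", "MultilayerNetwork", function(x) x@layers[[1]]@parcel_ids)
#' @describeIn parcelIds partition ensemble
#' @export
setMethod("parcelIds", "PartitionEnsemble", function(x) x@parcel_ids)
#' @describeIn parcelIds gene expression matrix
#' @export
setMethod("parcelIds", "GeneExpressionMatrix", function(x) x@parcel_ids)

#' Connectivity values
#' @param x a [ConnectivityMatrix-class].
#' @return the symmetric numeric matrix of Fisher-z scores.
#' @export
connectivityValues <- function(x) {
  stopifnot(is(x, "ConnectivityMatrix"))
  x@values
}

#' Modularity values across ensemble restarts
#' @param x a [PartitionEnsemble-class].
#' @return numeric vector of Q per iteration.
#' @export
qValues <- function(x) {
  stopifnot(is(x, "PartitionEnsemble"))
  x@q_values
}

#' Community labels of a partition ensemble
#' @param x a [PartitionEnsemble-class].
#' @return integer array `[iteration, layer, parcel]`.
#' @export
partitionLabels <- function(x) {
  stopifnot(is(x, "PartitionEnsemble"))
  x@labels
}

#' Pooled cross-fold correlation of a cross-validated result
#' @param x a [CvMultivariateResult-class].
#' @return correlation of the pooled test-fold predicted variates.
#' @export
crossFoldR <- function(x) {
  stopifnot(is(x, "CvMultivariateResult"))
  x@cross_fold_r
}

#' Permutation p-value
#' @param x a [CvMultivariateResult-class], [PlsResult-class] or
#'   [OverlapResult-class].
#' @return the permutation (or spin) p-value(s).
#' @export
permP <- function(x) {
  if (is(x, "CvMultivariateResult") || is(x, "PlsResult")) return(x@perm_p)
  if (is(x, "OverlapResult"))
    return(c(susceptibility = x@p_susceptibility, inverse = x@p_inverse))
  stop("no permutation p-value for class ", class(x))
}

#' Pooled test-fold predicted LV scores
#' @param x a [PlsResult-class].
#' @return numeric vector (per subject for behavioural PLS, per parcel for
#'   gene PLS).
#' @export
predictedScores <- function(x) {
  stopifnot(is(x, "PlsResult"))
  x@predicted_scores
}

#' Bootstrap-robust elements of a PLS result
#' @param x a [PlsResult-class].
#' @return character vector of element names whose CI excludes zero.
#' @export
robustElements <- function(x) {
  stopifnot(is(x, "PlsResult"))
  x@robust_elements
}

#' Per-subject polygenic risk scores
#' @param x a [PrsResult-class].
#' @return named numeric vector of scores.
#' @export
prsScores <- function(x) {
  stopifnot(is(x, "PrsResult"))
  x@scores
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_subjects, "subjects,",
      object@n_parcels, "parcels,", object@n_timepoints, "timepoints,",
      object@n_genes, "genes\n")
  cat("  planted: canonical_r =", object@canonical_r,
      "| shift =", object@community_shift_fraction,
      "| snr =", object@snr, "| seed =", object@seed, "\n")
})

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle:", length(object@time_series), "subjects x",
      length(object@time_series[[1]]), "task/wave series;",
      nrow(object@gene_matrix), "parcels x", ncol(object@gene_matrix),
      "genes;", ncol(object@receptor_maps), "receptors\n")
  cat("  stress sets:", length(object@stress_low), "low /",
      length(object@stress_high), "high\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix", object@task, object@wave, ":",
      nrow(object@values), "x", ncol(object@values), "Fisher-z")
  if (!is.na(object@n_zeroed)) cat(" (", object@n_zeroed, "zeroed )")
  cat("\n")
})

setMethod("show", "MultilayerNetwork", function(object) {
  cat("MultilayerNetwork:", length(object@layers), "layers x",
      nrow(object@layers[[1]]@values), "parcels; omega =", object@omega,
      "; gamma =", paste(unique(object@gamma), collapse = "/"), "\n")
})

setMethod("show", "PartitionEnsemble", function(object) {
  d <- dim(object@labels)
  cat("PartitionEnsemble:", d[1], "iterations x", d[2], "layers x", d[3],
      "parcels; Q in [", round(min(object@q_values), 4), ",",
      round(max(object@q_values), 4), "]\n")
})

setMethod("show", "CvMultivariateResult", function(object) {
  cat("CvMultivariateResult: n =", length(object@variate_x),
      "; cross-fold r =", round(object@cross_fold_r, 4))
  if (!is.na(object@perm_p)) cat("; perm p =", signif(object@perm_p, 3))
  cat("\n")
})

setMethod("show", "PlsResult", function(object) {
  cat("PlsResult: first singular value =",
      round(object@singular_values[1], 4))
  if (!is.na(object@perm_p)) cat("; perm p =", signif(object@perm_p, 3))
  cat(";", length(object@robust_elements), "robust elements\n")
})

setMethod("show", "SpinNullSet", function(object) {
  cat("SpinNullSet:", nrow(object@permutations), "spins x",
      ncol(object@permutations), "parcels; hemispheres",
      if (object@preserved_hemispheres) "preserved" else "free", "\n")
})

setMethod("show", "OverlapResult", function(object) {
  cat("OverlapResult: orig_pos =", object@orig_pos, ", orig_neg =",
      object@orig_neg, "\n  overlap high+/low-/high-/low+:",
      object@stress_high_pos, object@stress_low_neg, object@stress_high_neg,
      object@stress_low_pos, "\n  p(susceptibility) =",
      signif(object@p_susceptibility, 3), "; p(inverse) =",
      signif(object@p_inverse, 3), "\n")
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult: a =", round(object@a_path, 4), "; b =",
      round(object@b_path, 4), "; b(MxW) =", round(object@b_interaction, 4),
      "\n  index of moderated mediation =", round(object@index_modmed, 4),
      "[", round(object@index_lower, 4), ",", round(object@index_upper, 4),
      "]\n")
})

setMethod("show", "PrsResult", function(object) {
  cat("PrsResult:", length(object@scores), "subjects;", object@n_snps_used,
      "SNPs used\n")
})
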