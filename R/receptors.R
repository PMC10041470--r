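#' Participant-weighted average of tracer maps
#'
#' Combines several tracer-specific density maps for one neurotransmitter
#' into a single receptor map, weighting each tracer by the number of
#' participants in its source study.
#'
#' @param tracer_maps parcels x tracers matrix (or list of per-parcel
#'   vectors with identical parcel order).
#' @param participant_counts positive study sizes, one per tracer.
#' @return per-parcel weighted-mean density vector.
#' @export
weightedAverageTracers <- function(tracer_maps, participant_counts) {
  if (is.list(tracer_maps)) {
    len <- unique(vapply(tracer_maps, length, 0L))
    if (length(len) != 1) stop("mismatched parcel sets across tracers")
    tracer_maps <- do.call(cbind, tracer_maps)
  }
  tracer_maps <- as.matrix(tracer_maps)
  if (ncol(tracer_maps) != length(participant_counts))
    stop("one participant count per tracer required")
  if (any(participant_counts <= 0)) stop("participant counts must be > 0")
  as.vector(tracer_maps %*% participant_counts) / sum(participant_counts)
}

#' Standardize receptor maps across parcels
#'
#' @param maps parcels x receptors matrix.
#' @return matrix with column mean 0 and SD 1.
#' @export
standardizeReceptors <- function(maps) {
  standardize_cols(as.matrix(maps))
}

#' Composite serotonin receptor map
#'
#' Four of the five serotonin density indices (HT1a, HT2, HT4, HT6) are
#' moderately to strongly inter-correlated, so their standardized scores are
#' averaged into one composite; HT1b is carried separately.
#'
#' @param ht1a,ht2,ht4,ht6 standardized per-parcel density maps.
#' @return per-parcel composite (mean of the four inputs).
#' @export
compositeHt <- function(ht1a, ht2, ht4, ht6) {
  (ht1a + ht2 + ht4 + ht6) / 4
}

#' Cross-validated CCA between a brain map and receptor maps, spin-tested
#'
#' Runs the shared cross-validated CCA machinery with parcels as
#' observations (brain LV map on one side, receptor density maps on the
#' other) and replaces the free permutation null with spatially constrained
#' spins of the pooled brain variate, respecting the map's spatial
#' autocorrelation.
#'
#' @param brain_lv per-parcel brain LV score.
#' @param maps parcels x receptors standardized density matrix.
#' @param spins a [SpinNullSet-class] on the same parcels.
#' @param k_folds folds over parcels (default 10).
#' @param seed RNG seed.
#' @return a [CvMultivariateResult-class] with `perm_p` from the spin null.
#' @export
receptorCca <- function(brain_lv, maps, spins, k_folds = 10, seed = 1) {
  maps <- as.matrix(maps)
  if (length(brain_lv) != nrow(maps)) stop("parcels misaligned")
  res <- crossValidateCca(matrix(brain_lv, ncol = 1,
                                 dimnames = list(NULL, "brain_lv")),
                          maps, k_folds = k_folds, seed = seed)
  stopifnot(is(spins, "SpinNullSet"))
  res@perm_p <- permutationTest(res@variate_x, res@variate_y,
                                permutations = spins@permutations)
  res
}
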