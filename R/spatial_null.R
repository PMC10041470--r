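# Uniform random rotation matrices via normalized quaternions.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Greedy one-to-one nearest matching: repeatedly assign the globally closest
# (rotated, original) centroid pair among those still unassigned, so every
# rotated parcel inherits the value of exactly one original parcel.
greedy_match <- function(rotated, original) {
  n <- nrow(rotated)
  D <- sqrt(pmax(outer(rowSums(rotated^2), rowSums(original^2), "+") -
                   2 * tcrossprod(rotated, original), 0))
  perm <- integer(n)
  big <- max(D) + 1
  for (k in seq_len(n)) {
    m <- arrayInd(which.min(D), dim(D))
    perm[m[1]] <- m[2]
    D[m[1], ] <- big
    D[, m[2]] <- big
  }
  perm
}

#' Generate spatially constrained (spin) permutations
#'
#' Draws `n_null` uniform random 3D rotations (normalized quaternions),
#' applies each to the left-hemisphere spherical centroids and its
#' x-mirrored twin to the right hemisphere, and reassigns each parcel the
#' value of the nearest still-available original centroid (greedy one-to-one
#' matching), yielding hemisphere-preserving permutations that retain the
#' spatial autocorrelation of smooth maps.
#'
#' @param parcel_meta data.frame with columns `hemisphere` ("L"/"R") and
#'   centroid coordinates `x`, `y`, `z` on/near the unit sphere per
#'   hemisphere.
#' @param n_null number of permutations.
#' @param seed RNG seed.
#' @return a [SpinNullSet-class].
#' @export
generateSpins <- function(parcel_meta, n_null, seed = 1) {
  xyz <- as.matrix(parcel_meta[, c("x", "y", "z")])
  if (anyDuplicated(xyz)) stop("degenerate (duplicated) parcel centroids")
  hemi <- as.character(parcel_meta$hemisphere)
  left <- which(hemi == "L"); right <- which(hemi == "R")
  # normalize to unit length so rotations act on the sphere
  norms <- sqrt(rowSums(xyz^2))
  xyz <- xyz / norms
  M <- diag(c(-1, 1, 1))
  set.seed(seed)
  P <- matrix(NA_integer_, n_null, nrow(xyz))
  for (k in seq_len(n_null)) {
    R <- random_rotation()
    if (length(left)) {
      rotL <- xyz[left, , drop = FALSE] %*% t(R)
      P[k, left] <- left[greedy_match(rotL, xyz[left, , drop = FALSE])]
    }
    if (length(right)) {
      Rm <- M %*% R %*% M
      rotR <- xyz[right, , drop = FALSE] %*% t(Rm)
      P[k, right] <- right[greedy_match(rotR, xyz[right, , drop = FALSE])]
    }
  }
  new("SpinNullSet", permutations = P,
      preserved_hemispheres = length(left) > 0 && length(right) > 0,
      seed = as.numeric(seed))
}

#' Spin-test p-value of a map statistic
#'
#' Recomputes `statistic_fn` on the map reindexed by every spin permutation
#' and counts nulls whose absolute statistic reaches the observed absolute
#' value: `p = (1 + #\{|stat_null| >= |stat_obs|\}) / (1 + n_null)`.
#'
#' @param observed_stat the statistic of the unpermuted map.
#' @param statistic_fn pure function of a per-parcel vector.
#' @param map per-parcel values.
#' @param spins a [SpinNullSet-class].
#' @return the p-value.
#' @export
spinP <- function(observed_stat, statistic_fn, map, spins) {
  stopifnot(is(spins, "SpinNullSet"))
  P <- spins@permutations
  if (ncol(P) != length(map)) stop("map length must match spin set")
  stats_null <- apply(P, 1, function(idx) statistic_fn(map[idx]))
  (1 + sum(abs(stats_null) >= abs(observed_stat))) / (1 + nrow(P))
}

#' Neighbour-correlation measure of spatial autocorrelation
#'
#' Correlation between each parcel's value and the mean of its k nearest
#' neighbours (within hemisphere) — a simple Moran-style smoothness
#' statistic used to check that spun maps preserve, and naive shuffles
#' destroy, spatial structure.
#'
#' @param map per-parcel values.
#' @param parcel_meta data.frame with `hemisphere`, `x`, `y`, `z`.
#' @param k neighbours per parcel.
#' @return correlation coefficient.
#' @export
neighbourCorrelation <- function(map, parcel_meta, k = 5) {
  xyz <- as.matrix(parcel_meta[, c("x", "y", "z")])
  hemi <- as.character(parcel_meta$hemisphere)
  n <- nrow(xyz)
  D <- as.matrix(dist(xyz))
  D[outer(hemi, hemi, "!=")] <- Inf
  diag(D) <- Inf
  nb_mean <- vapply(seq_len(n), function(i) {
    mean(map[order(D[i, ])[seq_len(k)]])
  }, 0)
  cor(map, nb_mean)
}
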