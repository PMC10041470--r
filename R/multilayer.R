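#' Construct a multilayer network from connectivity layers
#'
#' Joins node-aligned connectivity layers with uniform interlayer coupling of
#' strength `omega` along `coupling_pairs`.  For the canonical four layers
#' (MID-w1, SST-w1, MID-w2, SST-w2) the default coupling is the 4-cycle:
#' between-task within each wave and within-task between waves — not
#' all-pairs categorical coupling.
#'
#' @param layers list of [ConnectivityMatrix-class] sharing parcel ids.
#' @param omega interlayer coupling strength (default 0.5, the value used for
#'   heterogeneous task states).
#' @param gamma per-layer resolution parameter(s) (default 1), recycled.
#' @param coupling_pairs two-column matrix of layer index pairs; `NULL` gives
#'   the 4-cycle for 4 layers, all pairs otherwise.
#' @return a [MultilayerNetwork-class].
#' @export
multilayerNetwork <- function(layers, omega = 0.5, gamma = 1,
                              coupling_pairs = NULL) {
  if (is.null(coupling_pairs)) {
    L <- length(layers)
    coupling_pairs <- if (L == 4) {
      rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
    } else if (L >= 2) {
      t(utils::combn(L, 2))
    } else {
      matrix(integer(0), 0, 2)
    }
  }
  coupling_pairs <- matrix(as.integer(coupling_pairs), ncol = 2)
  new("MultilayerNetwork", layers = layers,
      coupling_pairs = coupling_pairs, omega = omega,
      gamma = rep_len(gamma, length(layers)))
}

# Supra-node modularity quality matrix.  Within-layer blocks hold
# w_ijl - gamma_l * s_il s_jl / v_l (interlayer edges are excluded from the
# strengths s and the layer total v: the null model is intra-layer); coupled
# blocks hold omega on the node-identity diagonal.  twomu is the total weight
# across layers including both directions of every interlayer edge.
supra_quality <- function(network) {
  L <- length(network@layers)
  n <- nrow(network@layers[[1]]@values)
  N <- L * n
  B <- matrix(0, N, N)
  total <- 0
  for (l in seq_len(L)) {
    W <- network@layers[[l]]@values
    v <- sum(W)
    idx <- (l - 1L) * n + seq_len(n)
    if (v > 0) {
      s <- rowSums(W)
      B[idx, idx] <- W - network@gamma[l] * tcrossprod(s) / v
    } else {
      B[idx, idx] <- W
    }
    total <- total + v
  }
  cp <- network@coupling_pairs
  if (nrow(cp) && network@omega > 0) {
    for (k in seq_len(nrow(cp))) {
      a <- (cp[k, 1] - 1L) * n + seq_len(n)
      b <- (cp[k, 2] - 1L) * n + seq_len(n)
      B[cbind(a, b)] <- B[cbind(a, b)] + network@omega
      B[cbind(b, a)] <- B[cbind(b, a)] + network@omega
    }
    total <- total + 2 * network@omega * n * nrow(cp)
  }
  if (total <= 0) stop("empty network: total connection weight is zero")
  list(B = B, twomu = total, n_parcels = n, n_layers = L)
}

#' Multilayer modularity of a labeled partition
#'
#' Evaluates the multilayer quality
#' \deqn{Q = \frac{1}{2\mu} \sum_{ijlr} \left[(w_{ijl} - \gamma_l e_{ijl})
#'   \delta_{lr} + \delta_{ij}\,\omega_{jlr}\right] \delta(g_{il}, g_{jr})}
#' with the chance expectation \eqn{e_{ijl} = s_{il} s_{jl} / v_l}, summed
#' over ordered pairs (the i = j within-layer terms contribute their null
#' expectation) and normalised by the total weight \eqn{2\mu} including both
#' directions of every interlayer edge.
#'
#' @param network a [MultilayerNetwork-class].
#' @param labels integer matrix, layers x parcels, of community labels
#'   (comparable across layers).
#' @return the modularity Q.
#' @export
modularityQ <- function(network, labels) {
  sq <- supra_quality(network)
  labels <- as.matrix(labels)
  if (nrow(labels) != sq$n_layers || ncol(labels) != sq$n_parcels)
    stop("labels must be a layers x parcels matrix")
  flat <- as.integer(t(labels))        # layer-block order
  flat <- as.integer(as.factor(flat))  # tolerate arbitrary label values
  .partition_weight(sq$B, flat) / sq$twomu
}

#' Maximise multilayer modularity with a generalized-Louvain algorithm
#'
#' Greedy phase moves every (parcel, layer) supra-node to the neighbouring
#' community with the best positive modularity gain; the aggregation phase
#' collapses communities into super-nodes preserving intra- and interlayer
#' weights; the two alternate until no move improves Q by more than `tol`.
#' Node visit order is reshuffled each pass from a deterministic stream, so
#' a fixed seed yields identical labels.  Ties in the gain keep the current
#' community.
#'
#' @param network a [MultilayerNetwork-class].
#' @param seed integer seed for the move order.
#' @param tol convergence tolerance on the gain (default 1e-10).
#' @return list with `labels` (layers x parcels integer matrix) and `Q`
#'   (equal to `modularityQ(network, labels)` up to 1e-9).
#' @export
louvainMultilayer <- function(network, seed = 1, tol = 1e-10) {
  sq <- supra_quality(network)
  res <- .louvain_dense(sq$B, sq$twomu, as.integer(seed %% 2147483647),
                        tol, 100L)
  labels <- matrix(res$labels, nrow = sq$n_layers,
                   ncol = sq$n_parcels, byrow = TRUE)
  rownames(labels) <- vapply(network@layers,
                             function(l) paste(l@task, l@wave, sep = "_"), "")
  colnames(labels) <- parcelIds(network)
  list(labels = labels, Q = res$Q)
}

#' Run an ensemble of Louvain restarts
#'
#' The modularity landscape is nearly degenerate, so the optimiser is
#' restarted `n_iterations` times (default 100) and downstream diagnostics
#' are averaged across restarts.  Iteration k uses seed `base_seed + k`.
#'
#' @param network a [MultilayerNetwork-class].
#' @param n_iterations number of restarts (>= 1).
#' @param base_seed base RNG seed.
#' @return a [PartitionEnsemble-class].
#' @export
runEnsemble <- function(network, n_iterations = 100, base_seed = 1) {
  stopifnot(n_iterations >= 1)
  sq <- supra_quality(network)
  L <- sq$n_layers; n <- sq$n_parcels
  labels <- array(0L, dim = c(n_iterations, L, n))
  q <- numeric(n_iterations)
  for (k in seq_len(n_iterations)) {
    # first restart greedy from singletons, later restarts from random
    # partitions, so the ensemble explores distinct basins of the nearly
    # degenerate modularity landscape
    res <- .louvain_dense(sq$B, sq$twomu,
                          as.integer((base_seed + k) %% 2147483647),
                          1e-10, 100L, k > 1)
    labels[k, , ] <- matrix(res$labels, nrow = L, ncol = n, byrow = TRUE)
    q[k] <- res$Q
  }
  layer_names <- vapply(network@layers,
                        function(l) paste(l@task, l@wave, sep = "_"), "")
  new("PartitionEnsemble", labels = labels, q_values = q,
      layer_names = layer_names, parcel_ids = parcelIds(network))
}

#' Flexibility: cross-task community reassignment per wave
#'
#' For each parcel and wave, the fraction of ensemble restarts in which the
#' parcel's community label differs between the two task layers of that
#' wave.  "Number of times" over restarts is reported as a fraction in
#' [0, 1] so values are comparable across ensemble sizes.
#'
#' @param ensemble a [PartitionEnsemble-class].
#' @param wave_layer_pairs named list mapping each wave to its two layer
#'   indices, e.g. `list(w1 = c(1, 2), w2 = c(3, 4))`.
#' @return parcels x waves numeric matrix in [0, 1].
#' @export
flexibility <- function(ensemble, wave_layer_pairs) {
  stopifnot(is(ensemble, "PartitionEnsemble"))
  L <- dim(ensemble@labels)[2]
  out <- sapply(wave_layer_pairs, function(pr) {
    if (length(pr) != 2 || any(pr < 1) || any(pr > L))
      stop("each wave must map to exactly one pair of valid layers")
    colMeans(ensemble@labels[, pr[1], , drop = FALSE] !=
               ensemble@labels[, pr[2], , drop = FALSE])
  })
  out <- matrix(out, ncol = length(wave_layer_pairs),
                dimnames = list(ensemble@parcel_ids, names(wave_layer_pairs)))
  out
}

#' Recruitment: within-system co-assignment per layer
#'
#' For each parcel and layer, the fraction of restarts-weighted system mates
#' sharing the parcel's community: the mean over restarts of the proportion
#' of the parcel's native-system peers assigned to the same community.
#' Singleton systems have no peers; their value is `NA` with a warning.
#'
#' @param ensemble a [PartitionEnsemble-class].
#' @param native_system per-parcel system label (character or factor).
#' @return parcels x layers numeric matrix in [0, 1] (NA for singletons).
#' @export
recruitment <- function(ensemble, native_system) {
  stopifnot(is(ensemble, "PartitionEnsemble"))
  d <- dim(ensemble@labels)
  if (length(native_system) != d[3])
    stop("native_system must label every parcel")
  native_system <- as.character(native_system)
  sizes <- table(native_system)
  if (any(sizes < 2))
    warning("singleton native system(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            " - recruitment undefined, reported as NA")
  out <- matrix(NA_real_, d[3], d[2],
                dimnames = list(ensemble@parcel_ids, ensemble@layer_names))
  systems <- split(seq_len(d[3]), native_system)
  for (l in seq_len(d[2])) {
    acc <- matrix(0, d[1], d[3])
    for (S in systems) {
      if (length(S) < 2) next
      g <- ensemble@labels[, l, S, drop = FALSE][, 1, ]   # iterations x |S|
      g <- matrix(g, nrow = d[1])
      for (a in seq_along(S)) {
        same <- rowSums(g == g[, a]) - 1
        acc[, S[a]] <- same / (length(S) - 1)
      }
    }
    vals <- colMeans(acc)
    vals[native_system %in% names(sizes)[sizes < 2]] <- NA_real_
    out[, l] <- vals
  }
  out
}

#' Tabulate node metrics for the canonical 4-layer design
#'
#' Convenience wrapper producing the per-parcel table used by the
#' behavioural PLS: flexibility per wave and recruitment per task x wave.
#' Assumes layer order MID_w1, SST_w1, MID_w2, SST_w2.
#'
#' @param ensemble a [PartitionEnsemble-class] over the 4 canonical layers.
#' @param native_system per-parcel system label.
#' @return data.frame `parcel_id, flex_w1, flex_w2, recr_MID_w1, recr_SST_w1,
#'   recr_MID_w2, recr_SST_w2`.
#' @export
nodeMetrics <- function(ensemble, native_system) {
  fl <- flexibility(ensemble, list(w1 = c(1, 2), w2 = c(3, 4)))
  rc <- recruitment(ensemble, native_system)
  data.frame(parcel_id = ensemble@parcel_ids,
             flex_w1 = fl[, "w1"], flex_w2 = fl[, "w2"],
             recr_MID_w1 = rc[, 1], recr_SST_w1 = rc[, 2],
             recr_MID_w2 = rc[, 3], recr_SST_w2 = rc[, 4],
             row.names = NULL)
}
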