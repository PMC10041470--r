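# Shared fixtures and independent oracles.

# wrap a symmetric nonnegative matrix as a ConnectivityMatrix
conn <- function(A, task = "MID", wave = "w1") {
  diag(A) <- 0
  n <- nrow(A)
  new("ConnectivityMatrix", values = (A + t(A)) / 2, task = task,
      wave = wave, parcel_ids = sprintf("p%02d", seq_len(n)),
      n_zeroed = NA_real_)
}

# two disconnected 3-cliques with unit weights
clique_pair <- function() {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  A
}

# independent dense Newman-Girvan modularity (single layer)
newman_girvan <- function(W, labels, gamma = 1) {
  v <- sum(W)
  s <- rowSums(W)
  B <- W - gamma * outer(s, s) / v
  sum(B[outer(labels, labels, "==")]) / v
}

# enumerate all set partitions of n items as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxg) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (g in seq_len(maxg + 1)) rec(c(prefix, g), max(maxg, g))
  }
  rec(integer(0), 0L)
  out
}

# brute-force optimum of multilayer modularity over comparable labelings
brute_force_q <- function(network) {
  L <- length(network@layers)
  n <- nrow(network@layers[[1]]@values)
  best <- -Inf
  for (p in all_partitions(L * n)) {
    q <- modularityQ(network, matrix(p, nrow = L, byrow = TRUE))
    if (q > best) best <- q
  }
  best
}

# random symmetric nonnegative weight matrix
random_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- ifelse(runif(sum(up)) < density, runif(sum(up)), 0)
  A <- A + t(A)
  diag(A) <- 0
  A
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  exp_idx <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# independent generalized-eigenvalue oracle for the first canonical r
cca_eigen_oracle <- function(X, Y) {
  Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sqrt(max(Re(eigen(M)$values)))
}

# small parcel table on mirrored unit hemispheres
toy_parcel_meta <- function(n = 40, seed = 1) {
  cfg <- simulationConfig(n_subjects = 2, n_parcels = n, seed = seed)
  simulateParcelMeta(cfg)
}

# smooth map over a parcel table (exponential kernel)
smooth_map <- function(parcel_meta, rho = 0.3, seed = 1) {
  set.seed(seed)
  xyz <- as.matrix(parcel_meta[, c("x", "y", "z")])
  K <- exp(-as.matrix(dist(xyz)) / rho)
  as.vector(t(chol(K + diag(1e-8, nrow(K)))) %*% rnorm(nrow(K)))
}
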