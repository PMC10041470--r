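# Shared numerical helpers.

# permutation p with the (1 + exceed) / (1 + n) floor convention
perm_pvalue <- function(null_stats, observed, mid = FALSE) {
  if (mid) {
    (1 + sum(null_stats > observed) + 0.5 * sum(null_stats == observed)) /
      (1 + length(null_stats))
  } else {
    (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
  }
}

# percentile CI whose endpoints are order statistics of the draws
percentile_ci <- function(draws, level) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  alpha <- (1 - level) / 2
  k_lo <- min(max(1L, floor((n + 1) * alpha)), n)
  k_hi <- max(min(n, ceiling((n + 1) * (1 - alpha))), 1L)
  c(lower = draws[k_lo], upper = draws[k_hi])
}

# seeded k-fold assignment, optionally stratified by a factor
make_folds <- function(n, k, seed, strata = NULL) {
  if (k < 2) stop("k_folds must be >= 2")
  if (k > n) stop("more folds than observations")
  set.seed(seed)
  fold <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  sizes <- tabulate(fold, k)
  if (any(sizes < 3) && n >= 3 * k)
    warning("some folds have fewer than 3 observations")
  fold
}

# column standardization with guards for zero variance
standardize_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale < .Machine$double.eps] <- 1
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

# fast correlations of each column of X with vector y (pairwise complete not
# needed here; inputs are complete by construction)
col_cor <- function(X, y) {
  X <- as.matrix(X)
  xc <- sweep(X, 2, colMeans(X), "-")
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(crossprod(xc, yc)) / (sx * sy)
  r[sx < .Machine$double.eps | sy < .Machine$double.eps] <- 0
  r
}

# derive a stream of sub-seeds below 2^31 from one base seed
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}
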