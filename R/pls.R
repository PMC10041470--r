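#' Procrustes alignment of resampled singular vectors
#'
#' Axis rotations (LV order changes) and reflections (sign flips) that occur
#' under resampling are corrected by the orthogonal transform that brings
#' the resampled singular vectors closest (in Frobenius distance) to the
#' reference solution.
#'
#' @param reference_saliences,resampled_saliences matrices of identical
#'   shape (elements x LVs); vectors are treated as one-column matrices.
#' @return list with `aligned` (the transformed resampled saliences) and
#'   `rotation` (the orthogonal matrix, to be inverse-applied to partner
#'   vectors).
#' @export
procrustesAlign <- function(reference_saliences, resampled_saliences) {
  R <- as.matrix(reference_saliences)
  S <- as.matrix(resampled_saliences)
  if (!all(dim(R) == dim(S))) stop("shapes must match")
  sv <- svd(crossprod(S, R))
  rot <- sv$u %*% t(sv$v)
  list(aligned = S %*% rot, rotation = rot)
}

# training-fold condition x parcel correlation matrix with behaviour
condition_correlations <- function(stack, behaviour, rows) {
  t(vapply(stack, function(M) {
    r <- col_cor(M[rows, , drop = FALSE], behaviour[rows])
    r[!is.finite(r)] <- 0
    r
  }, numeric(ncol(stack[[1]]))))
}

#' Behavioural partial least squares with cross-validated significance
#'
#' Correlates one behavioural variable with every parcel measure within each
#' condition on the training folds, stacks the correlation vectors into a
#' conditions x parcels matrix and takes its SVD.  Training parcel saliences
#' project the left-out fold onto predicted brain scores per condition;
#' training condition weights project the behaviour likewise.  The observed
#' statistic is the first singular value of the condition-wise correlation
#' between the two pooled test-fold score matrices; its significance is the
#' fraction of within-condition permutations of the behaviour whose
#' statistic exceeds it.  Bootstrap over subjects gives 95% CIs for the
#' per-condition behaviour correlations and 99.9% CIs for the
#' (condition, parcel) loadings, whose exclusion of zero defines the robust
#' elements.
#'
#' @param stack named list of condition matrices (subjects x parcels) with
#'   consistent subject and parcel order.
#' @param behaviour per-subject variate.
#' @param k_folds folds over subjects (default 10).
#' @param n_perm permutations of the behaviour (default 999 for desk runs).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @param strata optional stratification for the fold split.
#' @return a [PlsResult-class]; `predicted_scores` are subject-level LV
#'   scores (condition-weighted sum of predicted brain scores).
#' @export
behaviouralPls <- function(stack, behaviour, k_folds = 10, n_perm = 999,
                           n_boot = 1000, seed = 1, strata = NULL) {
  stopifnot(is.list(stack), length(stack) >= 1)
  C <- length(stack)
  n <- nrow(stack[[1]]); np <- ncol(stack[[1]])
  if (length(behaviour) != n) stop("behaviour and stack must share subjects")
  zero_var <- vapply(stack, function(M) any(apply(M, 2, sd) == 0), TRUE)
  if (any(zero_var))
    warning("zero-variance parcel measures: their correlations are set to 0")
  fold <- make_folds(n, k_folds, seed, strata)

  # full-sample reference for sign orientation across folds
  R_full <- condition_correlations(stack, behaviour, seq_len(n))
  sv_full <- svd(R_full)

  brain_scores <- matrix(NA_real_, n, C)   # test-fold predicted, per condition
  behav_scores <- matrix(NA_real_, n, C)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    R_tr <- condition_correlations(stack, behaviour, which(!test))
    sv <- svd(R_tr)
    al <- procrustesAlign(sv_full$v[, 1, drop = FALSE],
                          sv$v[, 1, drop = FALSE])
    v1 <- as.numeric(al$aligned)               # parcel saliences
    u1 <- as.numeric(sv$u[, 1] %*% al$rotation)  # condition weights, partner
    for (cc in seq_len(C)) {
      brain_scores[test, cc] <- stack[[cc]][test, , drop = FALSE] %*% v1
      behav_scores[test, cc] <- behaviour[test] * u1[cc]
    }
  }

  cond_r <- function(Bs, Hs) {
    vapply(seq_len(ncol(Bs)), function(cc) {
      if (sd(Bs[, cc]) == 0 || sd(Hs[, cc]) == 0) return(0)
      cor(Bs[, cc], Hs[, cc])
    }, 0)
  }
  r_obs <- cond_r(brain_scores, behav_scores)
  stat_obs <- sqrt(sum(r_obs^2))   # first singular value of the 1 x C block

  set.seed(derive_seeds(seed, 1))
  stat_null <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    sqrt(sum(cond_r(brain_scores, behav_scores[idx, , drop = FALSE])^2))
  }, 0)
  perm_p <- perm_pvalue(stat_null, stat_obs)

  # subject-level LV score: condition-weighted sum of predicted brain scores
  u_full <- sv_full$u[, 1]
  lv_scores <- as.numeric(brain_scores %*% u_full)

  # bootstrap reliability
  set.seed(derive_seeds(seed, 2))
  load_obs <- unlist(lapply(seq_len(C), function(cc)
    col_cor(stack[[cc]], lv_scores)))
  behav_obs <- r_obs
  ld_draw <- matrix(NA_real_, n_boot, length(load_obs))
  bh_draw <- matrix(NA_real_, n_boot, C)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    ld_draw[b, ] <- unlist(lapply(seq_len(C), function(cc)
      col_cor(stack[[cc]][idx, , drop = FALSE], lv_scores[idx])))
    bh_draw[b, ] <- cond_r(brain_scores[idx, , drop = FALSE],
                           behav_scores[idx, , drop = FALSE])
  }
  ld_ci <- t(apply(ld_draw, 2, percentile_ci, level = 0.999))
  bh_ci <- t(apply(bh_draw, 2, percentile_ci, level = 0.95))

  cond_names <- names(stack)
  if (is.null(cond_names)) cond_names <- paste0("cond", seq_len(C))
  parcel_names <- colnames(stack[[1]])
  if (is.null(parcel_names)) parcel_names <- sprintf("p%03d", seq_len(np))
  el_names <- as.vector(outer(parcel_names, cond_names,
                              function(p, cn) paste(cn, p, sep = ":")))
  loadings <- data.frame(element = el_names, estimate = load_obs,
                         lower = ld_ci[, 1], upper = ld_ci[, 2],
                         row.names = NULL)
  robust <- loadings$element[loadings$lower > 0 | loadings$upper < 0]

  new("PlsResult",
      saliences = tcrossprod(u_full, sv_full$v[, 1]) *
        sv_full$d[1] + matrix(0, C, np,
                              dimnames = list(cond_names, parcel_names)),
      condition_weights = setNames(u_full, cond_names),
      singular_values = sv_full$d,
      predicted_scores = lv_scores,
      behav_correlations = data.frame(
        condition = cond_names, estimate = behav_obs,
        lower = bh_ci[, 1], upper = bh_ci[, 2], row.names = NULL),
      statistic = stat_obs, perm_p = perm_p,
      element_loadings = loadings, robust_elements = as.character(robust))
}

#' Variance accounted for by the first latent variable
#'
#' Proportion of the stacked correlation structure captured by the first
#' singular value: `d_1^2 / sum(d^2)`.
#'
#' @param result a [PlsResult-class].
#' @return fraction in [0, 1].
#' @export
varianceAccounted <- function(result) {
  stopifnot(is(result, "PlsResult"))
  d <- result@singular_values
  d[1]^2 / sum(d^2)
}

#' Gene PLS: transcriptomic profile of a brain map
#'
#' Relates a per-parcel brain latent-variable map to the parcel x gene
#' expression matrix.  Folds partition parcels (the observation unit here is
#' the parcel): per-gene correlations with the brain map on the training
#' parcels act as weights; the predicted gene LV score of a left-out parcel
#' is its expression profile times the training weights.  The pooled
#' statistic is the correlation between the brain map and the predicted gene
#' LV over all parcels; its significance is assessed against spatially
#' constrained (spin) permutations of the brain map, counting nulls whose
#' absolute correlation exceeds the observed.  Gene-level 99.9% bootstrap
#' CIs (over parcels) define robust genes; null gene LVs (per spin,
#' sign-aligned to the original by Procrustes) are returned for the
#' stress-overlap test.
#'
#' @param gene_matrix parcels x genes matrix (or
#'   [GeneExpressionMatrix-class]).
#' @param brain_lv per-parcel brain LV score.
#' @param spins a [SpinNullSet-class] on the same parcels.
#' @param k_folds folds over parcels (default 10).
#' @param n_boot bootstrap draws for gene CIs (default 1000).
#' @param seed RNG seed.
#' @return a [PlsResult-class]; `predicted_scores` are per-parcel gene LV
#'   scores and `attr(, "null_gene_lvs")` holds the genes x n_null aligned
#'   null weight vectors.
#' @export
genePls <- function(gene_matrix, brain_lv, spins, k_folds = 10,
                    n_boot = 1000, seed = 1) {
  if (is(gene_matrix, "GeneExpressionMatrix")) {
    G <- gene_matrix@values
  } else {
    G <- as.matrix(gene_matrix)
  }
  np <- nrow(G); ng <- ncol(G)
  if (length(brain_lv) != np) stop("parcels misaligned between inputs")
  miss <- !complete.cases(G) | !is.finite(brain_lv)
  if (any(miss)) {
    message(sum(miss), " parcel(s) without expression excluded pairwise")
    G <- G[!miss, , drop = FALSE]
    brain_lv <- brain_lv[!miss]
    np <- nrow(G)
  }
  fold <- make_folds(np, k_folds, seed)
  w_full <- col_cor(G, brain_lv)
  pred <- numeric(np)
  for (f in seq_len(k_folds)) {
    test <- fold == f
    w <- col_cor(G[!test, , drop = FALSE], brain_lv[!test])
    al <- procrustesAlign(matrix(w_full, ncol = 1), matrix(w, ncol = 1))
    w <- as.numeric(al$aligned)
    scl <- apply(G[!test, , drop = FALSE], 2, sd)
    scl[scl < .Machine$double.eps] <- 1
    pred[test] <- standardize_cols(G[test, , drop = FALSE],
                                   colMeans(G[!test, , drop = FALSE]),
                                   scl) %*% w
  }
  r_obs <- cor(brain_lv, pred)

  stopifnot(is(spins, "SpinNullSet"))
  P <- spins@permutations
  if (ncol(P) != np)
    stop("spin permutations must match the (retained) parcel count")
  n_null <- nrow(P)
  r_null <- numeric(n_null)
  null_lvs <- matrix(NA_real_, ng, n_null)
  for (k in seq_len(n_null)) {
    bl <- brain_lv[P[k, ]]
    r_null[k] <- cor(bl, pred)
    wk <- col_cor(G, bl)
    al <- procrustesAlign(matrix(w_full, ncol = 1), matrix(wk, ncol = 1))
    null_lvs[, k] <- as.numeric(al$aligned)
  }
  perm_p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_null)

  # gene-level bootstrap over parcels
  set.seed(derive_seeds(seed, 3))
  gl_draw <- matrix(NA_real_, n_boot, ng)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(np, replace = TRUE)
    gl_draw[b, ] <- col_cor(G[idx, , drop = FALSE], pred[idx])
  }
  gl_obs <- col_cor(G, pred)
  gl_ci <- t(apply(gl_draw, 2, percentile_ci, level = 0.999))
  symbols <- colnames(G)
  if (is.null(symbols)) symbols <- sprintf("g%05d", seq_len(ng))
  loadings <- data.frame(element = symbols, estimate = gl_obs,
                         lower = gl_ci[, 1], upper = gl_ci[, 2],
                         row.names = NULL)
  robust <- loadings$element[loadings$lower > 0 | loadings$upper < 0]

  out <- new("PlsResult",
             saliences = matrix(w_full, ncol = 1,
                                dimnames = list(symbols, "LV1")),
             condition_weights = 1,
             singular_values = sqrt(sum(w_full^2)),
             predicted_scores = pred,
             behav_correlations = data.frame(
               condition = "gene_lv", estimate = r_obs,
               lower = NA_real_, upper = NA_real_),
             statistic = r_obs, perm_p = perm_p,
             element_loadings = loadings,
             robust_elements = as.character(robust))
  attr(out, "null_gene_lvs") <- null_lvs
  out
}
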