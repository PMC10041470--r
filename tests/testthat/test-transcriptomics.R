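test_that("robust sigmoid hits its closed-form landmarks", {
  set.seed(1)
  x <- rnorm(101, mean = 5, sd = 2)
  med <- median(x)
  iqr <- IQR(x) / 1.35
  sig <- function(v) 1 / (1 + exp(-(v - med) / iqr))
  # value at the median -> 0.5 before rescaling
  expect_equal(sig(med), 0.5)
  # value at median + IQRx -> 1/(1+e^-1)
  expect_equal(sig(med + iqr), 0.7311, tolerance = 1e-4)
  # the package path applies the same sigmoid then unit-rescales per row
  set.seed(9)
  X <- rbind(x, rnorm(101, 4, 3))
  out <- robustSigmoidNormalize(X)
  expect_equal(min(out[1, ]), 0)
  expect_equal(max(out[1, ]), 1)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("normalisation is monotone within each sample", {
  set.seed(2)
  X <- matrix(rnorm(5 * 30), 5, 30)
  # first-stage (per-sample) transform preserves gene rank order
  st1 <- t(apply(X, 1, function(r) neurodevnet:::robust_sigmoid(r)$scaled))
  for (i in 1:5) expect_equal(order(st1[i, ]), order(X[i, ]))
  expect_error(robustSigmoidNormalize(rbind(rep(1, 10), rnorm(10))),
               "zero IQR")
})

test_that("sample aggregation is the donor-mean of means, not pooled mean", {
  # 6-sample fixture: donor A has 3 samples in parcel p1, donor B has 1
  vals <- matrix(c(0.1, 0.2, 0.3, 0.8, 0.5, 0.6), ncol = 1,
                 dimnames = list(NULL, "g1"))
  parcels <- c("p1", "p1", "p1", "p1", "p2", "p2")
  donors <- c("A", "A", "A", "B", "A", "B")
  gem <- aggregateSamplesToParcels(vals, parcels, donors,
                                   parcel_ids = c("p1", "p2", "p3"))
  # p1: donor A mean 0.2, donor B mean 0.8 -> 0.5 (pooled mean would be 0.35)
  expect_equal(gem@values["p1", "g1"], 0.5)
  expect_equal(gem@values["p2", "g1"], 0.55)
  expect_equal(gem@normalization_log$excluded_parcels, "p3")
  # one donor, one sample per parcel -> identity
  one <- aggregateSamplesToParcels(matrix(c(0.3, 0.9), ncol = 1),
                                   c("p1", "p2"), c("A", "A"))
  expect_equal(as.numeric(one@values), c(0.3, 0.9))
})

mk_gene_pls <- function(est, lower, upper, genes, stat = 0.5) {
  new("PlsResult", saliences = matrix(est, ncol = 1),
      condition_weights = 1, singular_values = 1,
      predicted_scores = numeric(0),
      behav_correlations = NULL, statistic = stat, perm_p = NA_real_,
      element_loadings = data.frame(element = genes, estimate = est,
                                    lower = lower, upper = upper),
      robust_elements = genes[lower > 0 | upper < 0])
}

test_that("overlap counts match exhaustive counting on a toy instance", {
  genes <- paste0("g", 1:10)
  # robust: g1,g2,g3 positive; g9,g10 negative
  est <- c(0.9, 0.8, 0.7, 0, 0, 0, 0, 0, -0.8, -0.9)
  lower <- c(0.5, 0.4, 0.3, -0.2, -0.2, -0.2, -0.2, -0.2, -0.9, -1)
  upper <- c(1, 1, 1, 0.2, 0.2, 0.2, 0.2, 0.2, -0.3, -0.4)
  gp <- mk_gene_pls(est, lower, upper, genes)
  sets <- stressGeneSets(stress_low = c("g9", "g4"),
                         stress_high = c("g1", "g2", "g6"))
  # two hand-built nulls
  null1 <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)   # top3 = g1,g2,g3; bottom2 = g9,g10
  null2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)   # top3 = g10,g9,g8; bottom2 = g1,g2
  ov <- overlapTest(gp, sets, null_gene_lvs = cbind(null1, null2))
  expect_equal(ov@orig_pos, 3); expect_equal(ov@orig_neg, 2)
  expect_equal(ov@stress_high_pos, 2)   # g1, g2
  expect_equal(ov@stress_low_neg, 1)    # g9
  # observed conjunction = 3; null1 conjunction = 2 (high in top) + 1 = 3 tie;
  # null2 = 0 + 0 = 0 -> mid-p = (1 + 0 + 0.5) / 3
  expect_equal(ov@p_susceptibility, 1.5 / 3)
  # inverse: observed low_pos + high_neg = 0; null1 = 1 low? g4 not in top3 -> 0+0;
  # null2: top3 g10,g9,g8 has g9 (low) = 1; bottom2 g1,g2 both high = 2 -> 3 > 0
  expect_equal(ov@p_inverse, (1 + 1 + 0.5) / 3)
})

test_that("maximal enrichment attains the permutation floor", {
  ng <- 60
  genes <- sprintf("g%02d", 1:ng)
  est <- c(rep(0.8, 20), rep(0, 20), rep(-0.8, 20))
  lower <- c(rep(0.5, 20), rep(-0.2, 20), rep(-1, 20))
  upper <- c(rep(1, 20), rep(0.2, 20), rep(-0.5, 20))
  gp <- mk_gene_pls(est, lower, upper, genes)
  sets <- stressGeneSets(stress_low = genes[41:60], stress_high = genes[1:20])
  set.seed(3)
  # nulls that never place stress genes in the selected tails
  nulls <- replicate(50, {
    v <- rnorm(ng)
    v[1:20] <- -abs(v[1:20]) - 10    # high genes pushed to the bottom-middle
    v[41:60] <- abs(v[41:60]) + 10
    v[21:40] <- v[21:40] * 0.1
    v
  })
  # top-20 of each null are the stress_low genes, bottom-20 the stress_high:
  # susceptibility conjunction (high in top + low in bottom) is always 0
  ov <- overlapTest(gp, sets, null_gene_lvs = nulls)
  expect_equal(ov@p_susceptibility, 1 / 51)
  expect_equal(ov@p_inverse, 1)
})

test_that("null overlap expectation matches the hypergeometric oracle", {
  set.seed(4)
  ng <- 500
  genes <- sprintf("g%03d", 1:ng)
  orig_pos <- 40
  est <- rep(0, ng); lower <- rep(-0.1, ng); upper <- rep(0.1, ng)
  lower[1:orig_pos] <- 0.2; est[1:orig_pos] <- 0.5; upper[1:orig_pos] <- 0.8
  gp <- mk_gene_pls(est, lower, upper, genes)
  high <- sample(genes, 45); low <- sample(setdiff(genes, high), 27)
  sets <- stressGeneSets(stress_low = low, stress_high = high)
  nulls <- matrix(rnorm(ng * 400), ng, 400)
  ov <- overlapTest(gp, sets, null_gene_lvs = nulls)
  # mean stress_high among the 40 top-ranked genes of a noise null
  counts <- vapply(seq_len(400), function(k) {
    top <- order(nulls[, k], decreasing = TRUE)[1:orig_pos]
    sum(genes[top] %in% high)
  }, 0)
  expected <- orig_pos * 45 / ng
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(400))
})

test_that("stress gene lists round-trip through plain text", {
  lo <- tempfile(); hi <- tempfile()
  writeLines(c("GENEA", "GENEB"), lo)
  writeLines("GENEC", hi)
  sets <- readStressGeneSets(lo, hi)
  expect_equal(sets@stress_low, c("GENEA", "GENEB"))
  expect_equal(sets@stress_high, "GENEC")
  expect_error(stressGeneSets(c("X", "Y"), c("Y", "Z")), "disjoint")
})
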