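small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 40, n_parcels = 30, n_timepoints = 80,
         n_genes = 120, n_networks = 3, seed = 7),
    list(...))
  do.call(simulationConfig, args)
}

test_that("configs validate their invariants", {
  expect_s4_class(small_cfg(), "SimulationConfig")
  expect_error(small_cfg(canonical_r = 1), "canonical_r")
  expect_error(small_cfg(community_shift_fraction = 1.2),
               "community_shift_fraction")
  expect_error(small_cfg(n_parcels = 0), "counts")
  expect_error(small_cfg(n_genes = 50), "stress")
})

test_that("identical seeds give bit-identical bundles", {
  b1 <- simulateBundle(small_cfg())
  b2 <- simulateBundle(small_cfg())
  expect_identical(b1@phenotypes, b2@phenotypes)
  expect_identical(b1@gene_matrix, b2@gene_matrix)
  expect_identical(b1@genotypes, b2@genotypes)
  expect_identical(b1@time_series[[5]], b2@time_series[[5]])
  b3 <- simulateBundle(small_cfg(seed = 8))
  expect_false(identical(b1@phenotypes, b3@phenotypes))
})

test_that("no NaN or Inf anywhere in a generated bundle", {
  b <- simulateBundle(small_cfg())
  expect_true(all(is.finite(b@gene_matrix)))
  expect_true(all(is.finite(b@receptor_maps)))
  expect_true(all(is.finite(b@genotypes)))
  expect_true(all(is.finite(as.matrix(
    b@phenotypes[, !names(b@phenotypes) %in% "subject_id"]))))
  expect_true(all(vapply(b@time_series[[1]],
                         function(m) all(is.finite(m)), TRUE)))
})

test_that("community shift moves exactly the requested parcel count", {
  set.seed(1)
  meta <- simulateParcelMeta(small_cfg())
  # zero shift: identical plans in both task layers
  p0 <- neurodevnet:::planted_partitions(small_cfg(
    community_shift_fraction = 0), meta)
  expect_identical(p0$MID, p0$SST)
  # full shift on 30 parcels: all change
  p1 <- neurodevnet:::planted_partitions(small_cfg(
    community_shift_fraction = 1), meta)
  expect_equal(sum(p1$MID != p1$SST), 30)
  # fractional shift
  p2 <- neurodevnet:::planted_partitions(small_cfg(
    community_shift_fraction = 0.2), meta)
  expect_equal(sum(p2$MID != p2$SST), round(0.2 * 30))
})

test_that("planted communities separate within- from between-community r", {
  cfg <- simulationConfig(n_subjects = 1, n_parcels = 120, n_timepoints = 400,
                          n_networks = 6, snr = 1, n_genes = 120, seed = 3)
  set.seed(cfg@seed)
  meta <- simulateParcelMeta(cfg)
  ts <- simulateTimeSeries(cfg, meta)
  X <- ts$series[[1]]$MID_w1
  r <- cor(t(X))
  g <- ts$partitions$MID
  same <- outer(g, g, "==") & upper.tri(r)
  diff <- (!outer(g, g, "==")) & upper.tri(r)
  expect_gt(mean(r[same]) - mean(r[diff]), 0.2)
})

test_that("time series reject too-short runs", {
  expect_error(simulateTimeSeries(small_cfg(n_timepoints = 5)),
               "unstable")
})

test_that("psychopathology totals behave like item sums", {
  b <- simulateBundle(small_cfg())
  ph <- b@phenotypes
  items <- ph[, grep("psy_wA_item", names(ph))]
  expect_true(all(as.matrix(items) %in% 0:2))
  expect_equal(psychopathologyTotal(ph, "wA"), as.integer(rowSums(items)))
  # maximum-sum case: 112 items all scored 2 -> 224
  fake <- as.data.frame(matrix(2L, 1, 112))
  names(fake) <- sprintf("psy_wA_item%03d", 1:112)
  expect_equal(psychopathologyTotal(fake, "wA"), 224L)
})

test_that("planted canonical correlation appears in the phenotypes", {
  cfg <- simulationConfig(n_subjects = 1000, n_parcels = 30, n_genes = 120,
                          canonical_r = 0.5, seed = 21)
  set.seed(cfg@seed)
  ph <- simulatePhenotypes(cfg)
  X <- riskBlock(ph$phenotypes, 1)
  Y <- cbind(psychopathologyTotal(ph$phenotypes, "wA"),
             psychopathologyTotal(ph$phenotypes, "wB"))
  r1 <- cancor(X, Y)$cor[1]
  expect_lt(abs(r1 - 0.5), 0.1)
})

test_that("gene matrix plants loadings and spatial autocorrelation", {
  cfg <- simulationConfig(n_subjects = 4, n_parcels = 80, n_genes = 500,
                          gene_loading = 0.6, spatial_rho = 0.3, seed = 5)
  set.seed(cfg@seed)
  meta <- simulateParcelMeta(cfg)
  gm <- simulateGeneMatrix(cfg, meta)
  expect_equal(length(gm$stress_low), 27)
  expect_equal(length(gm$stress_high), 45)
  expect_equal(length(union(gm$stress_low, gm$stress_high)), 72)
  r_high <- cor(gm$gene_matrix[, gm$stress_high], gm$pattern)
  r_low <- cor(gm$gene_matrix[, gm$stress_low], gm$pattern)
  expect_lt(abs(mean(r_high) - 0.6), 0.1)
  expect_lt(abs(mean(r_low) + 0.6), 0.1)
  # rho = 0 kills neighbour correlation
  cfg0 <- simulationConfig(n_subjects = 4, n_parcels = 80, n_genes = 200,
                           gene_loading = 0, spatial_rho = 0, seed = 6)
  set.seed(cfg0@seed)
  gm0 <- simulateGeneMatrix(cfg0, meta)
  nb <- apply(gm0$gene_matrix[, 1:50], 2, neighbourCorrelation,
              parcel_meta = meta)
  expect_lt(median(abs(nb)), 0.25)
  cfg1 <- simulationConfig(n_subjects = 4, n_parcels = 80, n_genes = 200,
                           gene_loading = 0, spatial_rho = 0.5, seed = 6)
  set.seed(cfg1@seed)
  gm1 <- simulateGeneMatrix(cfg1, meta)
  nb1 <- apply(gm1$gene_matrix[, 1:50], 2, neighbourCorrelation,
               parcel_meta = meta)
  expect_gt(median(nb1), median(abs(nb)) + 0.2)
})

test_that("genotype generator matches its stated frequencies and filters", {
  cfg <- simulationConfig(n_subjects = 10000, n_parcels = 30, n_genes = 120,
                          n_snps = 20, seed = 9)
  set.seed(cfg@seed)
  gt <- simulateGenotypes(cfg)
  counted <- attr(gt$genotypes, "counted_allele")
  eff_freq <- vapply(seq_len(20), function(k) {
    g <- gt$genotypes[, k]
    if (counted[k] != gt$weights$effect_allele[k]) g <- 2 - g
    mean(g) / 2
  }, 0)
  expect_true(all(abs(eff_freq - gt$maf) < 0.01))
  # ambiguous SNPs present and removed downstream
  amb <- neurodevnet:::ambiguous_pair(gt$weights$effect_allele,
                                      gt$weights$other_allele)
  expect_equal(sum(amb), 2)
  filt <- suppressWarnings(filterSnps(gt$weights, gt$genotypes))
  expect_setequal(filt$snp, gt$expected_kept)
  # MAF 0.5 -> mean additive code ~ 1
  set.seed(1)
  expect_lt(abs(mean(rbinom(10000, 2, 0.5)) - 1), 0.02)
})

test_that("receptor maps are standardized and carry the planted loading", {
  cfg <- simulationConfig(n_subjects = 4, n_parcels = 100, n_genes = 120,
                          receptor_loading = 0.45, seed = 13)
  set.seed(cfg@seed)
  meta <- simulateParcelMeta(cfg)
  pattern <- smooth_map(meta, seed = 2)
  pattern <- (pattern - mean(pattern)) / sd(pattern)
  maps <- simulateReceptors(cfg, meta, pattern)
  expect_equal(unname(colMeans(maps)), rep(0, 9), tolerance = 1e-10)
  expect_equal(unname(apply(maps, 2, sd)), rep(1, 9), tolerance = 1e-10)
  r <- cor(maps[, c("D2", "GABA", "GLU5R")], pattern)
  expect_lt(max(abs(r - 0.45)), 0.25)
  expect_lt(max(abs(cor(maps[, c("HT1b", "ACh")], pattern))), 0.35)
})

test_that("bundle writes to plain text and key tables round-trip", {
  b <- simulateBundle(small_cfg())
  dir <- file.path(tempdir(), "bundle_rt")
  writeSyntheticBundle(b, dir)
  expect_true(file.exists(file.path(dir, "sub-sub0001_task-MID_wave-1.tsv")))
  ts <- readTimeSeries(file.path(dir, "sub-sub0001_task-MID_wave-1.tsv"))
  expect_equal(ts, b@time_series[[1]]$MID_w1, tolerance = 1e-6)
  G <- readRaw(file.path(dir, "genotypes.raw"))
  expect_equal(unname(G), unname(b@genotypes))
  gm <- readMatrixTsv(file.path(dir, "gene_matrix.tsv"))
  expect_equal(gm, b@gene_matrix, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$canonical_r, 0.5)
  unlink(dir, recursive = TRUE)
})
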