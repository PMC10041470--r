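# deterministic genotype fixture with known structure
prs_fixture <- function(n = 50, seed = 1) {
  set.seed(seed)
  weights <- data.frame(
    snp = paste0("rs", 1:5),
    chrom = c("1", "2", "19", "19", "2"),
    pos = c(1e6, 2e6, 45e6, 44.9e6, 2.05e6),
    effect_allele = c("A", "G", "C", "A", "T"),
    other_allele = c("G", "A", "T", "C", "C"),
    beta = c(0.3, -0.2, 0.5, 0.1, 0.25),
    gwas_p = c(1e-9, 1e-10, 1e-12, 1e-8, 1e-11),
    stringsAsFactors = FALSE)
  G <- sapply(c(0.3, 0.4, 0.25, 0.35, 0.45), function(m) rbinom(n, 2, m))
  dimnames(G) <- list(sprintf("s%02d", 1:n), weights$snp)
  attr(G, "counted_allele") <- setNames(weights$effect_allele, weights$snp)
  list(weights = weights, G = G)
}

test_that("PRS equals the hand-summed weighted allele count", {
  fx <- prs_fixture()
  res <- computePrs(fx$G, fx$weights)
  hand <- as.vector(fx$G %*% fx$weights$beta)
  expect_equal(unname(res@scores), hand, tolerance = 1e-12)
  expect_equal(res@n_snps_used, 5)
  # single SNP, beta 0.3, count 2 -> 0.6
  w1 <- fx$weights[1, , drop = FALSE]
  g1 <- fx$G[, 1, drop = FALSE]
  g1[] <- 2
  expect_equal(unname(computePrs(g1, w1)@scores), rep(0.6, 50))
  # all betas zero -> all scores zero
  w0 <- fx$weights; w0$beta <- 0
  expect_true(all(computePrs(fx$G, w0)@scores == 0))
})

test_that("PRS is invariant to SNP order, linear in betas, flip-invariant", {
  fx <- prs_fixture(seed = 3)
  base <- computePrs(fx$G, fx$weights)@scores
  perm <- c(4, 2, 5, 1, 3)
  reordered <- computePrs(fx$G[, perm],
                          fx$weights[perm, ])@scores
  expect_equal(base, reordered, tolerance = 1e-12)
  w2 <- fx$weights; w2$beta <- 2 * w2$beta
  expect_equal(computePrs(fx$G, w2)@scores, 2 * base, tolerance = 1e-12)
  # flip one column's counted allele and its codes
  G2 <- fx$G
  G2[, 2] <- 2 - G2[, 2]
  ca <- attr(fx$G, "counted_allele")
  ca["rs2"] <- fx$weights$other_allele[2]
  attr(G2, "counted_allele") <- ca
  expect_equal(computePrs(G2, fx$weights)@scores, base, tolerance = 1e-12)
})

test_that("missing genotypes are mean-imputed and all-missing SNPs dropped", {
  fx <- prs_fixture(seed = 5)
  G <- fx$G
  G[1:10, 1] <- NA
  res <- computePrs(G, fx$weights)
  af <- mean(G[, 1], na.rm = TRUE) / 2
  exp1 <- fx$weights$beta[1] * 2 * af
  manual <- G
  manual[1:10, 1] <- 2 * af
  expect_equal(unname(res@scores),
               as.vector(manual %*% fx$weights$beta), tolerance = 1e-12)
  G[, 2] <- NA
  expect_warning(res2 <- computePrs(G, fx$weights), "no observed genotypes")
  expect_equal(res2@n_snps_used, 4)
})

test_that("filters remove ambiguous, rare, correlated and weak SNPs", {
  set.seed(7)
  n <- 400
  weights <- data.frame(
    snp = paste0("rs", 1:6),
    chrom = c("1", "1", "1", "2", "2", "3"),
    pos = c(1e6, 1.1e6, 5e6, 1e6, 1e6 + 2e5, 1e6),
    effect_allele = c("A", "A", "G", "C", "T", "A"),
    other_allele = c("G", "T", "A", "A", "G", "C"),
    beta = rep(0.2, 6),
    gwas_p = c(1e-9, 1e-9, 1e-9, 1e-9, 1e-8, 1e-4),
    stringsAsFactors = FALSE)
  G <- sapply(c(0.3, 0.3, 0.01, 0.4, 0.4, 0.3), function(m) rbinom(n, 2, m))
  colnames(G) <- weights$snp
  rownames(G) <- sprintf("s%03d", 1:n)
  # make rs5 highly correlated with rs4 (same chrom, 200 kb apart)
  G[, "rs5"] <- G[, "rs4"]
  flips <- sample.int(n, 30)
  G[flips, "rs5"] <- pmin(2, G[flips, "rs5"] + 1)
  expect_gt(cor(G[, "rs4"], G[, "rs5"])^2, 0.25)
  filt <- filterSnps(weights, G)
  log <- attr(filt, "filter_log")
  expect_false("rs2" %in% filt$snp)       # A/T ambiguous
  expect_false("rs3" %in% filt$snp)       # sample MAF ~0.01 < 0.05
  expect_false("rs5" %in% filt$snp)       # clumped against rs4 (worse p)
  expect_true("rs4" %in% filt$snp)
  expect_false("rs6" %in% filt$snp)       # p = 1e-4 > 5e-8
  expect_equal(log$ambiguous, 1)
  expect_equal(log$low_maf, 1)
  expect_equal(log$clumped, 1)
  expect_equal(log$gwas_p, 1)
  expect_setequal(filt$snp, c("rs1", "rs4"))
})

test_that("weight-table SNPs absent from genotypes are skipped with warning", {
  fx <- prs_fixture()
  w <- rbind(fx$weights,
             data.frame(snp = "rs99", chrom = "5", pos = 1e6,
                        effect_allele = "A", other_allele = "G",
                        beta = 1, gwas_p = 1e-9))
  expect_warning(filt <- filterSnps(w, fx$G), "absent from genotypes")
  expect_equal(attr(filt, "filter_log")$missing_in_genotypes, 1)
})

test_that("APOE region split is a closed-interval partition", {
  fx <- prs_fixture()
  sp <- splitApoeRegion(fx$weights)
  expect_setequal(sp$apoe$snp, c("rs3", "rs4"))   # chr19 at 45 and 44.9 Mb
  expect_setequal(sp$no_apoe$snp, c("rs1", "rs2", "rs5"))
  expect_setequal(c(sp$apoe$snp, sp$no_apoe$snp), fx$weights$snp)
  # boundary inclusion
  wb <- fx$weights[3, , drop = FALSE]; wb$pos <- 44.4e6
  expect_equal(nrow(splitApoeRegion(wb)$apoe), 1)
  # empty table -> two empty tables
  se <- splitApoeRegion(fx$weights[0, , drop = FALSE])
  expect_equal(nrow(se$apoe), 0); expect_equal(nrow(se$no_apoe), 0)
})

test_that("PLINK .raw round-trips through the reader", {
  fx <- prs_fixture(seed = 11)
  path <- tempfile(fileext = ".raw")
  writeRaw(fx$G, path)
  G2 <- readRaw(path)
  expect_equal(unname(G2), unname(fx$G))
  expect_equal(attr(G2, "counted_allele"), attr(fx$G, "counted_allele"))
  expect_equal(rownames(G2), rownames(fx$G))
})
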