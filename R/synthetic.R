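#' Create a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: a
#' two-task, two-wave cohort measured on a bi-hemispheric parcellation with
#' planted community structure (signal-to-noise 1, six communities), a
#' planted canonical correlation of 0.5 between the adversity/PRS block and
#' psychopathology, a spatially autocorrelated transcriptome with 27
#' expression-lowering and 45 expression-raising stress genes loaded at 0.6
#' on a smooth cortical pattern, receptor maps loaded at 0.45 on the same
#' pattern, and moderated-mediation paths a = 0.5, b_low = 0, b_high = 0.4.
#'
#' @param n_subjects,n_parcels,n_timepoints,n_genes,n_networks,n_snps
#'   problem sizes; see [SimulationConfig-class].
#' @param n_sites,n_items design sizes (scanner sites; psychopathology items
#'   per wave).
#' @param canonical_r,community_shift_fraction,snr,spatial_rho planted
#'   structure.
#' @param gene_loading,receptor_loading planted molecular loadings.
#' @param n_stress_low,n_stress_high stress-gene set sizes.
#' @param effect_a,effect_b_low,effect_b_high planted mediation paths.
#' @param item_severity probability an item scores above 0.
#' @param seed RNG seed.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(n_subjects = 300, n_parcels = 297,
                             n_timepoints = 400, n_genes = 15000,
                             n_networks = 6, n_snps = 40, n_sites = 3,
                             n_items = 112, canonical_r = 0.5,
                             community_shift_fraction = 0.2, snr = 1,
                             spatial_rho = 0.3, gene_loading = 0.6,
                             receptor_loading = 0.45, n_stress_low = 27,
                             n_stress_high = 45, effect_a = 0.5,
                             effect_b_low = 0, effect_b_high = 0.4,
                             item_severity = 0.35, seed = 1) {
  new("SimulationConfig", n_subjects = n_subjects, n_parcels = n_parcels,
      n_timepoints = n_timepoints, n_genes = n_genes,
      n_networks = n_networks, n_snps = n_snps, n_sites = n_sites,
      n_items = n_items, canonical_r = canonical_r,
      community_shift_fraction = community_shift_fraction, snr = snr,
      spatial_rho = spatial_rho, gene_loading = gene_loading,
      receptor_loading = receptor_loading, n_stress_low = n_stress_low,
      n_stress_high = n_stress_high, effect_a = effect_a,
      effect_b_low = effect_b_low, effect_b_high = effect_b_high,
      item_severity = item_severity, seed = seed)
}

# Fibonacci lattice of n near-uniform points on the unit sphere
fibonacci_sphere <- function(n, offset = 0) {
  i <- seq_len(n) - 0.5 + offset
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta),
        z = cos(phi))
}

#' Parcel metadata on two mirrored unit hemispheres
#'
#' Places left-hemisphere centroids on a Fibonacci lattice of the unit
#' sphere and mirrors the lattice across x for the right hemisphere (right
#' parcel j is the exact mirror of left parcel j), so the spin test acts on
#' true spherical geometry and bilaterally mirrored maps stay mirrored
#' under its mirrored rotations.  Native networks are contiguous blocks of
#' parcels.
#'
#' @param config a [SimulationConfig-class].
#' @return data.frame `parcel_id, hemisphere, x, y, z, network`.
#' @export
simulateParcelMeta <- function(config) {
  n <- config@n_parcels
  nL <- ceiling(n / 2); nR <- n - nL
  left <- fibonacci_sphere(nL)
  right <- left[seq_len(nR), , drop = FALSE]
  right[, "x"] <- -right[, "x"]
  xyz <- rbind(left, right)
  net <- sort(rep_len(seq_len(config@n_networks), n))
  data.frame(parcel_id = sprintf("p%03d", seq_len(n)),
             hemisphere = rep(c("L", "R"), c(nL, nR)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             network = paste0("net", net), stringsAsFactors = FALSE)
}

# Planted community plans: the base partition equals the native systems;
# the shifted plan moves round(fraction * n) parcels to a different
# community for the second task.
planted_partitions <- function(config, parcel_meta) {
  base <- as.integer(factor(parcel_meta$network))
  n <- config@n_parcels
  n_shift <- round(config@community_shift_fraction * n)
  shifted <- base
  if (n_shift > 0) {
    move <- sample.int(n, n_shift)
    if (config@n_networks > 1) {
      shifted[move] <- vapply(base[move], function(g) {
        sample(setdiff(seq_len(config@n_networks), g), 1)
      }, 0L)
    }
  }
  list(MID = base, SST = shifted,
       shifted_parcels = if (n_shift > 0) move else integer(0))
}

#' Simulate parcellated task time series with planted communities
#'
#' Each parcel's series is `sqrt(snr)` times its community's latent signal
#' plus independent unit Gaussian noise.  The community plan of the first
#' task (MID) equals the native systems; the second task (SST) reassigns
#' `round(community_shift_fraction x n_parcels)` parcels, and wave 2 reuses
#' the same plan.
#'
#' @param config a [SimulationConfig-class].
#' @param parcel_meta from [simulateParcelMeta()]; regenerated if `NULL`.
#' @param partitions planted plans from an earlier call (for regeneration).
#' @return list with `series` (per subject, the four named parcels x time
#'   matrices MID_w1, SST_w1, MID_w2, SST_w2) and `partitions`.
#' @export
simulateTimeSeries <- function(config, parcel_meta = NULL,
                               partitions = NULL) {
  validObject(config)
  if (config@n_timepoints < 10)
    stop("n_timepoints < 10 gives unstable correlations")
  if (is.null(parcel_meta)) parcel_meta <- simulateParcelMeta(config)
  if (is.null(partitions)) partitions <- planted_partitions(config, parcel_meta)
  n <- config@n_parcels; Tt <- config@n_timepoints
  ids <- parcel_meta$parcel_id
  layer_task <- c(MID_w1 = "MID", SST_w1 = "SST", MID_w2 = "MID",
                  SST_w2 = "SST")
  series <- vector("list", config@n_subjects)
  # between-subject heterogeneity in community coherence: individual SNRs
  # scatter lognormally (sd 0.3 on the log scale) around the configured SNR
  subject_snr <- config@snr * exp(rnorm(config@n_subjects, 0, 0.3))
  for (s in seq_len(config@n_subjects)) {
    sq <- sqrt(subject_snr[s])
    subj <- lapply(layer_task, function(task) {
      g <- partitions[[task]]
      Z <- matrix(rnorm(config@n_networks * Tt), config@n_networks, Tt)
      X <- sq * Z[g, , drop = FALSE] + matrix(rnorm(n * Tt), n, Tt)
      rownames(X) <- ids
      X
    })
    names(subj) <- names(layer_task)
    series[[s]] <- subj
  }
  names(series) <- sprintf("sub%04d", seq_len(config@n_subjects))
  list(series = series, partitions = partitions, subject_snr = subject_snr)
}

# discretize a latent vector into {0,1,2} with marginal P(>0) = severity
discretize_items <- function(latent, severity) {
  th1 <- qnorm(1 - severity)
  th2 <- qnorm(1 - severity / 3)
  as.integer(latent > th1) + as.integer(latent > th2)
}

#' Simulate the phenotype table with a planted canonical correlation
#'
#' A latent risk factor `u` and a latent psychopathology factor
#' `t = canonical_r * u + sqrt(1 - canonical_r^2) * e` generate: adversity
#' scales at two waves (deprivation, family conflict, and neighbourhood
#' safety coded so that higher = safer, to exercise reverse coding), three
#' PRS columns (the APOE-region score is deliberately null-loaded),
#' item-level psychopathology in \{0, 1, 2\} at two waves obtained by
#' thresholding item latents, and covariates (age, sex, handedness, medical
#' problems, site, per-task motion) independent of the planted factors.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `phenotypes` (data.frame) and `latents` (u, t per
#'   subject).
#' @export
simulatePhenotypes <- function(config) {
  validObject(config)
  if (config@canonical_r >= 1) stop("canonical_r must be < 1")
  n <- config@n_subjects
  r <- config@canonical_r
  u <- rnorm(n)
  tl <- r * u + sqrt(1 - r^2) * rnorm(n)
  lam <- 0.85
  noise <- function() rnorm(n)
  mk <- function(load, latent) load * latent + sqrt(1 - load^2) * noise()
  ph <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    deprivation_w1 = mk(lam, u), deprivation_w2 = mk(lam, u),
    conflict_w1 = mk(lam, u), conflict_w2 = mk(lam, u),
    safety_w1 = 4.2 - 0.8 * mk(lam, u), safety_w2 = 4.2 - 0.8 * mk(lam, u),
    prs_mdd = mk(lam, u), prs_ad_noapoe = mk(lam, u),
    prs_ad_apoe = rnorm(n),
    age = rnorm(n, 11, 0.62), sex = rbinom(n, 1, 0.48),
    handedness = rbinom(n, 1, 0.17),
    med_problems = rbinom(n, 3, 0.08),
    site = sample.int(config@n_sites, n, replace = TRUE),
    motion_mid = exp(rnorm(n, -1.5, 0.4)),
    motion_sst = exp(rnorm(n, -1.5, 0.4)),
    stringsAsFactors = FALSE)
  lam_item <- 0.6
  for (wave in c("wA", "wB")) {
    tw <- if (wave == "wA") tl else 0.8 * tl + 0.6 * rnorm(n)
    items <- vapply(seq_len(config@n_items), function(j) {
      discretize_items(lam_item * tw + sqrt(1 - lam_item^2) * rnorm(n),
                       config@item_severity)
    }, integer(n))
    colnames(items) <- sprintf("psy_%s_item%03d", wave,
                               seq_len(config@n_items))
    ph <- cbind(ph, as.data.frame(items))
  }
  list(phenotypes = ph, latents = list(u = u, t = tl))
}

#' Total psychopathology score of a wave
#'
#' Sum of the response values on all items of that wave.
#'
#' @param phenotypes the phenotype data.frame.
#' @param wave "wA" or "wB".
#' @return integer vector of totals.
#' @export
psychopathologyTotal <- function(phenotypes, wave = "wA") {
  cols <- grep(paste0("^psy_", wave, "_item"), names(phenotypes))
  if (!length(cols)) stop("no items for wave ", wave)
  as.integer(rowSums(phenotypes[, cols, drop = FALSE]))
}

# Cholesky factor of the exponential spatial kernel over the left-hemisphere
# centroids; molecular maps are generated on the left and mirrored to the
# right (expression and receptor maps are treated as bilaterally symmetric,
# which is also the structure the mirrored spin rotations preserve).
spatial_factor <- function(parcel_meta, rho) {
  left <- parcel_meta$hemisphere == "L"
  n <- sum(left)
  if (rho <= 0) return(diag(n))
  D <- as.matrix(dist(as.matrix(parcel_meta[left, c("x", "y", "z")])))
  K <- exp(-D / rho)
  t(chol(K + diag(1e-8, n)))
}

# draw k smooth mirrored fields over all parcels (left lattice mirrored to
# right; right parcel j duplicates left parcel j by construction)
smooth_fields_sym <- function(parcel_meta, rho, k) {
  Lf <- spatial_factor(parcel_meta, rho)
  nL <- sum(parcel_meta$hemisphere == "L")
  nR <- sum(parcel_meta$hemisphere == "R")
  f <- Lf %*% matrix(rnorm(nL * k), nL, k)
  rbind(f, f[seq_len(nR), , drop = FALSE])
}

#' Simulate a spatially autocorrelated parcel-by-gene matrix
#'
#' Gene maps are smooth fields (exponential kernel of length `spatial_rho`
#' over centroid distances).  A designated set of `n_stress_high` genes is
#' loaded `+gene_loading`, and `n_stress_low` genes `-gene_loading`, on one
#' smooth reference pattern; remaining genes are pattern-free.
#'
#' @param config a [SimulationConfig-class].
#' @param parcel_meta from [simulateParcelMeta()].
#' @return list with `gene_matrix` (parcels x genes), `stress_low`,
#'   `stress_high` (symbol vectors), `pattern` (the reference map) and
#'   `loading`.
#' @export
simulateGeneMatrix <- function(config, parcel_meta) {
  validObject(config)
  n <- nrow(parcel_meta); ng <- config@n_genes
  nl <- config@n_stress_low; nh <- config@n_stress_high
  if (ng < nl + nh) stop("n_genes must be at least the planted set sizes")
  pattern <- as.vector(smooth_fields_sym(parcel_meta, config@spatial_rho, 1))
  pattern <- (pattern - mean(pattern)) / sd(pattern)
  Fm <- smooth_fields_sym(parcel_meta, config@spatial_rho, ng)
  Fm <- standardize_cols(Fm)
  load <- numeric(ng)
  low_idx <- seq_len(nl)
  high_idx <- nl + seq_len(nh)
  load[low_idx] <- -config@gene_loading
  load[high_idx] <- config@gene_loading
  G <- outer(pattern, load) + sweep(Fm, 2, sqrt(1 - load^2), "*")
  symbols <- c(sprintf("STRL%03d", seq_len(nl)),
               sprintf("STRH%03d", seq_len(nh)),
               sprintf("GENE%05d", seq_len(ng - nl - nh)))
  dimnames(G) <- list(parcel_meta$parcel_id, symbols)
  list(gene_matrix = G, stress_low = symbols[low_idx],
       stress_high = symbols[high_idx], pattern = pattern,
       loading = config@gene_loading)
}

#' Simulate receptor density maps correlated with a brain pattern
#'
#' D2, GABA and GLU5R maps are loaded `receptor_loading` on the reference
#' pattern; the serotonin maps (HT1a, HT1b, HT2, HT4, HT6) and ACh are
#' pattern-free smooth fields.  Columns are standardized across parcels.
#'
#' @param config a [SimulationConfig-class].
#' @param parcel_meta parcel table.
#' @param pattern reference per-parcel map (e.g. from
#'   [simulateGeneMatrix()]).
#' @return parcels x 9 standardized receptor matrix.
#' @export
simulateReceptors <- function(config, parcel_meta, pattern) {
  rec <- c("D2", "GABA", "GLU5R", "HT1a", "HT1b", "HT2", "HT4", "HT6",
           "ACh")
  lam <- setNames(rep(0, length(rec)), rec)
  lam[c("D2", "GABA", "GLU5R")] <- config@receptor_loading
  n <- nrow(parcel_meta)
  fields <- smooth_fields_sym(parcel_meta, config@spatial_rho, length(rec))
  M <- vapply(seq_along(rec), function(k) {
    f <- fields[, k]
    f <- (f - mean(f)) / sd(f)
    lam[rec[k]] * pattern + sqrt(1 - lam[rec[k]]^2) * f
  }, numeric(n))
  colnames(M) <- rec
  rownames(M) <- parcel_meta$parcel_id
  standardize_cols(M)
}

#' Simulate an additive genotype table and GWAS weight table
#'
#' Additive codes are drawn binomially at per-SNP minor allele frequencies.
#' The weight table deliberately contains two ambiguous SNPs (A/T, G/C),
#' two low-MAF SNPs (0.01), three GWAS-nonsignificant SNPs and three SNPs
#' inside the APOE region of chromosome 19, to exercise every filter; a few
#' genotype columns count the non-effect allele to exercise orientation
#' flips.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `genotypes` (subjects x SNPs, `counted_allele`
#'   attribute), `weights`, `maf` (true frequencies) and `expected_kept`
#'   (SNP ids planted to survive all filters at the default thresholds).
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  n <- config@n_subjects; m <- config@n_snps
  snp <- sprintf("rs%05d", seq_len(m))
  maf <- runif(m, 0.1, 0.45)
  kinds <- rep("ok", m)
  if (m >= 10) {
    kinds[1:2] <- "ambiguous"
    kinds[3:4] <- "low_maf"
    kinds[5:7] <- "nonsig"
  }
  maf[kinds == "low_maf"] <- 0.01
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  al <- t(vapply(seq_len(m), function(k) {
    if (kinds[k] == "ambiguous") {
      if (k %% 2 == 0) c("A", "T") else c("G", "C")
    } else pairs[[1 + (k %% length(pairs))]]
  }, character(2)))
  chrom <- as.character(rep_len(c(1:18, 20:22), m))
  pos <- sample.int(2e8, m)
  if (m >= 10) {
    apoe_idx <- (m - 2):m
    chrom[apoe_idx] <- "19"
    pos[apoe_idx] <- round(seq(44.5e6, 46.4e6, length.out = 3))
  }
  gwas_p <- 10^-runif(m, 9, 20)
  gwas_p[kinds == "nonsig"] <- 10^-runif(sum(kinds == "nonsig"), 2, 5)
  beta <- rnorm(m, 0, 0.05)
  weights <- data.frame(snp = snp, chrom = chrom, pos = pos,
                        effect_allele = al[, 1], other_allele = al[, 2],
                        beta = beta, gwas_p = gwas_p,
                        stringsAsFactors = FALSE)
  G <- vapply(seq_len(m), function(k) rbinom(n, 2, maf[k]), numeric(n))
  dimnames(G) <- list(sprintf("sub%04d", seq_len(n)), snp)
  counted <- al[, 1]
  flip <- seq_len(m) %% 7 == 0    # some columns count the other allele
  counted[flip] <- al[flip, 2]
  G[, flip] <- 2 - G[, flip, drop = FALSE]
  attr(G, "counted_allele") <- setNames(counted, snp)
  expected_kept <- snp[kinds == "ok"]
  list(genotypes = G, weights = weights, maf = maf,
       expected_kept = expected_kept)
}

#' Generate the full synthetic bundle
#'
#' Runs every generator under one seeded RNG stream and assembles a
#' [SyntheticBundle-class] whose `truth` record (planted partitions,
#' latents, pattern, loadings, expected surviving SNPs, true PRS) suffices
#' to recompute every planted effect.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SyntheticBundle-class].
#' @export
simulateBundle <- function(config = simulationConfig()) {
  validObject(config)
  set.seed(config@seed)
  parcel_meta <- simulateParcelMeta(config)
  ts <- simulateTimeSeries(config, parcel_meta)
  phen <- simulatePhenotypes(config)
  gm <- simulateGeneMatrix(config, parcel_meta)
  receptors <- simulateReceptors(config, parcel_meta, gm$pattern)
  gt <- simulateGenotypes(config)

  kept <- gt$weights[gt$weights$snp %in% gt$expected_kept, , drop = FALSE]
  counted <- attr(gt$genotypes, "counted_allele")
  true_prs <- setNames(numeric(config@n_subjects),
                       rownames(gt$genotypes))
  for (k in seq_len(nrow(kept))) {
    g <- gt$genotypes[, kept$snp[k]]
    if (counted[kept$snp[k]] == kept$other_allele[k]) g <- 2 - g
    true_prs <- true_prs + kept$beta[k] * g
  }

  truth <- list(
    base_partition = ts$partitions$MID,
    task_partition = ts$partitions$SST,
    shifted_parcels = ts$partitions$shifted_parcels,
    subject_snr = ts$subject_snr,
    latent_u = phen$latents$u, latent_t = phen$latents$t,
    canonical_r = config@canonical_r,
    pattern = gm$pattern, gene_loading = gm$loading,
    receptor_loading = config@receptor_loading,
    expected_kept_snps = gt$expected_kept, true_prs = true_prs,
    true_maf = gt$maf,
    mediation = list(a = config@effect_a, b_low = config@effect_b_low,
                     b_high = config@effect_b_high))

  new("SyntheticBundle", config = config, time_series = ts$series,
      phenotypes = phen$phenotypes, genotypes = gt$genotypes,
      weights = gt$weights, parcel_meta = parcel_meta,
      gene_matrix = gm$gene_matrix,
      gene_symbols = colnames(gm$gene_matrix),
      receptor_maps = receptors, stress_low = gm$stress_low,
      stress_high = gm$stress_high, truth = truth)
}

#' Simulate data for the moderated mediation model
#'
#' Predictor X standard normal; binary moderator W; mediator
#' `M = a X + e`; outcome `Y = 0.1 X + (b_low (1 - W) + b_high W) M + e`,
#' homoscedastic unit noise.  The implied interaction coefficient is
#' `b_high - b_low` and the index of moderated mediation
#' `a (b_high - b_low)`.
#'
#' @param n sample size.
#' @param a,b_low,b_high planted paths.
#' @param seed RNG seed.
#' @param moderator "independent" (Bernoulli 0.5) or "split" (median split
#'   of X, as in the observational design).
#' @return data.frame with columns X, M, W, Y.
#' @export
simulateMediationData <- function(n, a = 0.5, b_low = 0, b_high = 0.4,
                                  seed = 1, moderator = "independent") {
  set.seed(seed)
  X <- rnorm(n)
  W <- if (moderator == "independent") rbinom(n, 1, 0.5) else medianSplit(X)
  M <- a * X + rnorm(n)
  Y <- 0.1 * X + (b_low * (1 - W) + b_high * W) * M + rnorm(n)
  data.frame(X = X, M = M, W = W, Y = Y)
}
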