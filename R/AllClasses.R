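#' @import methods
#' @importFrom stats cor median quantile sd rnorm runif rbinom coef lm
#'   complete.cases setNames aggregate IQR qnorm resid predict df.residual pt
#' @importFrom utils head read.table write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib neurodevnet, .registration = TRUE
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator: cohort and atlas sizes,
#' the planted canonical correlation between the risk and psychopathology
#' blocks, the fraction of parcels whose community assignment differs between
#' the two task layers, spatial autocorrelation length of molecular maps,
#' planted mediation paths, and the RNG seed.  Identical configs (including
#' the seed) produce bit-identical bundles.
#'
#' @slot n_subjects number of simulated participants.
#' @slot n_parcels number of cortical parcels (split across two hemispheres).
#' @slot n_timepoints time points per task run.
#' @slot n_genes number of genes in the parcel-by-gene expression matrix.
#' @slot n_networks number of planted functional communities / native systems.
#' @slot n_snps number of SNPs in the genotype table.
#' @slot n_sites number of synthetic scanner sites.
#' @slot n_items number of psychopathology items (0/1/2 Likert) per wave.
#' @slot canonical_r planted latent correlation between the adversity/PRS
#'   block and the psychopathology block, in [0, 1).
#' @slot community_shift_fraction fraction of parcels reassigned to a
#'   different community in the second task layer.
#' @slot snr signal-to-noise ratio of the community latent in the time series.
#' @slot spatial_rho autocorrelation length (exponential kernel on centroid
#'   distances; 0 disables smoothing) for gene and receptor maps.
#' @slot gene_loading planted loading of stress genes on the spatial pattern.
#' @slot receptor_loading planted correlation of receptor maps with the
#'   spatial pattern.
#' @slot n_stress_low,n_stress_high planted sizes of the two stress-gene sets.
#' @slot effect_a,effect_b_low,effect_b_high planted moderated-mediation
#'   paths (predictor to mediator; mediator to outcome in each moderator arm).
#' @slot item_severity probability mass placed on item responses 1 and 2.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig", representation(
  n_subjects = "numeric", n_parcels = "numeric", n_timepoints = "numeric",
  n_genes = "numeric", n_networks = "numeric", n_snps = "numeric",
  n_sites = "numeric", n_items = "numeric",
  canonical_r = "numeric", community_shift_fraction = "numeric",
  snr = "numeric", spatial_rho = "numeric", gene_loading = "numeric",
  receptor_loading = "numeric", n_stress_low = "numeric",
  n_stress_high = "numeric", effect_a = "numeric", effect_b_low = "numeric",
  effect_b_high = "numeric", item_severity = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  cnt <- c(n_subjects = object@n_subjects, n_parcels = object@n_parcels,
           n_timepoints = object@n_timepoints, n_genes = object@n_genes,
           n_networks = object@n_networks, n_snps = object@n_snps,
           n_sites = object@n_sites, n_items = object@n_items)
  if (any(cnt < 1) || any(cnt != round(cnt)))
    return("all counts must be integers >= 1")
  if (object@canonical_r < 0 || object@canonical_r >= 1)
    return("canonical_r must lie in [0, 1)")
  if (object@community_shift_fraction < 0 || object@community_shift_fraction > 1)
    return("community_shift_fraction must lie in [0, 1]")
  if (object@snr < 0) return("snr must be nonnegative")
  if (object@spatial_rho < 0) return("spatial_rho must be nonnegative")
  if (object@n_genes < object@n_stress_low + object@n_stress_high)
    return("n_genes must be at least |stress_low| + |stress_high|")
  TRUE
})

#' Bundle of synthetic inputs with planted ground truth
#'
#' Container for everything the pipeline consumes: per subject x task x wave
#' parcel-by-time matrices, a phenotype table, additive genotypes plus a GWAS
#' weight table, parcel metadata (hemisphere, spherical centroid, native
#' network), a parcel-by-gene expression matrix, parcel-by-receptor density
#' maps, the two directional stress-gene lists, and a `truth` record from
#' which every planted effect can be recomputed.
#'
#' @slot config the [SimulationConfig-class] that produced the bundle.
#' @slot time_series nested list `[[subject]][[task_wave]]` of parcels x time
#'   matrices; task_wave labels are `MID_w1`, `SST_w1`, `MID_w2`, `SST_w2`.
#' @slot phenotypes data.frame of adversity scales, item-level psychopathology
#'   at two waves, planted PRS columns and covariates.
#' @slot genotypes subject x SNP additive-code matrix (PLINK .raw dialect via
#'   [writeSyntheticBundle()]).
#' @slot weights GWAS weight table (snp, chrom, pos, effect/other allele,
#'   beta, gwas_p).
#' @slot parcel_meta data.frame `parcel_id, hemisphere, x, y, z, network`.
#' @slot gene_matrix parcels x genes expression matrix.
#' @slot gene_symbols character vector of gene symbols.
#' @slot receptor_maps parcels x receptor matrix.
#' @slot stress_low,stress_high planted stress-gene symbol sets.
#' @slot truth list of planted parameters (partitions, latents, true PRS, ...).
#' @export
setClass("SyntheticBundle", representation(
  config = "SimulationConfig", time_series = "list", phenotypes = "data.frame",
  genotypes = "matrix", weights = "data.frame", parcel_meta = "data.frame",
  gene_matrix = "matrix", gene_symbols = "character",
  receptor_maps = "matrix", stress_low = "character",
  stress_high = "character", truth = "list"))

setValidity("SyntheticBundle", function(object) {
  ids <- object@parcel_meta$parcel_id
  if (nrow(object@gene_matrix) && !identical(rownames(object@gene_matrix), ids))
    return("gene_matrix rows must match parcel_meta parcel ids")
  if (nrow(object@receptor_maps) && !identical(rownames(object@receptor_maps), ids))
    return("receptor_maps rows must match parcel_meta parcel ids")
  if (length(intersect(object@stress_low, object@stress_high)))
    return("stress_low and stress_high must be disjoint")
  TRUE
})

#' Task/wave connectivity matrix of Fisher-z scores
#'
#' Symmetric parcel x parcel matrix of Fisher z-transformed Pearson
#' correlations with a zero diagonal.  After [zeroNegative()] all entries are
#' nonnegative, which is the form entering the multilayer community analyses.
#'
#' @slot values symmetric numeric matrix (parcels x parcels).
#' @slot task,wave labels (e.g. "MID", "w1").
#' @slot parcel_ids ordered parcel identifiers.
#' @slot n_zeroed number of negative entries set to zero (NA before
#'   thresholding).
#' @export
setClass("ConnectivityMatrix", representation(
  values = "matrix", task = "character", wave = "character",
  parcel_ids = "character", n_zeroed = "numeric"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(!is.finite(v))) return("values must be finite")
  if (max(abs(v - t(v))) > 1e-8) return("values must be symmetric")
  if (any(diag(v) != 0)) return("diagonal must be zero")
  if (length(object@parcel_ids) != nrow(v))
    return("parcel_ids length must match matrix dimension")
  TRUE
})

#' Node-aligned multilayer network
#'
#' Ordered connectivity layers (canonically MID-w1, SST-w1, MID-w2, SST-w2)
#' sharing one parcel set, joined by uniform interlayer coupling of strength
#' omega along `coupling_pairs` (by default the 4-cycle: between-task within
#' wave and within-task between waves).  `gamma` is the per-layer resolution
#' of the modularity null term.
#'
#' @slot layers list of [ConnectivityMatrix-class].
#' @slot coupling_pairs integer matrix with two columns of layer indices.
#' @slot omega interlayer coupling strength (>= 0).
#' @slot gamma per-layer resolution parameter(s) (> 0), recycled to layers.
#' @export
setClass("MultilayerNetwork", representation(
  layers = "list", coupling_pairs = "matrix", omega = "numeric",
  gamma = "numeric"))

setValidity("MultilayerNetwork", function(object) {
  if (!length(object@layers)) return("at least one layer required")
  ids <- lapply(object@layers, function(l) l@parcel_ids)
  if (length(unique(ids)) != 1) return("all layers must share parcel_ids")
  if (object@omega < 0) return("omega must be >= 0")
  if (any(object@gamma <= 0)) return("gamma must be > 0")
  cp <- object@coupling_pairs
  if (nrow(cp) && (any(cp < 1) || any(cp > length(object@layers))))
    return("coupling_pairs reference invalid layers")
  TRUE
})

#' Ensemble of multilayer partitions
#'
#' Community labels per (iteration, layer, parcel) from repeated restarts of
#' the multilayer Louvain optimiser, with the modularity attained at each
#' restart.  Labels are comparable across layers within an iteration
#' (communities span layers), which is what makes flexibility well defined.
#'
#' @slot labels integer array `[iteration, layer, parcel]`.
#' @slot q_values modularity per iteration.
#' @slot layer_names,parcel_ids dimension labels.
#' @export
setClass("PartitionEnsemble", representation(
  labels = "array", q_values = "numeric", layer_names = "character",
  parcel_ids = "character"))

setValidity("PartitionEnsemble", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3) return("labels must be a 3-d array")
  if (d[1] < 1) return("at least one iteration required")
  if (length(object@q_values) != d[1])
    return("q_values must have one entry per iteration")
  if (any(object@labels < 0)) return("labels must be nonnegative")
  TRUE
})

#' Cross-validated multivariate (CCA) result
#'
#' Fold-wise canonical weights plus pooled out-of-sample variate scores, the
#' cross-fold correlation between the two predicted variates, its permutation
#' p-value, and bootstrap reliability of variable-level loadings and
#' standardized coefficients.
#'
#' @slot fold_assignment integer test-fold index per observation.
#' @slot weights_x,weights_y per-fold weight matrices (variables x folds).
#' @slot variate_x,variate_y pooled test-fold predicted variate scores.
#' @slot cross_fold_r correlation of the pooled predicted variates.
#' @slot perm_p permutation p-value (NA until tested).
#' @slot loadings,std_coefs data.frames with estimate, lower, upper per
#'   variable (NULL until bootstrapped).
#' @export
setClass("CvMultivariateResult", representation(
  fold_assignment = "integer", weights_x = "matrix", weights_y = "matrix",
  variate_x = "numeric", variate_y = "numeric", cross_fold_r = "numeric",
  perm_p = "numeric", loadings = "ANY", std_coefs = "ANY"))

setValidity("CvMultivariateResult", function(object) {
  if (length(object@variate_x) != length(object@variate_y))
    return("pooled variates must have equal length")
  if (length(object@fold_assignment) != length(object@variate_x))
    return("fold_assignment must cover every observation")
  if (abs(object@cross_fold_r) > 1 + 1e-12)
    return("cross_fold_r must lie in [-1, 1]")
  if (!is.na(object@perm_p) && (object@perm_p <= 0 || object@perm_p > 1))
    return("perm_p must lie in (0, 1]")
  TRUE
})

#' Behavioural / gene PLS result
#'
#' First-latent-variable summary of a partial least squares correlation:
#' saliences, singular values, pooled test-fold predicted LV scores, the
#' permutation p of the first singular structure, and the bootstrap-robust
#' elements (parcels or genes whose 99.9% CI excludes zero).
#'
#' @slot saliences element weights; for behavioural PLS a conditions x
#'   parcels matrix (outer product structure of the first LV), for gene PLS a
#'   genes x 1 matrix.
#' @slot condition_weights first left singular vector over conditions
#'   (behavioural PLS) or 1 (gene PLS).
#' @slot singular_values nonincreasing singular values of the stacked
#'   correlation matrix.
#' @slot predicted_scores pooled test-fold LV scores (per subject for
#'   behavioural PLS, per parcel for gene PLS).
#' @slot behav_correlations data.frame per condition: correlation of the
#'   behavioural variable with predicted brain scores, with CI bounds.
#' @slot statistic observed test statistic used for the permutation test.
#' @slot perm_p permutation (or spin) p-value.
#' @slot element_loadings data.frame per element: estimate, lower, upper.
#' @slot robust_elements names of elements whose CI excludes zero.
#' @export
setClass("PlsResult", representation(
  saliences = "matrix", condition_weights = "numeric",
  singular_values = "numeric", predicted_scores = "numeric",
  behav_correlations = "ANY", statistic = "numeric", perm_p = "numeric",
  element_loadings = "ANY", robust_elements = "character"))

setValidity("PlsResult", function(object) {
  sv <- object@singular_values
  if (length(sv) && (any(sv < -1e-12) || is.unsorted(rev(sv), strictly = FALSE)))
    return("singular_values must be nonincreasing and nonnegative")
  if (!is.na(object@perm_p) && (object@perm_p <= 0 || object@perm_p > 1))
    return("perm_p must lie in (0, 1]")
  TRUE
})

#' Set of spatially constrained (spin) permutations
#'
#' Each row is a bijection on parcels obtained by applying one uniform random
#' rotation to the left-hemisphere spherical centroids (and its x-mirrored
#' twin to the right) followed by greedy one-to-one nearest matching, so left
#' parcels map to left parcels and right to right.
#'
#' @slot permutations integer matrix `n_null x n_parcels`; row k maps parcel
#'   j to source parcel `permutations[k, j]`.
#' @slot preserved_hemispheres logical flag.
#' @slot seed RNG seed used.
#' @export
setClass("SpinNullSet", representation(
  permutations = "matrix", preserved_hemispheres = "logical",
  seed = "numeric"))

setValidity("SpinNullSet", function(object) {
  p <- object@permutations
  n <- ncol(p)
  ok <- apply(p, 1, function(r) identical(sort(r), seq_len(n)))
  if (!all(ok)) return("every row must be a permutation of 1..n_parcels")
  TRUE
})

#' Normalized parcel-by-gene expression matrix
#'
#' Values normalized with the robust sigmoid (per sample across genes, then
#' per gene across samples) and rescaled to the unit interval, aggregated
#' within donor then across donors, with a provenance log of the medians and
#' normalized IQRs used.
#'
#' @slot values parcels x genes matrix in [0, 1].
#' @slot gene_symbols,parcel_ids dimension labels.
#' @slot normalization_log list with per-stage medians and IQRs, and parcels
#'   excluded for lacking samples.
#' @export
setClass("GeneExpressionMatrix", representation(
  values = "matrix", gene_symbols = "character", parcel_ids = "character",
  normalization_log = "list"))

setValidity("GeneExpressionMatrix", function(object) {
  v <- object@values
  if (any(v < -1e-12 | v > 1 + 1e-12)) return("values must lie in [0, 1]")
  TRUE
})

#' Directional stress-gene sets
#'
#' The two externally derived gene lists: symbols whose stress-risk alleles
#' reduce expression (`stress_low`) and symbols whose risk alleles increase
#' it (`stress_high`).
#'
#' @slot stress_low,stress_high disjoint character vectors of gene symbols.
#' @export
setClass("StressGeneSets", representation(
  stress_low = "character", stress_high = "character"))

setValidity("StressGeneSets", function(object) {
  if (length(intersect(object@stress_low, object@stress_high)))
    return("stress_low and stress_high must be disjoint")
  TRUE
})

#' Stress-gene overlap test result
#'
#' Counts of robustly positively/negatively gene-LV-correlated genes, their
#' overlap with the two stress sets, and the permutation p-values of the
#' susceptibility and inverse conjunctions against Procrustes-aligned null
#' gene LVs.
#'
#' @slot orig_pos,orig_neg counts of robust positive/negative genes.
#' @slot stress_high_pos,stress_low_pos,stress_high_neg,stress_low_neg
#'   observed overlap counts.
#' @slot p_susceptibility,p_inverse permutation p-values.
#' @slot direction sign of the brain-gene LV correlation the conjunction was
#'   keyed to (+1 or -1).
#' @export
setClass("OverlapResult", representation(
  orig_pos = "numeric", orig_neg = "numeric", stress_high_pos = "numeric",
  stress_low_pos = "numeric", stress_high_neg = "numeric",
  stress_low_neg = "numeric", p_susceptibility = "numeric",
  p_inverse = "numeric", direction = "numeric"))

#' Moderated mediation result
#'
#' Path coefficients of the two OLS models (mediator on predictor; outcome on
#' predictor, mediator, moderator and mediator x moderator), the HC-robust
#' test of the interaction, conditional indirect effects per moderator level
#' with percentile bootstrap CIs, and the index of moderated mediation.
#'
#' @slot a_path predictor-to-mediator coefficient.
#' @slot b_path mediator coefficient in the outcome model (moderator = 0 arm).
#' @slot b_interaction mediator x moderator coefficient.
#' @slot interaction_t,interaction_df,interaction_p HC-robust interaction test.
#' @slot conditional_indirect data.frame per moderator level: effect, lower,
#'   upper.
#' @slot index_modmed,index_se,index_lower,index_upper index of moderated
#'   mediation (a x b_interaction) with bootstrap SE and percentile CI.
#' @slot covariate_coefs named outcome-model covariate coefficients.
#' @slot n_boot_failed bootstrap draws redrawn due to singular fits.
#' @export
setClass("MediationResult", representation(
  a_path = "numeric", b_path = "numeric", b_interaction = "numeric",
  interaction_t = "numeric", interaction_df = "numeric",
  interaction_p = "numeric", conditional_indirect = "data.frame",
  index_modmed = "numeric", index_se = "numeric", index_lower = "numeric",
  index_upper = "numeric", covariate_coefs = "numeric",
  n_boot_failed = "numeric"))

setValidity("MediationResult", function(object) {
  if (abs(object@index_modmed - object@a_path * object@b_interaction) > 1e-10)
    return("index_modmed must equal a_path * b_interaction")
  TRUE
})

#' Polygenic risk score result
#'
#' @slot scores named numeric vector of per-subject scores.
#' @slot n_snps_used number of SNPs surviving all filters and present in the
#'   genotypes.
#' @slot filter_log named counts removed by each filter plus imputation notes.
#' @export
setClass("PrsResult", representation(
  scores = "numeric", n_snps_used = "numeric", filter_log = "list"))
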