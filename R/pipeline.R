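#' Covariate matrix from the phenotype table
#'
#' Chronological age, biological sex, handedness, serious medical problems,
#' scanner-site dummies (first site is the reference) and average
#' modality-specific motion for each task.
#'
#' @param phenotypes phenotype data.frame.
#' @return numeric matrix of covariates.
#' @export
covariateMatrix <- function(phenotypes) {
  site <- factor(phenotypes$site)
  site_d <- NULL
  if (nlevels(site) > 1) {
    site_d <- stats::model.matrix(~site)[, -1, drop = FALSE]
    colnames(site_d) <- paste0("site", levels(site)[-1])
  }
  out <- cbind(age = phenotypes$age, sex = phenotypes$sex,
               handedness = phenotypes$handedness,
               med_problems = phenotypes$med_problems,
               motion_mid = phenotypes$motion_mid,
               motion_sst = phenotypes$motion_sst)
  if (!is.null(site_d)) out <- cbind(out, site_d)
  out
}

#' Adversity/PRS block of a wave
#'
#' Deprivation, family conflict, neighbourhood crime (the safety scale
#' reverse-coded so higher = more crime) plus the three PRS columns.
#'
#' @param phenotypes phenotype data.frame.
#' @param wave 1 or 2.
#' @return numeric matrix.
#' @export
riskBlock <- function(phenotypes, wave = 1) {
  w <- paste0("_w", wave)
  cbind(deprivation = phenotypes[[paste0("deprivation", w)]],
        conflict = phenotypes[[paste0("conflict", w)]],
        crime = -phenotypes[[paste0("safety", w)]],
        prs_mdd = phenotypes$prs_mdd,
        prs_ad_apoe = phenotypes$prs_ad_apoe,
        prs_ad_noapoe = phenotypes$prs_ad_noapoe)
}

#' Run the full analytic cascade on a synthetic (or equivalent) bundle
#'
#' Stage order follows the dependency structure: polygenic scoring and the
#' two phenotype CCAs; connectome construction; multilayer community
#' ensembles with flexibility/recruitment; behavioural PLS of the six
#' condition matrices against the wave-2 risk variate; gene PLS of the
#' brain LV map with spin nulls plus the stress-overlap test; receptor CCA
#' with spin nulls; and the moderated mediation.  A stage failure halts its
#' dependents while independent branches continue.  Resampling counts
#' default to reduced desk-run values; `full = TRUE` switches to the full
#' study counts (100,000 permutations and bootstraps, 50,000 mediation
#' bootstraps, 100 community restarts).
#'
#' @param bundle a [SyntheticBundle-class].
#' @param k_folds cross-validation folds.
#' @param n_perm,n_boot,n_spins,iterations,mediation_boot resampling sizes.
#' @param gamma,omega multilayer modularity parameters.
#' @param seed master seed; every stage derives its own stream from it.
#' @param full use the full study resampling counts.
#' @return list with `manifest` (parameters, per-stage summaries, p-values)
#'   and `results` (the stage objects).
#' @export
runPipeline <- function(bundle, k_folds = 10, n_perm = 999, n_boot = 500,
                        n_spins = 199, iterations = 20,
                        mediation_boot = 1000, gamma = 1, omega = 0.5,
                        seed = 1, full = FALSE) {
  stopifnot(is(bundle, "SyntheticBundle"))
  if (full) {
    n_perm <- 1e5; n_boot <- 1e5; n_spins <- 1e5
    iterations <- 100; mediation_boot <- 5e4
  }
  ph <- bundle@phenotypes
  n <- nrow(ph)
  covars <- covariateMatrix(ph)
  seeds <- derive_seeds(seed, 12)
  manifest <- list(parameters = list(
    k_folds = k_folds, n_perm = n_perm, n_boot = n_boot,
    n_spins = n_spins, iterations = iterations,
    mediation_boot = mediation_boot, gamma = gamma, omega = omega,
    seed = seed, n_subjects = n, n_parcels = bundle@config@n_parcels,
    bundle_seed = bundle@config@seed,
    package_version = as.character(utils::packageVersion("neurodevnet")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")),
    stages = list(), p_values = list())
  results <- list()
  run_stage <- function(name, deps, fn) {
    for (d in deps) {
      if (is.null(results[[d]])) {
        manifest$stages[[name]] <<- list(status = "skipped",
                                         reason = paste("dependency", d, "failed"))
        return(invisible(NULL))
      }
    }
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error")) {
      warning("stage ", name, " failed: ", conditionMessage(out))
      manifest$stages[[name]] <<- list(status = "error",
                                       reason = conditionMessage(out))
      return(invisible(NULL))
    }
    results[[name]] <<- out$object
    manifest$stages[[name]] <<- c(list(status = "ok"), out$summary)
    if (!is.null(out$p)) manifest$p_values[[name]] <<- out$p
    invisible(NULL)
  }

  # -- polygenic scores from the genotype table ----------------------------
  run_stage("prs", character(0), function() {
    w <- suppressWarnings(filterSnps(bundle@weights, bundle@genotypes))
    pr <- computePrs(bundle@genotypes, w)
    smry <- list(n_snps_used = pr@n_snps_used,
                 filter_log = attr(w, "filter_log"))
    if (!is.null(bundle@truth$true_prs))
      smry$cor_with_truth <- cor(pr@scores, bundle@truth$true_prs)
    list(object = pr, summary = smry)
  })

  # -- phenotype CCAs per wave ---------------------------------------------
  Y <- cbind(total_wA = psychopathologyTotal(ph, "wA"),
             total_wB = psychopathologyTotal(ph, "wB"))
  for (wv in 1:2) {
    local({
      wave <- wv
      run_stage(paste0("cca_w", wave), character(0), function() {
        X <- riskBlock(ph, wave)
        res <- crossValidateCca(X, Y, k_folds = k_folds,
                                seed = seeds[wave], covariates = covars,
                                strata = ph$site)
        res <- permutationTest(res, n_perm = n_perm, seed = seeds[wave])
        list(object = res,
             summary = list(cross_fold_r = res@cross_fold_r,
                            perm_p = res@perm_p),
             p = res@perm_p)
      })
    })
  }

  # -- connectomes ---------------------------------------------------------
  run_stage("connectome", character(0), function() {
    mats <- lapply(bundle@time_series, function(subj) {
      lapply(names(subj), function(lw) {
        task <- sub("_w[12]$", "", lw)
        wave <- sub("^.*_(w[12])$", "\\1", lw)
        zeroNegative(correlationMatrix(subj[[lw]], task = task, wave = wave))
      })
    })
    list(object = mats,
         summary = list(n_subjects = length(mats),
                        n_layers = length(mats[[1]])))
  })

  # -- multilayer communities and node metrics -----------------------------
  run_stage("communities", "connectome", function() {
    native <- bundle@parcel_meta$network
    conds <- c("flex_w1", "flex_w2", "recr_MID_w1", "recr_SST_w1",
               "recr_MID_w2", "recr_SST_w2")
    stack <- lapply(conds, function(...) matrix(
      NA_real_, n, bundle@config@n_parcels,
      dimnames = list(NULL, bundle@parcel_meta$parcel_id)))
    names(stack) <- conds
    qmeans <- numeric(n)
    for (s in seq_len(n)) {
      net <- multilayerNetwork(results$connectome[[s]], omega = omega,
                               gamma = gamma)
      ens <- runEnsemble(net, n_iterations = iterations,
                         base_seed = seeds[4] + s * 1000)
      nm <- nodeMetrics(ens, native)
      for (cn in conds) stack[[cn]][s, ] <- nm[[cn]]
      qmeans[s] <- mean(qValues(ens))
    }
    list(object = stack,
         summary = list(mean_q = mean(qmeans),
                        mean_flexibility = mean(stack$flex_w1, na.rm = TRUE),
                        mean_recruitment = mean(stack$recr_SST_w1,
                                                na.rm = TRUE)))
  })

  # -- behavioural PLS against the wave-2 risk variate ---------------------
  run_stage("brain_pls", c("communities", "cca_w2"), function() {
    behaviour <- results$cca_w2@variate_x
    stack <- results$communities
    names(stack) <- c("reorg_T1", "reorg_T2", "segMID_T1", "segSST_T1",
                      "segMID_T2", "segSST_T2")[match(
                        names(stack), c("flex_w1", "flex_w2", "recr_MID_w1",
                                        "recr_SST_w1", "recr_MID_w2",
                                        "recr_SST_w2"))]
    res <- behaviouralPls(stack, behaviour, k_folds = k_folds,
                          n_perm = n_perm, n_boot = n_boot,
                          seed = seeds[5], strata = ph$site)
    list(object = res,
         summary = list(first_singular = res@singular_values[1],
                        variance_accounted = varianceAccounted(res),
                        perm_p = res@perm_p,
                        n_robust = length(res@robust_elements)),
         p = res@perm_p)
  })

  # -- spin null set (shared by gene PLS and receptor CCA) -----------------
  run_stage("spins", "brain_pls", function() {
    sp <- generateSpins(bundle@parcel_meta[
      bundle@parcel_meta$parcel_id %in% names(brainLvMap(results$brain_pls)), ],
      n_null = n_spins, seed = seeds[6])
    list(object = sp, summary = list(n_null = n_spins))
  })

  # -- gene PLS + stress overlap -------------------------------------------
  run_stage("gene_pls", c("brain_pls", "spins"), function() {
    lv <- brainLvMap(results$brain_pls)
    G <- bundle@gene_matrix[names(lv), , drop = FALSE]
    res <- genePls(G, lv, results$spins, k_folds = k_folds,
                   n_boot = n_boot, seed = seeds[7])
    list(object = res,
         summary = list(gene_brain_r = res@statistic, perm_p = res@perm_p,
                        n_robust = length(res@robust_elements)),
         p = res@perm_p)
  })

  run_stage("overlap", "gene_pls", function() {
    sets <- stressGeneSets(bundle@stress_low, bundle@stress_high)
    ov <- overlapTest(results$gene_pls, sets)
    list(object = ov,
         summary = list(orig_pos = ov@orig_pos, orig_neg = ov@orig_neg,
                        p_susceptibility = ov@p_susceptibility,
                        p_inverse = ov@p_inverse),
         p = ov@p_susceptibility)
  })

  # -- receptor CCA --------------------------------------------------------
  run_stage("receptor_cca", c("brain_pls", "spins"), function() {
    lv <- brainLvMap(results$brain_pls)
    maps <- bundle@receptor_maps[names(lv), , drop = FALSE]
    ht <- compositeHt(maps[, "HT1a"], maps[, "HT2"], maps[, "HT4"],
                      maps[, "HT6"])
    maps <- cbind(maps[, c("D2", "GABA", "GLU5R", "HT1b", "ACh")],
                  HT_composite = ht)
    res <- receptorCca(lv, standardizeReceptors(maps), results$spins,
                       k_folds = k_folds, seed = seeds[8])
    list(object = res,
         summary = list(cross_fold_r = res@cross_fold_r,
                        perm_p = res@perm_p),
         p = res@perm_p)
  })

  # -- moderated mediation -------------------------------------------------
  run_stage("mediation", c("cca_w1", "cca_w2", "communities", "brain_pls"),
            function() {
    risk <- rowMeans(cbind(scale(results$cca_w1@variate_x),
                           scale(results$cca_w2@variate_x)))
    lv <- brainLvMap(results$brain_pls)
    cw <- results$brain_pls@condition_weights
    sst <- results$communities$recr_SST_w1[, names(lv), drop = FALSE] %*%
      lv * cw["segSST_T1"] +
      results$communities$recr_SST_w2[, names(lv), drop = FALSE] %*%
      lv * cw["segSST_T2"]
    d <- data.frame(risk = risk, brain = as.numeric(sst),
                    outcome = prepareOutcome(psychopathologyTotal(ph, "wB"),
                                             psychopathologyTotal(ph, "wA")),
                    group = medianSplit(risk), covars, check.names = FALSE)
    res <- fitModeratedMediation(
      d, predictor = "risk", mediator = "brain", outcome = "outcome",
      moderator = "group", covariates = colnames(covars),
      n_boot = mediation_boot, seed = seeds[9])
    list(object = res,
         summary = list(index_modmed = res@index_modmed,
                        index_ci = c(res@index_lower, res@index_upper),
                        interaction_b = res@b_interaction,
                        interaction_p = res@interaction_p),
         p = res@interaction_p)
  })

  list(manifest = manifest, results = results)
}

#' Per-parcel brain LV map of a behavioural PLS result
#'
#' Condition-weighted aggregation of the first-LV saliences: the parcel
#' singular vector scaled by the first singular value.
#'
#' @param pls a [PlsResult-class] from [behaviouralPls()].
#' @return named per-parcel vector.
#' @export
brainLvMap <- function(pls) {
  stopifnot(is(pls, "PlsResult"))
  v <- as.numeric(crossprod(pls@saliences, pls@condition_weights))
  names(v) <- colnames(pls@saliences)
  v
}
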