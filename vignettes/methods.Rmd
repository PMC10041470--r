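---
title: "Methods: multilayer network maturation, molecular correlates and risk pathways"
author: "neurodevnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilayer network maturation, molecular correlates and risk pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodevnet)
```

# The analytic cascade

`neurodevnet` implements a multivariate cascade that links early-life
adversity and polygenic risk to the maturation of task-evoked functional
brain networks, and those network changes to their transcriptomic and
receptor-density correlates and to later psychopathology. The stages, each
exposed as ordinary functions and chained by `runPipeline()`, are:

1. **Polygenic risk scores** (`filterSnps()`, `computePrs()`,
   `splitApoeRegion()`): per-subject weighted sums of risk-allele counts,
   after excluding ambiguous (A/T, G/C) variants, sample minor allele
   frequency < 0.05, GWAS p > 5e-8, and greedy clumping of SNP pairs with
   genotype r² > 0.10 within 500 kb (best GWAS p retained). The
   apolipoprotein-E region is split out as chr19:44.4–46.5 Mb (closed
   interval).
2. **Phenotype CCA** (`crossValidateCca()`): the first canonical mode
   between the adversity/PRS block and global psychopathology, estimated
   with 10-fold cross-validation; the reported correlation is computed on
   the pooled out-of-fold variate scores and tested by permutation.
3. **Task connectomes** (`correlationMatrix()`, `zeroNegative()`):
   parcel-by-parcel Pearson correlations per task and wave, Fisher
   z-transformed (`atanh`, clipped at |r| = 1 − 1e−7 so perfect correlation
   stays finite), negatives set to zero.
4. **Multilayer communities** (`multilayerNetwork()`, `runEnsemble()`):
   generalized-Louvain maximisation of the multilayer modularity
   $$Q = \frac{1}{2\mu}\sum_{ijlr}\left[(w_{ijl}-\gamma_l e_{ijl})\delta_{lr}
   + \delta_{ij}\,\omega_{jlr}\right]\delta(g_{il},g_{jr}),\qquad
   e_{ijl}=\frac{s_{il}s_{jl}}{v_l},$$
   over the four task × wave layers, with resolution γ = 1 and interlayer
   coupling ω = 0.5 on the 4-cycle (between tasks within wave, within task
   between waves). **Flexibility** is the fraction of optimiser restarts in
   which a parcel changes community between the two tasks at a wave;
   **recruitment** is the fraction of a parcel's native-system peers sharing
   its community, averaged over restarts.
5. **Behavioural PLS** (`behaviouralPls()`): SVD of the stacked
   condition-wise correlations between the risk variate and each parcel
   measure (two reorganisation and four segregation conditions), with
   test-fold projection, within-condition permutation of the behaviour for
   significance, and bootstrap CIs (99.9% at the parcel level, 95% at the
   condition level).
6. **Gene PLS and stress overlap** (`genePls()`, `overlapTest()`): the
   brain LV map is correlated gene-wise with the parcel × gene expression
   matrix (folds partition parcels); significance uses spatially
   constrained spins; enrichment of the robust genes for the two
   directional stress sets (27 expression-lowering, 45 expression-raising)
   is tested against Procrustes-aligned null gene LVs.
7. **Receptor CCA** (`receptorCca()`): the brain LV map against
   standardized receptor density maps (serotonin maps HT1a/HT2/HT4/HT6
   averaged into a composite, HT1b separate), spin-based significance.
8. **Moderated mediation** (`fitModeratedMediation()`): OLS path models
   M ~ X and Y ~ X + M + W + M×W (moderation of the mediator→outcome path),
   heteroscedasticity-consistent (HC3 by default) coefficient tests,
   percentile bootstrap for conditional indirect effects a(b + b₃W) and the
   index of moderated mediation a·b₃. The outcome is the square root of the
   later psychopathology total residualised for the square root of the
   earlier one; the moderator is a median split of the risk variate (ties
   go low).

Gene expression preprocessing is available as `robustSigmoidNormalize()`
(the outlier-resistant sigmoid
$x_{norm} = 1/(1+\exp(-(x-\langle x\rangle)/IQR_x))$ with the median and the
normalized interquartile range IQR/1.35, then unit-interval rescaling, per
sample across genes and then per gene across samples) and
`aggregateSamplesToParcels()` (within-donor then across-donor means).

# Numerical and design choices

**Modularity bookkeeping.** Interlayer edges are excluded from the node
strengths $s_{il}$ and layer totals $v_l$ (the chance term is intra-layer by
its printed definition) but included in $2\mu$; the $i=j$ within-layer terms
contribute their chance expectation, so an all-in-one partition of a single
layer scores exactly 0 and the two-disconnected-triangles fixture scores
exactly 0.5.

**Louvain engine.** The optimiser works on the dense supra-modularity matrix
in compiled code. Each restart is deterministic given its seed: node visit
order is reshuffled per pass from an explicit Mersenne-Twister stream; ties
keep the current community; a node detaches into a fresh singleton when
every alternative is strictly worse; convergence tolerance is 1e−10 on the
gain with a 100-pass guard. Each restart runs two hierarchies — one from
singletons and one from a random initial partition — and keeps the better:
singleton-only greedy can provably miss the optimum on small two-layer
networks, while the dual start leaves unambiguous optima (e.g. disconnected
cliques) bit-stable across restarts. Ensembles default to 100 restarts and
diagnostics are averaged over restarts, so "number of times" quantities are
reported as fractions in [0, 1] and are comparable across ensemble sizes.

**Cross-validated CCA orientation.** Canonical weights have an arbitrary
sign per fold. Orienting each fold against the full-sample solution leaks
test-fold information through the orientation: on pure-noise data it
inflates the pooled-variate permutation test to roughly 15% rejections at
the 5% level. The package instead fixes each fold's sign by a fold-local
convention (the coordinate with the largest absolute training weight is
made positive), which orients folds consistently whenever a stable mode
exists and never touches test data.

**Permutation conventions.** All permutation and spin p-values use
$(1+\#\{\text{null} \ge \text{obs}\})/(1+N)$, so the attainable floor is
$1/(N+1)$. Pooled cross-validated scores are only exchangeable within a
fold (each fold projects through different training weights), so the CCA
permutation shuffles within folds; measured on null data this yields 5–7%
rejections at the 5% level and a uniform p distribution, where free
shuffling is anti-conservative. Spin tests compare absolute statistics
(two-sided on the map correlation). The stress-overlap conjunction counts
are small integers with heavy ties, so those two p-values use the mid-p
convention (ties counted half); with strict exceedance the null p
distribution is visibly non-uniform.

**Spin nulls.** Uniform rotations are drawn via normalized quaternions and
applied to the left-hemisphere centroids, with the x-mirrored rotation
applied to the right hemisphere; values are reassigned by greedy one-to-one
nearest matching, so every null is a hemisphere-preserving permutation. The
null assumes the map is (second-order) rotation-invariant within each
hemisphere. Maps with un-mirrored correlation *across* the midline violate
that assumption and inflate any spin test; bilaterally mirrored maps are
exactly the structure the mirrored rotations preserve.

**Bootstrap CIs.** Percentile intervals whose endpoints are order statistics
of the draws; variable-level robustness uses 99.9% intervals, variate- and
condition-level summaries 95%. Mediation bootstrap draws that produce a
rank-deficient refit are redrawn and counted.

# The synthetic cohort

`simulateBundle()` generates every input with known planted structure; its
defaults are the study conditions under which the package's properties are
tested.

* **Geometry**: parcels (default 297) on two unit hemispheres; the left
  hemisphere is a Fibonacci lattice and the right its exact x-mirror, so
  spins act on true spherical geometry. Native systems (default 6) are
  contiguous parcel blocks.
* **Time series** (default 400 time points): parcel signal =
  √SNR × community latent + unit Gaussian noise, SNR 1. The first task uses
  the native systems as its community plan; the second task reassigns a
  fraction (default 0.2) of parcels; wave 2 reuses the plan. Per-subject
  SNR scatters lognormally (sd 0.3 on the log scale) around the configured
  value: without between-subject heterogeneity every subject's
  flexibility/recruitment map is numerically identical and the mediation
  stage would be rank-deficient by construction.
* **Phenotypes**: a latent risk factor u and a latent psychopathology
  factor t with corr(u, t) = `canonical_r` (default 0.5). Adversity scales
  and two of the three PRS columns load 0.85 on u (the APOE-region score is
  deliberately null-loaded); neighbourhood safety is coded so higher =
  safer, exercising reverse coding. Psychopathology items (112 per wave,
  three-point 0/1/2) discretize item latents loading 0.6 on t; totals are
  raw sums. Because indicators are noisy and items ordinal, the observable
  canonical correlation is mildly attenuated relative to the latent one
  (≈ 0.45 at the defaults), which is why recovery tolerances are ±0.1.
  Item severity (P(score > 0) = 0.35) is a free choice; no public item
  distributions exist to calibrate against. Covariates (age, sex,
  handedness, medical problems, 3 synthetic sites, per-task motion) are
  independent of the planted factors.
* **Genotypes** (default 40 SNPs): additive codes drawn binomially at MAFs
  U(0.1, 0.45), with planted ambiguous, rare (MAF 0.01), nonsignificant and
  APOE-region SNPs, and some columns counting the non-effect allele. The
  truth record stores the SNPs expected to survive the default filters and
  the implied true scores. Linkage disequilibrium is not simulated;
  clumping is exercised with constructed correlated pairs in the tests.
* **Molecular maps**: smooth fields from an exponential kernel
  (length-scale `spatial_rho`, default 0.3, on centroid distances),
  generated on the left hemisphere and mirrored to the right — expression
  and receptor maps are treated as bilaterally symmetric. 45
  expression-raising and 27 expression-lowering stress genes load ±0.6 on
  one smooth reference pattern; D2, GABA and GLU5R receptor maps load 0.45
  on the same pattern, serotonin and acetylcholine maps are pattern-free.

What the generator does **not** emulate: haemodynamics and autocorrelated
scanner noise, realistic LD, site or motion confounding correlated with
risk, donor-level expression artefacts, and any subject-level coupling
between risk and network topology (the planted brain-side and
phenotype-side structures are independent unless the user wires them).
Passing tests therefore certify the estimators and their calibration, not
performance on real cohort data.

# Problem sizes and determinism

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen as the package's own reduced defaults: 300 subjects × 100 parcels ×
200 time points, 1200 genes, 999 permutations, 199 spins, 500–2000
bootstraps, 10 community restarts; full-scale counts (100,000 permutations
and bootstraps, 50,000 mediation bootstraps, 100 restarts) sit behind
`runPipeline(..., full = TRUE)`. Every stage derives its stream from one
master seed, so a rerun with the same bundle and seed reproduces the
manifest bit-for-bit. Null calibration of the whole cascade is checked over
20 seeds of a null bundle (no planted effects); with seven p-values per run
an occasional single sub-1% p-value is the expected behaviour of calibrated
tests, not evidence of inflation.

# Known limitations

* The first latent variable / canonical mode only; no sparse or multi-mode
  variants.
* The variance-accounted summary of the behavioural PLS is the first
  squared singular value over the sum of squares — a specific reading of
  "variance explained" for a stacked correlation matrix.
* Spin tests inherit the hemisphere-stationarity assumption above.
* Greedy modularity maximisation carries no optimality guarantee beyond the
  small-network fixtures where it is checked against exhaustive
  enumeration.
* The moderated mediation model is the moderated-b (PROCESS model 14)
  topology; moderation of the direct path is not fitted.
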