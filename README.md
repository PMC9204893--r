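# larsig

Luminal androgen receptor (LAR) subtyping of triple-negative breast cancer
(TNBC) from bulk transcriptomics, and the downstream analyses that make the
split clinically interpretable: concordance benchmarking against other
subtyping schemes, a random-effects meta-analysis of neoadjuvant chemotherapy
(NAC) response, single-cell-anchored deconvolution of the tumor
microenvironment, and per-sample gene-set scoring. The package is aimed at
translational genomics analysts who have gene-by-sample expression matrices
(counts or normalized), per-sample outcome annotations, and optionally a typed
single-cell reference — and who need the whole chain to be reproducible and
testable offline, which is why every stage also has a synthetic-data generator
with known ground truth.

## What it computes

**Signature discovery.** Genes correlated with the androgen receptor anchor
(`select_anchor_correlated`), a k-means + silhouette scan confirming the
two-cluster structure (`scan_kmeans`), and a negative-binomial exact test for
differential expression (`nb_exact_de`): library sizes are equalized by TMM
rescaling, a common dispersion maximizes the conditional count-sum likelihood,
tagwise dispersions are shrunk by weighted likelihood, and each gene is tested
against the exact conditional distribution of one group's sum given the total.
`build_signature` keeps genes with |log2FC| > 2 and Bonferroni p <= 0.05.

**Classification.** A nearest-shrunken-centroid model (`train_nsc`,
`predict`): standardized centroid contrasts
d<sub>kj</sub> = (x̄<sub>kj</sub> − x̄<sub>j</sub>) / (m<sub>k</sub>(s<sub>j</sub> + s<sub>0</sub>)),
soft-thresholded by Δ (chosen by stratified 10-fold CV if requested), with
discriminant δ<sub>k</sub>(x) = Σ<sub>j</sub>(x<sub>j</sub> − x̄′<sub>kj</sub>)²/(s<sub>j</sub> + s<sub>0</sub>)² − 2 log π<sub>k</sub>.
Agreement with external subtype calls is scored by Cohen's kappa
(`cohens_kappa`, `pairwise_kappa`).

**Response meta-analysis.** Per treatment arm i with pCR counts by group, the
model is logit P(pCR | LAR) = β₀ + uᵢ and
logit P(pCR | non-LAR) = β₀ + uᵢ + β_L + vᵢ with independent
uᵢ ~ N(0, σᵤ²), vᵢ ~ N(0, σᵥ²). `fit_random_effects_logit` maximizes the
marginal likelihood by adaptive Gauss–Hermite product quadrature and reports
the pooled odds ratio exp(β_L) with a Wald 95% CI. The 13 published NAC arm
tables ship with the package (`nac_arms()`).

**Deconvolution.** A balanced single-cell reference (k nearest cells per type
centroid, `build_balanced_reference`), dropout-aware gene selection
(`dropout_feature_filter`), a cell-type signature matrix
(`build_signature_matrix`), and per-sample fraction estimation by NNLS or
linear nu-SVR (`deconvolve`), with limma-moderated abundance tests
(`test_abundance`).

**Gene-set scoring.** Parametric mean-z scores (`pgsea_scores`), rank-walk
variation scores bounded in [−1, 1] (`gsva_scores`), signature-overlap
filtering (`filter_sets`), Jaccard clustering (`jaccard_cluster`), Welch group
tests with Bonferroni control (`test_set_scores`), and immunogram median
tables (`immunogram_table`).

## Worked example

Meta-analysis of the bundled per-arm pCR tables:

```r
library(larsig)
arms <- nac_arms()
round(arm_odds_ratio(arms), 2)[c(2, 6, 13)]
#> 3.60 2.20 6.12
fit <- fit_random_effects_logit(arms)
fit
#> random-effects logit meta-analysis over 13 arms
#> pooled OR (non-LAR vs LAR) = 2.152, 95% CI [1.544, 3.000]
#> b0 = -0.833, bL = 0.767 (SE 0.169), sigma_u = 0.370, sigma_v = 0.000
#> log-likelihood -66.494, converged: TRUE (variance component at boundary)
rate_summary(arms)$n_nonlar_higher
#> 11
```

The pooled odds ratio says non-LAR tumors had about 2.15 times the odds of
pathological complete response of LAR tumors across these 13 arms; σᵤ = 0.37
is real arm-to-arm baseline heterogeneity, while the group effect shows no
detectable heterogeneity (σᵥ pinned at the zero boundary). Non-LAR response
rates exceeded LAR rates in 11 of the 13 arms.

Discovery-to-classification on a synthetic cohort shaped like the discovery
design (28 LAR / 95 non-LAR):

```r
sim <- simulate_bulk(bulk_sim_params(seed = 1))
lg  <- tmm_log_cpm(filter_by_median_count(sim$expr, 32))
sel <- select_anchor_correlated(lg, "AR", threshold = 0.5)
length(sel)
#> 128
scan_kmeans(lg, genes = c("AR", sel), k_max = 6, n_init = 20, seed = 1)
#> k-means / silhouette scan
#>    k2    k3    k4    k5    k6
#> 0.334 0.184 0.154 0.131 0.098
#> best k: 2
de  <- nb_exact_de(filter_by_median_count(sim$expr, 32), sim$samples$group_label)
sig <- build_signature(de)
sig
#> signature_spec: 35 genes (|log2FC| > 2, bonferroni p <= 0.05)
m <- train_nsc(lg[sig$genes, ], sim$samples$group_label, delta = "cv", seed = 1)
cohens_kappa(predict(m, lg)$label, sim$samples$group_label)$kappa
#> 1
```

The silhouette scan picks two clusters, the exact test recovers a stringent
signature, and the cross-validated shrunken-centroid model reproduces the
planted subtype labels perfectly (kappa = 1).

## Limitations

Gene matching is by exact uppercase symbol (no alias resolution); the
anchor-correlation rule and the dropout gene filter are documented defaults
standing in for under-specified published procedures; plots are out of scope —
every stage returns tables ready for external plotting. See the methods
vignette (`vignettes/lar-subtyping-methods.Rmd`) for the full model
descriptions and design decisions.
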