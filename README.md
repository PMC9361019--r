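# StemSig

Transcriptomic stemness-index analysis for bulk tumor cohorts, packaged as
a tested, reusable pipeline. `StemSig` addresses a recurring question in
tumor transcriptomics — how far a tumor has de-differentiated toward a
stem-like state, and whether that degree of stemness predicts drug
response and survival — for bioinformaticians who want the full analysis
chain to run, end to end, on data they control.

## What it computes

**mRNAsi.** A one-class logistic regression (OCLR) model is trained on a
stem-cell reference compendium. With no intercept and elastic-net
penalties, the per-gene weight vector *w* minimizes

    J(w) = -(1/n) Σᵢ log σ(wᵀxᵢ) + λ₁‖w‖₁ + (λ₂/2)‖w‖₂²

over the centered expression profiles *xᵢ* of the stem samples
(σ the logistic function). A tumor sample's stemness is the Spearman
correlation between *w* and its expression profile, min–max rescaled
within the cohort to the mRNA stemness index mRNAsi ∈ [0, 1].

**Subgroups and enrichment.** Cohorts are split at the median mRNAsi;
differential expression (Welch *t*, BH adjustment, |log2FC| > 1.5 and
adjusted p < 0.01 by default) feeds Monti consensus clustering
(1 − Pearson distance, average linkage, 1000 × 80 % subsampling, delta-area
rule for *k*), chi-square subgroup–response association tests,
hypergeometric over-representation analysis and preranked GSEA.

**Regulatory structure.** Bootstrap Bayesian-network inference (Gaussian
BIC hill-climbing over resamples) scores edge support among pathway
activities and among the four-gene RXRB → NR1H3 → CYP8B1 → SCD panel.

**Response signature and survival.** The four-gene panel's first two
principal components give a per-sample score (PPARscore = Dim1 + Dim2)
with a closest-top-left ROC cutoff; Kaplan–Meier curves, log-rank tests
and Efron-tie Cox models stratify survival by an mRNAsi threshold.

A synthetic-data module generates a stem/differentiated reference with a
planted stemness program, a tumor cohort whose latent stemness drives
response and hazard, and a planted linear-Gaussian regulatory chain, so
every stage is testable offline.

## Worked example

```r
library(StemSig)

cfg    <- simConfig(seed = 7)                 # study-scale synthetic data
ref    <- generateReferenceCompendium(cfg)
cohort <- generateTumorCohort(cfg, ref$truth)

ctr   <- centerByCompendium(ref$expression)
model <- trainOclr(ctr$centered[, ref$isStem], centeringMeans = ctr$means)
model
#> StemnessModel (one-class logistic regression)
#>   genes:      500
#>   trained on: 40 stem samples
#>   penalties:  l1 = 0, l2 = 1
#>   objective:  0.103823 (converged: TRUE)
#>   non-zero weights: 500

scores <- scoreMrnasi(model, cohort$expression)
cor(cohort$truth$latentStemness, mrnasi(scores), method = "spearman")
#> [1] 0.8556594
```

The correlation of 0.86 says the index reconstructs the simulated latent
stemness gradient almost rank-perfectly from expression alone. Running the
whole chain and writing every table plus a manifest:

```r
m <- runFullPipeline(cfg, outDir = "results/run1")
m$log$logrank_p        # survival split at mRNAsi 0.55
#> [1] 0.002099675
```

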