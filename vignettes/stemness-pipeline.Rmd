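---
title: "Stemness indices, response signatures, and what the synthetic data can show"
author: "StemSig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stemness indices, response signatures, and what the synthetic data can show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StemSig)
```

# The model

`StemSig` quantifies tumor de-differentiation from bulk expression. The
core is a one-class classifier: only the positive class (stem-cell
reference samples) is observed, so an ordinary two-class logistic fit is
unavailable. One-class logistic regression (OCLR) instead minimizes, over
the per-gene weight vector $w$ with no intercept,

$$J(w) = -\frac{1}{n}\sum_{i=1}^{n}\log\sigma(w^\top x_i)
  \;+\; \lambda_1\lVert w\rVert_1 \;+\; \frac{\lambda_2}{2}\lVert w\rVert_2^2,$$

where $x_i$ is the centered expression profile of stem sample $i$ and
$\sigma$ is the logistic function. The objective is convex; the solver is
accelerated proximal gradient (FISTA) with backtracking and a monotone
restart, and it stops when the sup-norm of the minimal subgradient falls
below `tol` (default `1e-6`). On problems small enough for a brute-force
fixed-step proximal-gradient reference, the two agree to below `1e-4` in
sup-norm, and the final objective to `1e-8`.

**Centering matters.** Per-gene means are taken over the *full* reference
compendium (stem and differentiated), and OCLR is then trained on the stem
subset of the centered matrix. If the training subset were centered on
itself, the gradient of the log-likelihood at the origin would vanish and
$w = 0$ would be the exact penalized optimum — the procedure would learn
nothing. This is the only mathematically coherent reading, and the
training function will in fact return exactly zero weights on
self-centered data (a property the tests pin down).

A tumor sample's raw stemness is the Spearman correlation between $w$ and
the sample's expression over the genes shared with the model (average
ranks for ties; at least 50 % of model genes must be present). Within a
cohort the correlations are min–max rescaled to the mRNAsi in $[0,1]$.
Because the score is rank-based it is invariant to any strictly
increasing per-sample transform of expression; because the rescaling is
per-cohort, a fixed threshold such as 0.55 is *cohort-relative* — a
model-anchored alternative would require transporting the training
cohort's correlation range, which the package deliberately does not
assume.

# Downstream stages and their defaults

| Stage | Parameter | Default | Why |
|---|---|---|---|
| OCLR | $\lambda_1$, $\lambda_2$ | 0, 1 | ridge-only training is stable on compendium-scale gene counts; both exposed |
| DE | thresholds | \|log2FC\| > 1.5, adj. p < 0.01 | the conventional strict cutoffs for this analysis; Welch *t* + BH |
| Consensus | reps, subsample | 1000, 0.8 | Monti resampling; 1 − Pearson distance, average linkage |
| Consensus | delta-area threshold | 0.1 | see below |
| GSEA | permutations, exponent | 1000, 1 | gene-set (size-matched) permutations suit a single preranked vector |
| BN | bootstraps R | 200 | desk default; published analyses of this type use 10000 — pass `R = 10000` to match |
| BN | max parents | 3 | bounds the hill-climbing move space |
| Signature | components | 2 | PPARscore = Dim1 + Dim2 on standardized panel genes |
| Classification | cutoff | −0.56 | the published ROC-optimal threshold for this signature |
| Survival | stratum cutoff, horizon | 0.55, 60 months | median-anchored mRNAsi split; fixed five-year window |

**Welch *t* instead of a moderated *t*.** Differential expression uses the
per-gene Welch two-sample *t* test. Empirical-Bayes variance moderation
(as in `limma`) changes ranking mainly for very small groups; the package
keeps the unmoderated test so the statistic is exactly reproducible from
first principles, at identical thresholds. This is a deliberate,
documented deviation from common practice.

**Choosing k by delta-area.** For each candidate $k$ the consensus matrix
yields an empirical CDF of its pairwise entries; $A(k)$ is the area under
that CDF. The selection rule takes the smallest $k$ whose *next* area
increment $A(k{+}1)-A(k)$ falls below 0.1. The increment is kept on the
absolute scale: it is bounded by the fraction of sample pairs whose
co-clustering changed, so one threshold is meaningful across datasets. A
relative version (dividing by $A(k)$) never levels off on crisply
clustered data, where $A(2)$ is small and even sub-splits of a few
outliers inflate the ratio past any fixed threshold — on a planted
two-blob fixture it keeps climbing to the top of the range, while the
absolute rule selects $k = 2$ there and $k = 3$ on a three-blob fixture.

**Proportion tests.** The per-subgroup "test of proportion" is a
chi-square goodness-of-fit of the subgroup's (responder, non-responder)
counts against equal proportions, df = 1, no continuity correction. This
operationalization reproduces, to the printed precision, both published
subgroup p-values (7.76e-9 and 5.79e-4) from the contingency table
reconstructed from the published marginals — which is how the package
fixes the otherwise underdetermined phrase "test of proportion".

**GSEA details.** The walk adds $|s|^{p}/\sum_{hits}|s|^{p}$ at hits and
subtracts $1/(N-K)$ at misses; the ES is the extremum by absolute value.
The null is size-matched random gene sets; NES divides the ES by the mean
absolute null ES of matching sign, and the permutation p carries a +1
pseudocount so it is never exactly zero. Monte-Carlo standard errors are
reported alongside.

**Bayesian networks.** Structure learning is greedy hill-climbing over
add/delete/reverse moves on the Gaussian BIC, acyclicity enforced per
move, random restarts from perturbed graphs. Node scores are computed
from the empirical covariance (the residual variance of a
linear-Gaussian node given parents is a Schur complement), so bootstrap
replications are cheap. On ≤ 4 variables the climber reaches the
exhaustive-search optimum in the test fixtures. Pathway activity is the
mean member-gene z-score: simple, monotone and variance-stabilized; the
aggregation is a package choice since no standard exists. Note that for
a chain without v-structures only the *skeleton* is identifiable; edge
directions in the consensus network carry a separate
direction-confidence rather than a claim of identification.

**Signature sign convention.** Principal components are sign-fixed so
each component's largest-|loading| entry is positive. Without such a
rule the sign of PPARscore — and therefore any fixed cutoff on it — is
arbitrary. Coordinates are plain projections of standardized data (not
eigenvalue-scaled), and new cohorts are projected with the stored
means/SDs and loadings rather than refit, so scores stay comparable even
for cohorts far too small to refit a stable PCA (a `refit` flag exists).

**Five-year survival.** The fixed-horizon rule administratively censors
at 60 months rather than excluding longer-followed patients: exclusion
conditions on the future and biases the risk sets. The exclusion variant
is available behind `method = "exclude"` for comparison.

# What the synthetic data emulates — and what it does not

`simConfig()` fixes the study conditions. The reference compendium
(default 40 stem + 60 differentiated samples, 500 genes, 50 program
genes) plants a stemness program whose genes carry one of two effect
magnitudes (0.5× or 1.5× the mean shift of 2 on the log2 scale). The
heterogeneity is essential, not cosmetic: a perfectly uniform program
shifts every program gene by the same amount per sample, which is a
constant offset in that sample's profile and therefore *invisible* to
correlation-based sample distances; real programs always have strong and
weak members. The tumor cohort (default n = 150) draws latent stemness
$s \sim U(0,1)$; non-response is Bernoulli with logit $-2.4 + 8s$, fixing
the marginal non-response rate near 0.69 — the rate reported in published
sorafenib cohorts — while making stemness a strong driver; survival is
exponential with hazard $0.02\,e^{1.5 s}$ per month, satisfying
proportional hazards so Cox recovery is well-posed. The four panel genes
follow a linear-Gaussian chain whose root is mean-shifted (+1.5) in
non-responders; the shift propagates down the chain, so all four genes
are higher in non-responders while the chain keeps its Markov structure
(the partial correlation of ends given the middle is zero — a pinned
test). Each generator operation draws from its own seed stream derived
from `(seed, operation name)`, so adding operations never perturbs
earlier draws and identical configs are byte-reproducible.

What the simulation does **not** contain: count-level noise
(negative-binomial mean–variance), batch effects, correlated background
genes, probe-level artifacts, non-proportional hazards, or informative
censoring. Passing tests therefore demonstrate that the algorithms
recover the structures they assume, at realistic effect sizes and sample
sizes — not that those assumptions hold in any particular real cohort.
In particular the published headline values that depend on real cohorts
(AUC = 0.8861, cutoff −0.56, 845 DEGs, the cohort medians, NES values,
the log-rank p of 0.00039) are treated as method anchors, not as numbers
a simulation could or should reproduce.

# Numerical and degenerate-input choices

* OCLR declares non-convergence (with the final objective and gradient
  norm) rather than returning a stale iterate; `w = 0` short-circuits
  exactly when the origin satisfies the optimality conditions.
* Zero-variance genes: an error for PCA panel genes and BN variables
  (the statistic is undefined), `p = 1` with a warning in rank tests,
  `NA` with a warning in correlations, silent exclusion in z-score-based
  pathway activity.
* Median split sends exact ties to "low" (strictly-greater rule);
  response classification sends a score exactly at the cutoff to
  "responder" (strict inequality).
* ROC candidate thresholds are midpoints between consecutive unique
  scores plus ±∞; AUC uses the Mann–Whitney identity with ties counted
  one half; cutoff ties break toward higher sensitivity, then lower
  threshold.
* Duplicate gene ids on load collapse to the row with the highest mean
  (the usual microarray convention); every discarded record is counted
  in a message.
* MAF mutation frequencies count distinct mutated samples, never
  records, and exclude silent/intronic/UTR/flank/RNA classes by default.

# Problem sizes in the shipped tests

The suite runs the full synthetic study at its default scale (500 genes,
100 reference samples, cohort 150) for the recovery checks; consensus
clustering at 1000 repetitions on the planted-blob fixture; bootstrap
networks at R = 200 on the n = 500 chain cohort; and the orchestrated
pipeline twice at a reduced scale (150 genes, cohort 80) to pin
byte-level determinism. These sizes were chosen so the whole suite
completes in well under a minute of compute per module while keeping
every statistical check at meaningful power.

# Known limitations

* mRNAsi is cohort-relative by construction; cross-cohort thresholds
  (0.55, −0.56) are conventions inherited from the anchor analysis, and
  their transportability is an assumption the package flags rather than
  verifies.
* The consensus-clustering inner loop is hierarchical; with very few
  samples per cluster, stable sub-splits of noise can legitimately pull
  the delta-area choice above the true k.
* BN edge directions within a Markov-equivalence class are reported with
  direction-confidence but are not identifiable from observational
  Gaussian data.
* The Welch-t DE stage will be slightly conservative relative to
  moderated-t pipelines for very small groups.
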