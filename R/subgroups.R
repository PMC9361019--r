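#' Split a cohort at the median stemness index
#'
#' Samples strictly greater than the cohort median are labeled `"high"`,
#' all others (including exact ties with the median) `"low"`.
#'
#' @param scores a [StemnessScores-class] or a named numeric vector.
#' @return Named factor with levels `high`, `low`.
#' @export
splitByMedian <- function(scores) {
  v <- if (methods::is(scores, "StemnessScores")) mrnasi(scores) else scores
  if (length(v) < 2L) stop("domain error: need at least 2 samples")
  if (diff(range(v)) < 1e-15)
    stop("degenerate split error: all scores identical")
  med <- stats::median(v)
  factor(ifelse(v > med, "high", "low"), levels = c("high", "low"))
}

#' Differential expression between two groups (Welch t)
#'
#' Per-gene Welch two-sample t-test on log2 expression between the `high`
#' and `low` groups, with Benjamini-Hochberg adjustment across all genes.
#' `log2fc` is `mean(high) - mean(low)`. A gene is flagged a DEG when
#' `|log2fc| > lfcThreshold` and `adj_p < pThreshold` (defaults 1.5 and
#' 0.01, the conventional thresholds for this analysis).
#'
#' @param X genes x samples matrix.
#' @param labels factor/character per sample with exactly two levels; the
#'   first level is the "high" group.
#' @param lfcThreshold absolute log2 fold-change threshold (default 1.5).
#' @param pThreshold adjusted-p threshold (default 0.01).
#' @return data.frame with columns `gene`, `log2fc`, `p`, `adj_p`, `is_deg`.
#' @export
differentialExpression <- function(X, labels, lfcThreshold = 1.5,
                                   pThreshold = 0.01) {
  X <- .asExprMatrix(X, "X")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("domain error: labels must have exactly two levels")
  labels <- droplevels(labels)
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2L || n2 < 2L)
    stop("domain error: each group needs >= 2 samples")
  X1 <- X[, g1, drop = FALSE]; X2 <- X[, g2, drop = FALSE]
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: p = 1 when means agree, else effectively 0
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  adj <- stats::p.adjust(p, method = "BH")
  lfc <- m1 - m2
  data.frame(
    gene = rownames(X), log2fc = lfc, p = p, adj_p = adj,
    is_deg = abs(lfc) > lfcThreshold & adj < pThreshold,
    stringsAsFactors = FALSE
  )
}

# Area under the empirical CDF of the off-diagonal consensus entries.
.consensusCdfArea <- function(m) {
  x <- sort(m[upper.tri(m)])
  x <- c(0, x, 1)
  cdf <- stats::ecdf(m[upper.tri(m)])
  sum(diff(x) * cdf(x[-length(x)]))
}

#' Consensus clustering by Monti subsampling
#'
#' Repeatedly subsamples a fraction of the samples, clusters each subsample
#' hierarchically (distance `1 - Pearson` between samples, average linkage),
#' and records for every sample pair the fraction of co-subsampled runs in
#' which the pair co-clusters. The cluster count is chosen by the relative
#' delta-area rule on the consensus CDF: the smallest k whose next relative
#' area increase falls below `deltaThreshold`. Final labels come from
#' hierarchical clustering of `1 - consensus` at the chosen k.
#'
#' @param X genes x samples matrix (typically restricted to DEGs).
#' @param kRange candidate cluster counts (default 2:6).
#' @param reps number of subsampling repetitions (default 1000).
#' @param subsample fraction of samples per repetition (default 0.8).
#' @param seed integer RNG seed.
#' @param deltaThreshold relative delta-area threshold (default 0.1).
#' @param scaleGenes z-score genes before the distance (default TRUE).
#' @return A [ConsensusResult-class] object.
#' @export
consensusCluster <- function(X, kRange = 2:6, reps = 1000L,
                             subsample = 0.8, seed = 1L,
                             deltaThreshold = 0.1, scaleGenes = TRUE) {
  X <- .asExprMatrix(X, "X")
  n <- ncol(X)
  kRange <- sort(as.integer(kRange))
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stop("domain error: kRange must lie within [2, n - 1]")
  if (scaleGenes) {
    sds <- apply(X, 1L, stats::sd)
    keep <- sds > 0
    X <- (X[keep, , drop = FALSE] - rowMeans(X[keep, , drop = FALSE])) /
      sds[keep]
  }
  D <- 1 - stats::cor(X)        # sample x sample dissimilarity
  m <- ceiling(subsample * n)
  nK <- length(kRange)
  hit <- array(0, dim = c(n, n, nK))
  cnt <- matrix(0, n, n)
  .withSeed(.opSeed(seed, "consensus_cluster"), {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m))
      cnt[idx, idx] <- cnt[idx, idx] + 1
      hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "average")
      for (ki in seq_len(nK)) {
        cl <- stats::cutree(hc, k = kRange[ki])
        same <- outer(cl, cl, "==")
        hit[idx, idx, ki] <- hit[idx, idx, ki] + same
      }
    }
  })
  mats <- lapply(seq_len(nK), function(ki) {
    cm <- hit[, , ki] / pmax(cnt, 1)
    cm[cnt == 0] <- 0
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(colnames(X), colnames(X))
    cm
  })
  areas <- vapply(mats, .consensusCdfArea, numeric(1))
  # delta-area per k: the increase of the consensus CDF area. The
  # increments are kept on the absolute scale, which is bounded by the
  # fraction of sample pairs whose co-clustering changed, so a single
  # threshold is meaningful across datasets; dividing by A(k-1) instead
  # never levels off on crisply clustered data, where A(2) is small.
  deltas <- c(areas[1L], if (nK > 1L) diff(areas))
  # smallest k whose NEXT delta-area drops below the threshold
  chosen <- kRange[nK]
  for (ki in seq_len(nK - 1L)) {
    if (deltas[ki + 1L] < deltaThreshold) { chosen <- kRange[ki]; break }
  }
  cm <- mats[[match(chosen, kRange)]]
  hcFinal <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  labels <- stats::cutree(hcFinal, k = chosen)
  methods::new("ConsensusResult",
    kRange = kRange, consensusMatrices = mats,
    cdfAreas = areas, deltaAreas = deltas,
    chosenK = as.integer(chosen),
    labels = stats::setNames(as.integer(labels), colnames(X)))
}

#' Subgroup vs response association tests
#'
#' Builds the subgroup x response contingency table; for each subgroup runs
#' a chi-square goodness-of-fit test (df = 1, no continuity correction) of
#' its (responder, non-responder) counts against equal proportions, and an
#' overall Pearson chi-square on the full table.
#'
#' @param labels per-sample subgroup labels (factor/character).
#' @param response per-sample response labels, two levels.
#' @return list with `contingency` (table), `perSubgroupP` (named numeric)
#'   and `overallP`.
#' @export
associationTest <- function(labels, response) {
  labels <- as.factor(labels); response <- as.factor(response)
  if (nlevels(droplevels(response)) != 2L)
    stop("domain error: response must have exactly two levels")
  tab <- table(labels, response)
  if (any(rowSums(tab) == 0L))
    stop("domain error: empty subgroup")
  perP <- apply(tab, 1L, function(o) {
    e <- sum(o) / 2
    stats::pchisq(sum((o - e)^2 / e), df = 1L, lower.tail = FALSE)
  })
  overall <- stats::chisq.test(tab, correct = FALSE)$p.value
  list(contingency = tab, perSubgroupP = perP, overallP = unname(overall))
}

#' Per-gene Wilcoxon rank-sum comparison between response groups
#'
#' Two-sided Wilcoxon rank-sum test per queried gene, with Hommel step-up
#' adjustment across the queried genes.
#'
#' @param X genes x samples matrix.
#' @param genes genes to test.
#' @param response per-sample response labels, two levels.
#' @return data.frame with columns `gene`, `statistic`, `p`, `adj_p`.
#' @export
compareExpressionWilcoxon <- function(X, genes, response) {
  X <- .asExprMatrix(X, "X")
  response <- droplevels(as.factor(response))
  if (nlevels(response) != 2L)
    stop("domain error: response must have exactly two levels")
  if (any(table(response) == 0L))
    stop("domain error: empty response group")
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("gene(s) not in the matrix: ", paste(miss, collapse = ", "))
  res <- t(vapply(genes, function(g) {
    x <- X[g, ]
    if (diff(range(x)) < 1e-15) {
      warning("gene ", g, " is constant; p set to 1")
      return(c(NA_real_, 1))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x[response == levels(response)[1L]],
                         x[response == levels(response)[2L]]))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2)))
  data.frame(gene = genes, statistic = res[, 1L], p = res[, 2L],
             adj_p = stats::p.adjust(res[, 2L], method = "hommel"),
             stringsAsFactors = FALSE)
}
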