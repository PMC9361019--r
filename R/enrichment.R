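#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the selected gene list overlaps the set
#' more than expected by chance: `p = P(X >= k)` under
#' `Hypergeometric(N, K, n)` with `N` the universe size, `K` the set size
#' within the universe, `n` the selection size and `k` the observed
#' overlap. Sets are intersected with the universe before testing;
#' Benjamini-Hochberg adjustment is applied across tested sets.
#'
#' @param selected character vector of selected genes (e.g. DEGs); must be
#'   a subset of `universe`.
#' @param universe character vector of all measured genes.
#' @param db named list of gene sets.
#' @return data.frame with columns `set`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   ordered by increasing `p`.
#' @export
oraHypergeometric <- function(selected, universe, db) {
  selected <- unique(selected); universe <- unique(universe)
  if (!length(selected)) stop("domain error: empty selected gene list")
  if (!all(selected %in% universe))
    stop("selected genes must be a subset of the universe")
  N <- length(universe); n <- length(selected)
  rows <- lapply(names(db), function(nm) {
    set <- intersect(db[[nm]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(selected, set))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the universe")
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

# Running-sum walk over a descending ranking. Returns the enrichment score
# (extremum by absolute value) and the leading-edge gene indices.
.gseaWalk <- function(statSorted, isHit, weightExponent) {
  N <- length(statSorted); K <- sum(isHit)
  w <- abs(statSorted)^weightExponent * isHit
  tot <- sum(w)
  if (tot == 0) w[isHit] <- 1 / K else w <- w / tot
  steps <- ifelse(isHit, w, -1 / (N - K))
  running <- cumsum(steps)
  iMax <- which.max(running); iMin <- which.min(running)
  es <- if (abs(running[iMax]) >= abs(running[iMin]))
    running[iMax] else running[iMin]
  lead <- if (es >= 0) which(isHit & seq_len(N) <= iMax)
          else which(isHit & seq_len(N) >= iMin)
  list(es = es, leadingEdge = lead)
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov-style running sum over a single
#' preranked statistic (typically the per-gene log2 fold change): genes are
#' sorted in descending order; hits add `|stat|^weightExponent`
#' (normalized over the set), misses subtract `1/(N - K)`; the enrichment
#' score (ES) is the extremum of the walk by absolute value. The null
#' distribution comes from size-matched random gene sets; NES is the ES
#' divided by the mean |null ES| of matching sign, and the permutation p is
#' the fraction of matching-sign null scores at least as extreme (with a
#' +1 pseudocount so p stays positive).
#'
#' @param stats named numeric, the ranking statistic per gene.
#' @param db named list of gene sets (or a single character vector).
#' @param nPerm number of gene-set permutations (default 1000).
#' @param weightExponent hit-weight exponent (default 1).
#' @param seed integer RNG seed.
#' @param minSize minimum set overlap with the ranking (default 3).
#' @param maxSize maximum set overlap (default 500).
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p`, `mc_se`
#'   (Monte-Carlo standard error of `p`) and `leading_edge`
#'   (comma-separated genes).
#' @export
gseaPreranked <- function(stats, db, nPerm = 1000L, weightExponent = 1,
                          seed = 1L, minSize = 3L, maxSize = 500L) {
  if (is.null(names(stats))) stop("stats must be a named vector")
  if (is.character(db)) db <- list(set = db)
  ord <- order(stats, decreasing = TRUE)
  statSorted <- stats[ord]
  genesSorted <- names(statSorted)
  N <- length(statSorted)
  .withSeed(.opSeed(seed, "gsea_preranked"), {
    rows <- lapply(names(db), function(nm) {
      hits <- genesSorted %in% db[[nm]]
      K <- sum(hits)
      if (K >= N)
        stop("degenerate-set error: set '", nm, "' equals the universe")
      if (K < minSize || K > maxSize) {
        warning("skipping set '", nm, "' (overlap ", K, ")")
        return(NULL)
      }
      obs <- .gseaWalk(statSorted, hits, weightExponent)
      nullEs <- vapply(seq_len(nPerm), function(i) {
        h <- logical(N); h[sample.int(N, K)] <- TRUE
        .gseaWalk(statSorted, h, weightExponent)$es
      }, numeric(1))
      same <- nullEs[sign(nullEs) == sign(obs$es)]
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      nSame <- length(same)
      p <- (sum(abs(same) >= abs(obs$es)) + 1L) / (nSame + 1L)
      data.frame(
        set = nm, size = K, es = obs$es, nes = nes, p = p,
        mc_se = sqrt(p * (1 - p) / max(nSame, 1L)),
        leading_edge = paste(genesSorted[obs$leadingEdge], collapse = ","),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no testable gene set")
    out[order(out$p), , drop = FALSE]
  })
}
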