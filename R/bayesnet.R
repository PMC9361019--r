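#' Per-sample pathway activity
#'
#' Activity of a pathway in a sample is the mean of its member genes'
#' z-scores (per-gene standardization across samples) — a simple monotone,
#' variance-stabilized aggregate. Pathways with fewer than `minSize`
#' measured, non-constant members are skipped with a warning.
#'
#' @param X genes x samples matrix.
#' @param db named list of gene sets.
#' @param minSize minimum measured members per pathway (default 3).
#' @return pathway x sample numeric matrix.
#' @export
pathwayActivity <- function(X, db, minSize = 3L) {
  X <- .asExprMatrix(X, "X")
  sds <- apply(X, 1L, stats::sd)
  if (all(sds == 0)) stop("domain error: all genes have zero variance")
  Z <- (X[sds > 0, , drop = FALSE] - rowMeans(X[sds > 0, , drop = FALSE])) /
    sds[sds > 0]
  rows <- lapply(names(db), function(nm) {
    mem <- intersect(db[[nm]], rownames(Z))
    if (length(mem) < minSize) {
      warning("skipping pathway '", nm, "' (", length(mem),
              " measured members)")
      return(NULL)
    }
    colMeans(Z[mem, , drop = FALSE])
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no pathway has enough measured members")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- names(db)[keep]
  out
}

# Gaussian BIC contribution of one node given its parents, computed from
# the MLE covariance S of the (centered) data: the residual variance of a
# linear regression with intercept is S_yy - S_yP S_PP^{-1} S_Py, so each
# rescore is a tiny solve instead of a full lm fit. `env` carries S and n.
.nodeBic <- function(env, j, parents) {
  S <- env$S; n <- env$n
  sigma2 <- if (length(parents)) {
    Spp <- S[parents, parents, drop = FALSE]
    spy <- S[parents, j]
    drop(S[j, j] - crossprod(spy, solve(Spp, spy)))
  } else S[j, j]
  sigma2 <- max(sigma2, 1e-12)
  k <- length(parents) + 2L   # coefficients + intercept + variance
  -n / 2 * (log(2 * pi) + log(sigma2) + 1) - k / 2 * log(n)
}

# TRUE if adding edge from -> to creates a cycle (path to -> ... -> from).
.createsCycle <- function(adj, from, to) {
  stack <- to
  seen <- logical(nrow(adj))
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == from) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ]))
  }
  FALSE
}

.scoreEnv <- function(dat) {
  # dat: samples x variables
  n <- nrow(dat)
  ctr <- sweep(dat, 2L, colMeans(dat))
  list2env(list(S = crossprod(ctr) / n, n = n), parent = emptyenv())
}

.totalBic <- function(env, adj) {
  sum(vapply(seq_len(nrow(env$S)), function(j)
    .nodeBic(env, j, which(adj[, j])), numeric(1)))
}

# Greedy hill-climbing from a given start adjacency; returns the local
# optimum and its score. adj[i, j] == TRUE means i -> j.
.hillClimb <- function(env, adj, maxParents) {
  p <- nrow(env$S)
  nodeScores <- vapply(seq_len(p), function(j)
    .nodeBic(env, j, which(adj[, j])), numeric(1))
  repeat {
    bestGain <- 1e-10; best <- NULL
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (!adj[i, j] && !adj[j, i]) {               # add i -> j
        if (sum(adj[, j]) >= maxParents) next
        if (.createsCycle(adj, i, j)) next
        gain <- .nodeBic(env, j, c(which(adj[, j]), i)) - nodeScores[j]
        if (gain > bestGain) {
          bestGain <- gain; best <- list(op = "add", i = i, j = j)
        }
      } else if (adj[i, j]) {
        # delete i -> j
        gain <- .nodeBic(env, j, setdiff(which(adj[, j]), i)) - nodeScores[j]
        if (gain > bestGain) {
          bestGain <- gain; best <- list(op = "del", i = i, j = j)
        }
        # reverse i -> j to j -> i
        if (sum(adj[, i]) < maxParents) {
          adj2 <- adj; adj2[i, j] <- FALSE
          if (!.createsCycle(adj2, j, i)) {
            gain <- (.nodeBic(env, j, setdiff(which(adj[, j]), i)) -
                       nodeScores[j]) +
                    (.nodeBic(env, i, c(which(adj[, i]), j)) - nodeScores[i])
            if (gain > bestGain) {
              bestGain <- gain; best <- list(op = "rev", i = i, j = j)
            }
          }
        }
      }
    }
    if (is.null(best)) break
    i <- best$i; j <- best$j
    if (best$op == "add") {
      adj[i, j] <- TRUE
    } else if (best$op == "del") {
      adj[i, j] <- FALSE
    } else {
      adj[i, j] <- FALSE; adj[j, i] <- TRUE
      nodeScores[i] <- .nodeBic(env, i, which(adj[, i]))
    }
    nodeScores[j] <- .nodeBic(env, j, which(adj[, j]))
  }
  list(adj = adj, score = sum(nodeScores))
}

#' Learn a Bayesian network structure (Gaussian BIC hill-climbing)
#'
#' Greedy hill-climbing over add/delete/reverse edge moves maximizing the
#' BIC of a linear-Gaussian network, with acyclicity enforced at every move
#' and random restarts from perturbed graphs. Deterministic given the seed.
#'
#' @param data variables x samples numeric matrix.
#' @param maxParents maximum parents per node (default 3).
#' @param restarts number of random restarts beyond the empty start
#'   (default 5).
#' @param seed integer RNG seed for the restarts.
#' @return list with `adjacency` (logical variables x variables matrix,
#'   `[i, j]` meaning i -> j), `edges` (data.frame from/to) and `score`
#'   (total BIC).
#' @export
learnStructure <- function(data, maxParents = 3L, restarts = 5L, seed = 1L) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric variables x samples matrix")
  if (is.null(rownames(data)))
    rownames(data) <- paste0("V", seq_len(nrow(data)))
  const <- apply(data, 1L, function(x) diff(range(x)) < 1e-15)
  if (any(const))
    stop("domain error: constant variable(s): ",
         paste(rownames(data)[const], collapse = ", "))
  env <- .scoreEnv(t(data))
  p <- nrow(data)
  empty <- matrix(FALSE, p, p)
  best <- .hillClimb(env, empty, maxParents)
  .withSeed(.opSeed(seed, "learn_structure"), {
    for (r in seq_len(restarts)) {
      adj <- empty
      nAdd <- sample.int(max(1L, p), 1L)
      for (e in seq_len(nAdd)) {
        i <- sample.int(p, 1L); j <- sample.int(p, 1L)
        if (i != j && !adj[i, j] && !adj[j, i] &&
            sum(adj[, j]) < maxParents && !.createsCycle(adj, i, j))
          adj[i, j] <- TRUE
      }
      cand <- .hillClimb(env, adj, maxParents)
      if (cand$score > best$score) best <- cand
    }
  })
  adj <- best$adj
  dimnames(adj) <- list(rownames(data), rownames(data))
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = rownames(adj)[idx[, 1L]],
                      to = rownames(adj)[idx[, 2L]],
                      stringsAsFactors = FALSE)
  list(adjacency = adj, edges = edges, score = best$score)
}

#' Bootstrap-consensus Bayesian network
#'
#' Resamples the samples with replacement `R` times, learns a structure on
#' each resample, and summarizes edge support: `strength` is the fraction
#' of bootstrap networks containing an edge in either orientation;
#' `directionConfidence` the fraction of those oriented from -> to. The
#' consensus network keeps edges with strength at or above the threshold,
#' oriented by majority direction.
#'
#' @param data variables x samples numeric matrix.
#' @param R number of bootstrap resamples (published analyses of this kind
#'   use 10000; default 200 keeps desk runs fast).
#' @param strengthThreshold consensus inclusion threshold (default 0.5).
#' @param maxParents maximum parents per node (default 3).
#' @param restarts hill-climbing restarts per bootstrap (default 2).
#' @param seed integer RNG seed.
#' @return A [BNetwork-class] object.
#' @export
bootstrapNetwork <- function(data, R = 200L, strengthThreshold = 0.5,
                             maxParents = 3L, restarts = 2L, seed = 1L) {
  if (R < 1L) stop("configuration error: R must be >= 1")
  if (strengthThreshold <= 0 || strengthThreshold > 1)
    stop("configuration error: strengthThreshold must lie in (0, 1]")
  vars <- rownames(data)
  if (is.null(vars)) vars <- paste0("V", seq_len(nrow(data)))
  rownames(data) <- vars
  p <- length(vars)
  n <- ncol(data)
  countDir <- matrix(0L, p, p, dimnames = list(vars, vars))
  .withSeed(.opSeed(seed, "bootstrap_network"), {
    subSeeds <- sample.int(2147483646L, R)
    for (b in seq_len(R)) {
      idx <- sample.int(n, n, replace = TRUE)
      fit <- learnStructure(data[, idx, drop = FALSE],
                            maxParents = maxParents,
                            restarts = restarts, seed = subSeeds[b])
      countDir <- countDir + fit$adjacency
    }
  })
  either <- countDir + t(countDir)
  rows <- list()
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    strength <- either[i, j] / R
    if (strength >= strengthThreshold) {
      if (countDir[i, j] >= countDir[j, i]) { a <- i; bIdx <- j }
      else { a <- j; bIdx <- i }
      rows[[length(rows) + 1L]] <- data.frame(
        from = vars[a], to = vars[bIdx], strength = strength,
        directionConfidence = countDir[a, bIdx] / either[i, j],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(),
               strength = numeric(), directionConfidence = numeric(),
               stringsAsFactors = FALSE)
  net <- methods::new("BNetwork",
    nodes = vars, edges = edges, nBootstrap = as.integer(R),
    strengthThreshold = strengthThreshold)
  attr(net, "strengthMatrix") <- either / R
  net
}

#' Edge strengths from a bootstrap network
#'
#' @param net a [BNetwork-class].
#' @return symmetric variables x variables matrix of bootstrap strengths
#'   (fraction of resamples containing the edge in either direction).
#' @export
edgeStrengthMatrix <- function(net) {
  m <- attr(net, "strengthMatrix")
  if (is.null(m)) stop("network carries no strength matrix")
  m
}
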