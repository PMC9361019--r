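# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute force, enumeration, closed forms.

# Mann-Whitney AUC by looping over all (positive, negative) pairs.
bruteForceAuc <- function(pos, neg) {
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by hand.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m); out[o] <- adj
  out
}

# Hommel adjustment by exhaustive closed testing with Simes local tests:
# adjusted p_i = max over all subsets I containing i of the Simes p-value
# of I. Exponential in m; fine for m <= 5.
closedTestingHommel <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  subsets <- unlist(lapply(seq_len(m), function(k)
    utils::combn(m, k, simplify = FALSE)), recursive = FALSE)
  simes <- function(idx) {
    ps <- sort(p[idx]); k <- length(ps)
    min(k * ps / seq_len(k))
  }
  for (i in seq_len(m)) {
    adj[i] <- min(1, max(vapply(subsets[vapply(subsets, function(s)
      i %in% s, logical(1))], simes, numeric(1))))
  }
  adj
}

# Plain proximal gradient descent with a small fixed step for the one-class
# logistic objective; independent of the package's accelerated solver.
proxGradOclr <- function(X, l1, l2, step = NULL, iters = 200000L,
                         tol = 1e-10) {
  n <- ncol(X)
  if (is.null(step)) step <- 1 / (sum(X^2) / (4 * n) + l2)
  w <- numeric(nrow(X))
  for (it in seq_len(iters)) {
    z <- drop(crossprod(X, w))
    g <- drop(-(X %*% (1 - 1 / (1 + exp(-z)))) / n) + l2 * w
    v <- w - step * g
    wNew <- sign(v) * pmax(abs(v) - step * l1, 0)
    if (max(abs(wNew - w)) < tol) { w <- wNew; break }
    w <- wNew
  }
  w
}

oclrObjective <- function(X, w, l1, l2) {
  z <- drop(crossprod(X, w))
  -mean(ifelse(z >= 0, -log1p(exp(-z)), z - log1p(exp(z)))) +
    l1 * sum(abs(w)) + (l2 / 2) * sum(w^2)
}

# Gaussian BIC of a whole DAG via explicit lm() fits (intercept included).
lmBicScore <- function(data, adj) {
  # data: variables x samples; adj[i, j] TRUE means i -> j
  dat <- t(data); n <- nrow(dat); tot <- 0
  for (j in seq_len(ncol(dat))) {
    pa <- which(adj[, j])
    fit <- if (length(pa))
      stats::lm(dat[, j] ~ dat[, pa, drop = FALSE])
    else stats::lm(dat[, j] ~ 1)
    sigma2 <- sum(stats::residuals(fit)^2) / n
    k <- length(pa) + 2L
    tot <- tot + (-n / 2 * (log(2 * pi) + log(sigma2) + 1) - k / 2 * log(n))
  }
  tot
}

# All DAGs on p nodes by filtering every directed graph for acyclicity.
# 543 DAGs at p = 3 is actually 25; p = 4 gives 543.
allDags <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  nP <- nrow(pairs)
  out <- list()
  # each unordered pair is absent, i->j, or j->i
  for (code in seq_len(3^nP) - 1L) {
    adj <- matrix(FALSE, p, p)
    c0 <- code
    for (e in seq_len(nP)) {
      st <- c0 %% 3L; c0 <- c0 %/% 3L
      if (st == 1L) adj[pairs[e, 1L], pairs[e, 2L]] <- TRUE
      if (st == 2L) adj[pairs[e, 2L], pairs[e, 1L]] <- TRUE
    }
    if (isAcyclic(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

isAcyclic <- function(adj) {
  p <- nrow(adj); indeg <- colSums(adj); active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (v in src) {
      indeg[adj[v, ]] <- indeg[adj[v, ]] - 1L
      active[v] <- FALSE
    }
  }
  !any(active)
}

# Exhaustive-search BIC optimum over all DAGs (p <= 4).
exhaustiveBestDag <- function(data) {
  dags <- allDags(nrow(data))
  scores <- vapply(dags, function(a) lmBicScore(data, a), numeric(1))
  list(adj = dags[[which.max(scores)]], score = max(scores))
}

# Kaplan-Meier log-rank statistic from a hand risk-set tabulation.
manualLogrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  ts <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox partial log-likelihood for a single covariate, no ties.
coxPartialLoglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Generated fixture: two sample blobs with opposite expression programs
# (separation `sep` in units of the within-blob sd), the planted-partition
# setting for correlation-based clustering.
makeBlobMatrix <- function(nPerBlob = 10L, nGenes = 40L, sep = 10,
                           sd = 1, seed = 42L) {
  set.seed(seed)
  pattern <- rep(c(sep / 2, -sep / 2), each = nGenes / 2)
  X <- cbind(
    matrix(rnorm(nGenes * nPerBlob, 0, sd), nGenes) + pattern,
    matrix(rnorm(nGenes * nPerBlob, 0, sd), nGenes) - pattern
  )
  dimnames(X) <- list(paste0("g", seq_len(nGenes)),
                      paste0("s", seq_len(2L * nPerBlob)))
  list(X = X, truth = rep(1:2, each = nPerBlob))
}

# Small deterministic simulated survival cohort with a known hazard ratio.
makeSurvCohort <- function(n, hr, seed, censorRate = 0.2) {
  set.seed(seed)
  x <- rep(0:1, length.out = n)
  time <- rexp(n, rate = 0.05 * hr^x)
  cens <- rbinom(n, 1, censorRate) == 1
  time[cens] <- runif(sum(cens)) * time[cens]
  data.frame(sample_id = paste0("p", seq_len(n)),
             time_months = time, event = as.integer(!cens), x = x)
}
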