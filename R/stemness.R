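#' Center expression by the reference compendium
#'
#' Centers each gene by its mean over ALL reference samples (stem and
#' differentiated). The one-class model is then trained on the stem subset
#' of the centered matrix: centering on the training subset itself would
#' make the zero vector the exact penalized optimum and the procedure
#' vacuous, so the compendium-wide mean is the reference point that gives
#' the stem class a non-trivial signal.
#'
#' @param X genes x samples reference matrix (log2 scale).
#' @return list with `centered` (matrix) and `means` (named numeric).
#' @export
centerByCompendium <- function(X) {
  X <- .asExprMatrix(X, "X")
  if (ncol(X) < 2L)
    stop("domain error: centering needs at least two reference samples")
  m <- rowMeans(X)
  list(centered = X - m, means = m)
}

#' Train the one-class logistic regression (OCLR) stemness model
#'
#' Minimizes, over the per-gene weight vector `w` with no intercept,
#' \deqn{J(w) = -\frac{1}{n}\sum_i \log\sigma(w^\top x_i)
#'   + \lambda_1\|w\|_1 + \frac{\lambda_2}{2}\|w\|_2^2}
#' where the `x_i` are the centered expression profiles of the stem
#' training samples and \eqn{\sigma} is the logistic function. The solver
#' is accelerated proximal gradient (FISTA) with backtracking line search
#' and a monotone restart, declaring convergence when the sup-norm of the
#' minimal subgradient falls below `tol`.
#'
#' @param X genes x samples matrix of CENTERED stem-sample expression.
#' @param l1 L1 penalty (default 0).
#' @param l2 L2 penalty (default 1).
#' @param tol subgradient sup-norm tolerance (default 1e-6).
#' @param maxIter iteration cap (default 10000).
#' @param centeringMeans optional named numeric stored in the model for
#'   later scoring metadata (not used in training).
#' @return A [StemnessModel-class] object.
#' @export
trainOclr <- function(X, l1 = 0, l2 = 1, tol = 1e-6, maxIter = 10000L,
                      centeringMeans = NULL) {
  X <- .asExprMatrix(X, "X")
  if (tol <= 0) stop("tol must be > 0")
  p <- nrow(X); n <- ncol(X)
  if (is.null(centeringMeans)) {
    centeringMeans <- stats::setNames(rep(NA_real_, p), rownames(X))
  } else {
    centeringMeans <- centeringMeans[rownames(X)]
  }

  obj <- function(w) {
    z <- drop(crossprod(X, w))
    -mean(.logSigmoid(z)) + l1 * sum(abs(w)) + (l2 / 2) * sum(w^2)
  }
  smoothGrad <- function(w) {
    z <- drop(crossprod(X, w))
    drop(-(X %*% (1 - .sigmoid(z))) / n) + l2 * w
  }
  # sup-norm of the minimal subgradient of J at w
  subgradNorm <- function(w) {
    g <- smoothGrad(w)
    s <- ifelse(w != 0, abs(g + l1 * sign(w)), pmax(abs(g) - l1, 0))
    max(s)
  }
  prox <- function(v, t) sign(v) * pmax(abs(v) - t * l1, 0)

  w <- numeric(p)
  if (subgradNorm(w) <= tol) {
    model <- methods::new("StemnessModel",
      geneIds = rownames(X), weights = w, l1 = l1, l2 = l2,
      nTrain = n, centeringMeans = unname(centeringMeans),
      converged = TRUE, objective = obj(w))
    return(model)
  }

  # FISTA with backtracking
  L <- max(1e-3, sum(X^2) / (4 * n) + l2)
  y <- w; tk <- 1; fw <- obj(w)
  smooth <- function(w) {
    z <- drop(crossprod(X, w))
    -mean(.logSigmoid(z)) + (l2 / 2) * sum(w^2)
  }
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    g <- smoothGrad(y)
    fy <- smooth(y)
    repeat {
      wNew <- prox(y - g / L, 1 / L)
      d <- wNew - y
      if (smooth(wNew) <= fy + sum(g * d) + (L / 2) * sum(d^2) + 1e-12) break
      L <- 2 * L
    }
    fNew <- obj(wNew)
    if (fNew > fw) {          # monotone restart
      y <- w; tk <- 1
      g <- smoothGrad(y); fy <- smooth(y)
      repeat {
        wNew <- prox(y - g / L, 1 / L)
        d <- wNew - y
        if (smooth(wNew) <= fy + sum(g * d) + (L / 2) * sum(d^2) + 1e-12) break
        L <- 2 * L
      }
      fNew <- obj(wNew)
    }
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- wNew + ((tk - 1) / tNew) * (wNew - w)
    w <- wNew; tk <- tNew; fw <- fNew
    if (it %% 10L == 0L || it < 10L) {
      if (subgradNorm(w) <= tol) { converged <- TRUE; break }
    }
  }
  if (!converged && subgradNorm(w) > tol)
    stop(sprintf(
      "convergence error: OCLR did not converge in %d iterations (J = %.6g, subgradient sup-norm = %.3g)",
      maxIter, obj(w), subgradNorm(w)))
  methods::new("StemnessModel",
    geneIds = rownames(X), weights = w, l1 = l1, l2 = l2,
    nTrain = n, centeringMeans = unname(centeringMeans),
    converged = TRUE, objective = obj(w))
}

#' Score cohort samples with the stemness model (mRNAsi)
#'
#' For each sample, computes the Spearman correlation between the model's
#' weight vector and the sample's expression over the overlapping genes
#' (average ranks for ties), then min-max rescales the correlations to
#' `[0, 1]` within the cohort — the mRNAsi.
#'
#' @param model a [StemnessModel-class].
#' @param X genes x samples cohort matrix.
#' @param minOverlap minimum fraction of model genes that must be present
#'   in the cohort (default 0.5).
#' @return A [StemnessScores-class] object.
#' @export
scoreMrnasi <- function(model, X, minOverlap = 0.5) {
  X <- .asExprMatrix(X, "X")
  ov <- intersect(model@geneIds, rownames(X))
  if (length(ov) < minOverlap * length(model@geneIds))
    stop(sprintf(
      "compatibility error: only %d of %d model genes found (need >= %.0f%%)",
      length(ov), length(model@geneIds), 100 * minOverlap))
  w <- model@weights[match(ov, model@geneIds)]
  rw <- rank(w)
  rho <- apply(X[ov, , drop = FALSE], 2L, function(x)
    stats::cor(rw, rank(x)))
  if (length(rho) >= 2L && diff(range(rho)) < 1e-12)
    stop("degenerate-cohort error: all samples have identical rho; ",
         "mRNAsi is undefined")
  mr <- if (length(rho) == 1L) rho * 0 else
    (rho - min(rho)) / (max(rho) - min(rho))
  methods::new("StemnessScores",
    sampleIds = colnames(X), rho = unname(rho), mrnasi = unname(mr))
}

#' Correlate individual genes with mRNAsi
#'
#' Per-gene Spearman correlation (with p-value from the t-approximation)
#' between a gene's expression and the cohort mRNAsi.
#'
#' @param X genes x samples cohort matrix.
#' @param scores a [StemnessScores-class] for the same samples.
#' @param genes genes to test (must be rows of `X`).
#' @return data.frame with columns `gene`, `rho`, `p`; constant genes get
#'   `NA` with a warning.
#' @export
correlateGenesWithStemness <- function(X, scores, genes) {
  X <- .asExprMatrix(X, "X")
  miss <- setdiff(genes, rownames(X))
  if (length(miss))
    stop("gene(s) not in the matrix: ", paste(miss, collapse = ", "))
  m <- mrnasi(scores)[colnames(X)]
  if (anyNA(m)) stop("scores do not cover all samples of X")
  res <- lapply(genes, function(g) {
    x <- X[g, ]
    if (diff(range(x)) < 1e-12) {
      warning("gene ", g, " is constant; rho undefined")
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, m, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(gene = genes, rho = res[, 1L], p = res[, 2L],
             stringsAsFactors = FALSE)
}
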