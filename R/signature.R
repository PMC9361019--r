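#' Default four-gene response panel
#'
#' The RXRB / NR1H3 / CYP8B1 / SCD analog panel used by the PCA signature.
#' @export
defaultPanelGenes <- function() c("RXRB", "NR1H3", "CYP8B1", "SCD")

#' Fit the PCA signature on a gene panel
#'
#' Standardizes each panel gene to zero mean and unit variance on the
#' fitting cohort, then takes the top-2 right singular vectors of the
#' standardized samples x genes matrix as loadings. Each component's sign
#' is fixed so its largest-|loading| entry is positive — without a sign
#' convention the summed score (and any fixed cutoff on it) would be
#' meaningless.
#'
#' @param X genes x samples matrix containing the panel genes.
#' @param panelGenes character vector of panel genes
#'   (default [defaultPanelGenes()]).
#' @return A [SignaturePanel-class] object.
#' @export
fitSignature <- function(X, panelGenes = defaultPanelGenes()) {
  X <- .asExprMatrix(X, "X")
  miss <- setdiff(panelGenes, rownames(X))
  if (length(miss))
    stop("compatibility error: panel gene(s) missing: ",
         paste(miss, collapse = ", "))
  Xp <- X[panelGenes, , drop = FALSE]
  if (ncol(Xp) < 3L) stop("domain error: need >= 3 samples to fit")
  mu <- rowMeans(Xp)
  sds <- apply(Xp, 1L, stats::sd)
  if (any(sds == 0))
    stop("domain error: zero-variance panel gene(s): ",
         paste(panelGenes[sds == 0], collapse = ", "))
  Z <- t((Xp - mu) / sds)              # samples x genes, standardized
  sv <- svd(Z, nu = 0L, nv = min(2L, ncol(Z)))
  V <- sv$v[, 1:2, drop = FALSE]
  for (a in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, a])), a] < 0) V[, a] <- -V[, a]
  }
  rownames(V) <- panelGenes
  methods::new("SignaturePanel",
    geneIds = panelGenes, means = unname(mu), sds = unname(sds),
    loadings = V,
    explainedVariance = sv$d[1:2]^2 / (nrow(Z) - 1L))
}

#' Project samples onto a fitted signature panel
#'
#' New samples are standardized with the panel's stored means and SDs and
#' projected onto the stored loadings; the summed score is
#' `pparscore = dim1 + dim2`. Projection (rather than refitting) keeps the
#' score comparable across cohorts, including cohorts too small for a
#' stable refit.
#'
#' @param panel a [SignaturePanel-class].
#' @param X genes x samples matrix containing the panel genes.
#' @param refit refit the PCA on `X` instead of projecting (default FALSE).
#' @return A [SignatureScores-class] (without predicted classes; see
#'   [classifyResponse()]).
#' @export
scoreSignature <- function(panel, X, refit = FALSE) {
  X <- .asExprMatrix(X, "X")
  if (refit) panel <- fitSignature(X, panel@geneIds)
  miss <- setdiff(panel@geneIds, rownames(X))
  if (length(miss))
    stop("compatibility error: panel gene(s) missing: ",
         paste(miss, collapse = ", "))
  Xp <- X[panel@geneIds, , drop = FALSE]
  Z <- t((Xp - panel@means) / panel@sds)
  dims <- Z %*% panel@loadings
  methods::new("SignatureScores",
    sampleIds = colnames(X),
    dim1 = unname(dims[, 1L]), dim2 = unname(dims[, 2L]),
    pparscore = unname(dims[, 1L] + dims[, 2L]),
    predicted = character())
}

#' ROC curve, AUC, and the closest-top-left cutoff
#'
#' The AUC is computed by the Mann-Whitney identity (ties counted 1/2).
#' Candidate thresholds are the midpoints of consecutive sorted unique
#' scores plus infinities; a sample is called positive when its score is
#' strictly greater than the threshold. The optimal cutoff minimizes the
#' squared distance to the top-left corner,
#' `(1 - sensitivity)^2 + (1 - specificity)^2`, with ties broken by higher
#' sensitivity and then lower threshold.
#'
#' @param scores numeric scores, or a [SignatureScores-class] (uses
#'   `pparscore`).
#' @param labels per-sample class labels.
#' @param positive label treated as the positive class
#'   (default `"non_responder"`).
#' @return list of class `"rocResult"`: `thresholds` (decreasing), `tpr`,
#'   `fpr` (both non-decreasing), `auc`, `optimalCutoff`,
#'   `sensitivityAtCutoff`, `specificityAtCutoff`.
#' @export
rocCurve <- function(scores, labels, positive = "non_responder") {
  if (methods::is(scores, "SignatureScores")) scores <- pparScore(scores)
  labels <- as.character(labels)
  if (!positive %in% labels || all(labels == positive))
    stop("domain error: both classes must be present")
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  nP <- length(pos); nN <- length(neg)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
  u <- sort(unique(scores))
  thr <- c(Inf, rev((u[-1] + u[-length(u)]) / 2), -Inf)
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  d2 <- (1 - tpr)^2 + fpr^2
  best <- order(d2, -tpr, thr)[1L]
  structure(list(
    thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
    optimalCutoff = thr[best],
    sensitivityAtCutoff = tpr[best],
    specificityAtCutoff = 1 - fpr[best]
  ), class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f; optimal cutoff = %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$optimalCutoff, x$sensitivityAtCutoff,
              x$specificityAtCutoff))
  invisible(x)
}

#' Classify response from signature scores
#'
#' Samples with score strictly greater than the cutoff are predicted
#' non-responders (resistant); all others responders. The default cutoff
#' of -0.56 is the published ROC-optimal threshold for this signature.
#'
#' @param scores a [SignatureScores-class] or numeric vector.
#' @param cutoff classification threshold (default -0.56).
#' @return The input [SignatureScores-class] with `predicted` filled, or a
#'   character vector for numeric input.
#' @export
classifyResponse <- function(scores, cutoff = -0.56) {
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  if (methods::is(scores, "SignatureScores")) {
    pred <- ifelse(scores@pparscore > cutoff, "non_responder", "responder")
    return(methods::new("SignatureScores",
      sampleIds = scores@sampleIds, dim1 = scores@dim1, dim2 = scores@dim2,
      pparscore = scores@pparscore, predicted = pred))
  }
  ifelse(scores > cutoff, "non_responder", "responder")
}
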