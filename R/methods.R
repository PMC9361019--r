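#' @rdname accessors
#' @aliases geneIds,StemnessModel-method
setMethod("geneIds", "StemnessModel", function(object) object@geneIds)

#' @rdname accessors
setMethod("geneIds", "SignaturePanel", function(object) object@geneIds)

#' @rdname accessors
setMethod("stemnessWeights", "StemnessModel", function(object) {
  stats::setNames(object@weights, object@geneIds)
})

#' @rdname accessors
setMethod("sampleIds", "StemnessScores", function(object) object@sampleIds)

#' @rdname accessors
setMethod("sampleIds", "SignatureScores", function(object) object@sampleIds)

#' @rdname accessors
setMethod("mrnasi", "StemnessScores", function(object) {
  stats::setNames(object@mrnasi, object@sampleIds)
})

#' @rdname accessors
setMethod("rawRho", "StemnessScores", function(object) {
  stats::setNames(object@rho, object@sampleIds)
})

#' @rdname accessors
setMethod("chosenK", "ConsensusResult", function(object) object@chosenK)

#' @rdname accessors
setMethod("clusterLabels", "ConsensusResult", function(object) object@labels)

#' @rdname accessors
#' @param k cluster count whose consensus matrix is requested.
setMethod("consensusMatrix", "ConsensusResult", function(object, k) {
  i <- match(as.integer(k), object@kRange)
  if (is.na(i)) stop("k = ", k, " is not in the evaluated kRange")
  object@consensusMatrices[[i]]
})

#' @rdname accessors
setMethod("networkEdges", "BNetwork", function(object) object@edges)

#' @rdname accessors
setMethod("signatureLoadings", "SignaturePanel", function(object) object@loadings)

#' @rdname accessors
setMethod("pparScore", "SignatureScores", function(object) {
  stats::setNames(object@pparscore, object@sampleIds)
})

#' @rdname accessors
setMethod("predictedResponse", "SignatureScores", function(object) {
  if (!length(object@predicted)) return(NULL)
  stats::setNames(object@predicted, object@sampleIds)
})

setMethod("show", "StemnessModel", function(object) {
  cat("StemnessModel (one-class logistic regression)\n")
  cat("  genes:      ", length(object@geneIds), "\n", sep = "")
  cat("  trained on: ", object@nTrain, " stem samples\n", sep = "")
  cat(sprintf("  penalties:  l1 = %g, l2 = %g\n", object@l1, object@l2))
  cat(sprintf("  objective:  %.6g (converged: %s)\n",
              object@objective, object@converged))
  nz <- sum(object@weights != 0)
  cat("  non-zero weights: ", nz, "\n", sep = "")
})

setMethod("show", "StemnessScores", function(object) {
  cat("StemnessScores for ", length(object@sampleIds), " samples\n", sep = "")
  cat(sprintf("  rho:    [%.3f, %.3f]\n", min(object@rho), max(object@rho)))
  cat(sprintf("  mRNAsi: median %.4f\n", stats::median(object@mrnasi)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k = ",
      paste(range(object@kRange), collapse = ".."), "\n", sep = "")
  cat("  chosen k: ", object@chosenK, "\n", sep = "")
  cat("  cluster sizes: ",
      paste(table(object@labels), collapse = ", "), "\n", sep = "")
})

setMethod("show", "BNetwork", function(object) {
  cat("BNetwork with ", length(object@nodes), " nodes, ",
      nrow(object@edges), " consensus edges (R = ", object@nBootstrap,
      ", threshold = ", object@strengthThreshold, ")\n", sep = "")
  if (nrow(object@edges)) {
    e <- object@edges[order(-object@edges$strength), , drop = FALSE]
    for (i in seq_len(min(10L, nrow(e)))) {
      cat(sprintf("  %s -> %s  strength %.2f  direction %.2f\n",
                  e$from[i], e$to[i], e$strength[i], e$directionConfidence[i]))
    }
  }
})

setMethod("show", "SignaturePanel", function(object) {
  cat("SignaturePanel on ", length(object@geneIds), " genes: ",
      paste(object@geneIds, collapse = ", "), "\n", sep = "")
  ev <- object@explainedVariance / sum(object@explainedVariance)
  cat(sprintf("  PC1/PC2 variance share of top-2 space: %.2f / %.2f\n",
              ev[1], ev[2]))
})

setMethod("show", "SignatureScores", function(object) {
  cat("SignatureScores for ", length(object@sampleIds), " samples\n", sep = "")
  cat(sprintf("  PPARscore: [%.3f, %.3f]\n",
              min(object@pparscore), max(object@pparscore)))
  if (length(object@predicted)) {
    tab <- table(object@predicted)
    cat("  predicted: ",
        paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
  }
})
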