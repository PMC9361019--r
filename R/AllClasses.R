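#' @import methods
NULL

#' One-class logistic regression stemness model
#'
#' Holds the per-gene stemness weight vector learned from a stem-cell
#' reference compendium, together with the elastic-net penalties used, the
#' per-gene centering means of the full compendium, and convergence metadata.
#'
#' @slot geneIds character, ordered gene identifiers.
#' @slot weights numeric, one weight per gene (the stemness weight w).
#' @slot l1 numeric(1), L1 penalty coefficient.
#' @slot l2 numeric(1), L2 penalty coefficient.
#' @slot nTrain integer(1), number of stem samples used for training.
#' @slot centeringMeans numeric, per-gene reference means subtracted before
#'   training (taken over the full compendium, stem and differentiated).
#' @slot converged logical(1), whether the optimizer met its tolerance.
#' @slot objective numeric(1), final penalized objective value.
#'
#' @exportClass StemnessModel
setClass("StemnessModel",
  representation(
    geneIds = "character",
    weights = "numeric",
    l1 = "numeric",
    l2 = "numeric",
    nTrain = "integer",
    centeringMeans = "numeric",
    converged = "logical",
    objective = "numeric"
  )
)

setValidity("StemnessModel", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@geneIds))
    msg <- c(msg, "weights and geneIds must have equal length")
  if (length(object@centeringMeans) != length(object@geneIds))
    msg <- c(msg, "centeringMeans and geneIds must have equal length")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "geneIds must be unique")
  if (!all(is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (length(object@l1) != 1L || object@l1 < 0)
    msg <- c(msg, "l1 must be a single non-negative value")
  if (length(object@l2) != 1L || object@l2 < 0)
    msg <- c(msg, "l2 must be a single non-negative value")
  if (!isTRUE(object@converged))
    msg <- c(msg, "model must carry converged = TRUE")
  if (length(msg)) msg else TRUE
})

#' Per-sample stemness scores
#'
#' Raw Spearman correlations between the model weight vector and each
#' sample's expression profile (`rho`), and their per-cohort min-max
#' rescaling to `[0, 1]` (`mrnasi`).
#'
#' @slot sampleIds character, ordered sample identifiers.
#' @slot rho numeric, raw Spearman correlation per sample, in `[-1, 1]`.
#' @slot mrnasi numeric, rescaled stemness index per sample, in `[0, 1]`.
#'
#' @exportClass StemnessScores
setClass("StemnessScores",
  representation(
    sampleIds = "character",
    rho = "numeric",
    mrnasi = "numeric"
  )
)

setValidity("StemnessScores", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@rho) != n || length(object@mrnasi) != n)
    msg <- c(msg, "sampleIds, rho and mrnasi must have equal length")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sampleIds must be unique")
  if (any(object@rho < -1 - 1e-12 | object@rho > 1 + 1e-12))
    msg <- c(msg, "rho must lie in [-1, 1]")
  if (any(object@mrnasi < -1e-12 | object@mrnasi > 1 + 1e-12))
    msg <- c(msg, "mrnasi must lie in [0, 1]")
  if (n >= 2 && length(unique(object@rho)) >= 2) {
    if (abs(min(object@mrnasi)) > 1e-9 || abs(max(object@mrnasi) - 1) > 1e-9)
      msg <- c(msg, "mrnasi must attain 0 and 1 in a non-degenerate cohort")
    if (!identical(order(object@mrnasi), order(object@rho)))
      msg <- c(msg, "mrnasi must preserve the rank order of rho")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' Per-k consensus matrices from Monti subsampling, the areas under their
#' consensus CDFs, the relative delta-area series used to choose the cluster
#' count, and the final sample labels.
#'
#' @slot kRange integer, candidate cluster counts.
#' @slot consensusMatrices list of symmetric sample-by-sample matrices, one
#'   per k, entries in `[0, 1]` with unit diagonal.
#' @slot cdfAreas numeric, area under the consensus CDF per k.
#' @slot deltaAreas numeric, relative area increase per k.
#' @slot chosenK integer(1), selected cluster count.
#' @slot labels integer, final cluster id per sample (named).
#'
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(
    kRange = "integer",
    consensusMatrices = "list",
    cdfAreas = "numeric",
    deltaAreas = "numeric",
    chosenK = "integer",
    labels = "integer"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  if (length(object@consensusMatrices) != length(object@kRange))
    msg <- c(msg, "one consensus matrix per k is required")
  for (m in object@consensusMatrices) {
    if (!is.matrix(m) || !isSymmetric(unname(m), tol = 1e-8)) {
      msg <- c(msg, "consensus matrices must be symmetric")
      break
    }
    if (any(m < -1e-9 | m > 1 + 1e-9) || any(abs(diag(m) - 1) > 1e-9)) {
      msg <- c(msg, "consensus entries must lie in [0,1] with unit diagonal")
      break
    }
  }
  if (length(object@chosenK) != 1L || !(object@chosenK %in% object@kRange))
    msg <- c(msg, "chosenK must be one of kRange")
  if (length(unique(object@labels)) != object@chosenK)
    msg <- c(msg, "labels must take exactly chosenK distinct values")
  if (length(msg)) msg else TRUE
})

#' Bootstrap-consensus Bayesian network
#'
#' Nodes and consensus directed edges from bootstrap structure learning:
#' each edge carries the fraction of bootstrap networks containing it in
#' either orientation (`strength`) and the fraction of those oriented
#' from -> to (`directionConfidence`).
#'
#' @slot nodes character, variable names.
#' @slot edges data.frame with columns `from`, `to`, `strength`,
#'   `directionConfidence`.
#' @slot nBootstrap integer(1), number of bootstrap resamples.
#' @slot strengthThreshold numeric(1), consensus inclusion threshold.
#'
#' @exportClass BNetwork
setClass("BNetwork",
  representation(
    nodes = "character",
    edges = "data.frame",
    nBootstrap = "integer",
    strengthThreshold = "numeric"
  )
)

setValidity("BNetwork", function(object) {
  msg <- character()
  need <- c("from", "to", "strength", "directionConfidence")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges must have columns from, to, strength, directionConfidence")
  else {
    if (nrow(object@edges) &&
        (any(object@edges$strength < 0 | object@edges$strength > 1) ||
         any(object@edges$strength < object@strengthThreshold - 1e-12)))
      msg <- c(msg, "edge strengths must lie in [0,1] and pass the threshold")
    if (nrow(object@edges) &&
        !all(object@edges$from %in% object@nodes & object@edges$to %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (object@strengthThreshold <= 0 || object@strengthThreshold > 1)
    msg <- c(msg, "strengthThreshold must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PCA signature panel
#'
#' Standardization constants and top-2 principal-component loadings fitted on
#' a small gene panel (by default the four-gene RXRB/NR1H3/CYP8B1/SCD analog
#' panel); new cohorts are projected with the stored constants.
#'
#' @slot geneIds character, panel genes.
#' @slot means numeric, per-gene standardization means from the fitting cohort.
#' @slot sds numeric, per-gene standardization SDs (all > 0).
#' @slot loadings matrix, genes x 2 orthonormal loading vectors, sign-fixed so
#'   the largest-|loading| entry of each component is positive.
#' @slot explainedVariance numeric(2), variance explained by each component.
#'
#' @exportClass SignaturePanel
setClass("SignaturePanel",
  representation(
    geneIds = "character",
    means = "numeric",
    sds = "numeric",
    loadings = "matrix",
    explainedVariance = "numeric"
  )
)

setValidity("SignaturePanel", function(object) {
  msg <- character()
  p <- length(object@geneIds)
  if (length(object@means) != p || length(object@sds) != p)
    msg <- c(msg, "means and sds must match geneIds")
  if (any(object@sds <= 0))
    msg <- c(msg, "standardization sds must be positive")
  if (!all(dim(object@loadings) == c(p, 2L)))
    msg <- c(msg, "loadings must be a genes x 2 matrix")
  else {
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(2))) > 1e-6)
      msg <- c(msg, "loadings must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample signature scores
#'
#' Coordinates of samples on the panel's first two principal components and
#' their sum, the PPAR-style risk score; optionally a predicted response
#' class from a fixed cutoff.
#'
#' @slot sampleIds character, sample identifiers.
#' @slot dim1 numeric, coordinate on PC1 per sample.
#' @slot dim2 numeric, coordinate on PC2 per sample.
#' @slot pparscore numeric, `dim1 + dim2` per sample.
#' @slot predicted character, `"responder"`/`"non_responder"` per sample, or
#'   length zero before classification.
#'
#' @exportClass SignatureScores
setClass("SignatureScores",
  representation(
    sampleIds = "character",
    dim1 = "numeric",
    dim2 = "numeric",
    pparscore = "numeric",
    predicted = "character"
  )
)

setValidity("SignatureScores", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@dim1) != n || length(object@dim2) != n ||
      length(object@pparscore) != n)
    msg <- c(msg, "dim1, dim2 and pparscore must match sampleIds")
  if (n && max(abs(object@pparscore - (object@dim1 + object@dim2))) > 1e-10)
    msg <- c(msg, "pparscore must equal dim1 + dim2")
  if (length(object@predicted) &&
      (length(object@predicted) != n ||
       !all(object@predicted %in% c("responder", "non_responder"))))
    msg <- c(msg, "predicted must be responder/non_responder per sample")
  if (length(msg)) msg else TRUE
})
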