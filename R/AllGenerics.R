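#' Accessor generics
#'
#' Small accessor family for the package's S4 result objects.
#'
#' @param object an object of one of the package's S4 classes.
#' @return The slot contents; see the method for each class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("stemnessWeights", function(object) standardGeneric("stemnessWeights"))

#' @rdname accessors
#' @export
setGeneric("mrnasi", function(object) standardGeneric("mrnasi"))

#' @rdname accessors
#' @export
setGeneric("rawRho", function(object) standardGeneric("rawRho"))

#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(object, k) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("signatureLoadings", function(object) standardGeneric("signatureLoadings"))

#' @rdname accessors
#' @export
setGeneric("pparScore", function(object) standardGeneric("pparScore"))

#' @rdname accessors
#' @export
setGeneric("predictedResponse", function(object) standardGeneric("predictedResponse"))
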