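#' Accessor generics
#'
#' Small accessor family for the package's S4 containers. Use these instead of
#' reaching into slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname accessors
#' @export
setGeneric("majorRegion", function(x) standardGeneric("majorRegion"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("eligibleMask", function(x) standardGeneric("eligibleMask"))

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname accessors
#' @export
setGeneric("normalizationState", function(x) standardGeneric("normalizationState"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("canonicalCorrelations", function(x) standardGeneric("canonicalCorrelations"))

#' @rdname accessors
#' @export
setGeneric("sourceWeights", function(x) standardGeneric("sourceWeights"))

#' @rdname accessors
#' @export
setGeneric("targetWeights", function(x) standardGeneric("targetWeights"))

#' @rdname accessors
#' @export
setGeneric("sourceMaps", function(x) standardGeneric("sourceMaps"))

#' @rdname accessors
#' @export
setGeneric("targetMaps", function(x) standardGeneric("targetMaps"))

## ---- methods ----

#' @rdname accessors
#' @export
setMethod("regionIds", "RegionAtlas", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("regionIds", "Connectome", function(x) x@regionIds)

#' @rdname accessors
#' @export
setMethod("majorRegion", "RegionAtlas", function(x) x@majorRegion)

#' @rdname accessors
#' @export
setMethod("centroids", "RegionAtlas", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("nRegions", "RegionAtlas", function(x) length(x@regionIds))

#' @rdname accessors
#' @export
setMethod("nRegions", "Connectome", function(x) length(x@regionIds))

#' @rdname accessors
#' @export
setMethod("adjacency", "Connectome", function(x) x@adjacency)

#' @rdname accessors
#' @export
setMethod("eligibleMask", "Connectome", function(x) x@eligibleMask)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("geneSymbols", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setMethod("normalizationState", "ExpressionMatrix", function(x) x@normalizationState)

#' @rdname accessors
#' @export
setMethod("scores", "ReducedExpression", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("loadings", "ReducedExpression", function(x) x@loadings)

#' @rdname accessors
#' @export
setMethod("explainedVariance", "ReducedExpression", function(x) x@explainedVarianceRatio)

#' @rdname accessors
#' @export
setMethod("canonicalCorrelations", "WiringPI", function(x) x@rho)

#' @rdname accessors
#' @export
setMethod("sourceWeights", "WiringPI", function(x) x@A)

#' @rdname accessors
#' @export
setMethod("targetWeights", "WiringPI", function(x) x@B)

#' @rdname accessors
#' @export
setMethod("sourceMaps", "PIMaps", function(x) x@Ps)

#' @rdname accessors
#' @export
setMethod("targetMaps", "PIMaps", function(x) x@Pt)

## ---- show methods ----

setMethod("show", "RegionAtlas", function(object) {
  cat(sprintf("RegionAtlas: %d regions, %d major regions\n",
              length(object@regionIds), nlevels(droplevels(object@majorRegion))))
})

setMethod("show", "Connectome", function(object) {
  n <- sum(object@adjacency[object@eligibleMask])
  cat(sprintf("Connectome: %d regions, %d eligible cells, %d eligible connections\n",
              length(object@regionIds), sum(object@eligibleMask), n))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d regions x %d genes (%s)\n",
              nrow(object@values), ncol(object@values), object@normalizationState))
})

setMethod("show", "ReducedExpression", function(object) {
  cat(sprintf("ReducedExpression: %d regions x %d components (%.1f%% variance)\n",
              nrow(object@scores), ncol(object@scores),
              100 * sum(object@explainedVarianceRatio)))
})

setMethod("show", "ConnectionPairs", function(object) {
  cat(sprintf("ConnectionPairs: %d connections, D = %d\n",
              length(object@sourceIdx), ncol(object@Xs)))
})

setMethod("show", "HoldoutSplit", function(object) {
  cat(sprintf("HoldoutSplit: %d train / %d test cells (test fraction %.2f, seed %d)\n",
              length(object@trainCells), length(object@testCells),
              object@testFraction, object@seed))
})

setMethod("show", "WiringPI", function(object) {
  cat(sprintf("WiringPI: K = %d components, rho = %s\n",
              length(object@rho),
              paste(sprintf("%.3f", object@rho), collapse = ", ")))
})

setMethod("show", "PIMaps", function(object) {
  cat(sprintf("PIMaps: %d regions x %d components (source and target)\n",
              nrow(object@Ps), ncol(object@Ps)))
})

setMethod("show", "DPIMatrix", function(object) {
  cat(sprintf("DPIMatrix: %d x %d, first %d components\n",
              nrow(object@values), ncol(object@values), object@kUsed))
})

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf("SpatialWeights: %d regions, scheme %s%s\n",
              nrow(object@W), object@scheme,
              if (object@rowStandardized) ", row-standardized" else ""))
})
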