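#' Accessors for pseudocascade classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @return `cellIds()`: character vector of cell identifiers.
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname accessors
#' @return `pseudotime()`: numeric pseudotime values.
#' @export
setGeneric("pseudotime", function(object) standardGeneric("pseudotime"))

#' @rdname accessors
#' @export
setMethod("cellIds", "CellOrdering", function(object) object@cellIds)

#' @rdname accessors
#' @export
setMethod("pseudotime", "CellOrdering", function(object) object@pseudotime)

#' @rdname accessors
#' @export
setMethod("cellIds", "TrajectoryFit", function(object) object@cellIds)

#' @rdname accessors
#' @export
setMethod("pseudotime", "TrajectoryFit", function(object) object@pseudotime)

#' @rdname accessors
#' @return `termIds()`: character vector of term identifiers.
#' @export
setGeneric("termIds", function(object) standardGeneric("termIds"))

#' @rdname accessors
#' @export
setMethod("termIds", "TermAnnotation", function(object) names(object@sets))

#' @rdname accessors
#' @return `termNames()`: named character vector of term display names.
#' @export
setGeneric("termNames", function(object) standardGeneric("termNames"))

#' @rdname accessors
#' @export
setMethod("termNames", "TermAnnotation", function(object) object@termNames)

#' @rdname accessors
#' @return `geneSets()`: named list of member gene vectors.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setMethod("geneSets", "TermAnnotation", function(object) object@sets)

#' @rdname accessors
#' @return `annotationUniverse()`: union of all member sets.
#' @export
setGeneric("annotationUniverse", function(object) standardGeneric("annotationUniverse"))

#' @rdname accessors
#' @export
setMethod("annotationUniverse", "TermAnnotation", function(object) object@universe)

#' @rdname accessors
#' @return `fittedValues()`: genes x cells matrix of fitted expression.
#' @export
setGeneric("fittedValues", function(object) standardGeneric("fittedValues"))

#' @rdname accessors
#' @export
setMethod("fittedValues", "TrajectoryFit", function(object) object@fitted)

#' @rdname accessors
#' @return `scaledValues()`: retained-genes x cells matrix of scaled fits.
#' @export
setGeneric("scaledValues", function(object) standardGeneric("scaledValues"))

#' @rdname accessors
#' @export
setMethod("scaledValues", "TrajectoryFit", function(object) object@scaled)

#' @rdname accessors
#' @return `pValues()`, `qValues()`: named numeric vectors.
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setMethod("pValues", "TrajectoryFit", function(object) object@pvalue)

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))

#' @rdname accessors
#' @export
setMethod("qValues", "TrajectoryFit", function(object) object@qvalue)

#' @rdname accessors
#' @return `retainedGenes()`: identifiers of genes with q-value below the
#'   retention level.
#' @export
setGeneric("retainedGenes", function(object) standardGeneric("retainedGenes"))

#' @rdname accessors
#' @export
setMethod("retainedGenes", "TrajectoryFit",
  function(object) object@geneIds[object@retained])

#' @rdname accessors
#' @return `cascadeTable()`: the per-gene result data.frame in cascade order.
#' @export
setGeneric("cascadeTable", function(object) standardGeneric("cascadeTable"))

#' @rdname accessors
#' @export
setMethod("cascadeTable", "CascadeResult", function(object) object@table)

#' @rdname accessors
#' @return `cascadeOrder()`: gene identifiers in cascade order.
#' @export
setGeneric("cascadeOrder", function(object) standardGeneric("cascadeOrder"))

#' @rdname accessors
#' @export
setMethod("cascadeOrder", "CascadeResult", function(object) object@table$gene)

#' @rdname accessors
#' @return `switchPoints()`: named list of 1-based switch-point index vectors.
#' @export
setGeneric("switchPoints", function(object) standardGeneric("switchPoints"))

#' @rdname accessors
#' @export
setMethod("switchPoints", "CascadeResult", function(object) object@switchPoints)

#' @rdname accessors
#' @return `consistentGenes()`: genes with identical temporal pattern in
#'   every sample.
#' @export
setGeneric("consistentGenes", function(object) standardGeneric("consistentGenes"))

#' @rdname accessors
#' @export
setMethod("consistentGenes", "MultiSampleCascade",
  function(object) object@consistentGenes)

#' @rdname accessors
#' @return `switchPointCI()`: data.frame of mean +/- 2 SE switch-point
#'   intervals on the fraction scale.
#' @export
setGeneric("switchPointCI", function(object) standardGeneric("switchPointCI"))

#' @rdname accessors
#' @export
setMethod("switchPointCI", "MultiSampleCascade", function(object) object@switchCI)

#' @rdname accessors
#' @return `consensusCascade()`: the consensus [CascadeResult-class].
#' @export
setGeneric("consensusCascade", function(object) standardGeneric("consensusCascade"))

#' @rdname accessors
#' @export
setMethod("consensusCascade", "MultiSampleCascade", function(object) object@consensus)
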