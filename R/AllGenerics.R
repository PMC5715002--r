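#' @rdname InteractionMatrix
#' @param object,x an object.
#' @export
setGeneric("interactionValues", function(object)
    standardGeneric("interactionValues"))

#' @rdname InteractionMatrix
#' @export
setGeneric("networkLevel", function(object) standardGeneric("networkLevel"))

#' @rdname InteractionMatrix
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname InteractionMatrix
#' @export
setGeneric("thresholdUsed", function(object)
    standardGeneric("thresholdUsed"))

#' @rdname TaxonRegistry
#' @export
setGeneric("plantInfo", function(object) standardGeneric("plantInfo"))

#' @rdname TaxonRegistry
#' @export
setGeneric("insectInfo", function(object) standardGeneric("insectInfo"))

#' @rdname IndexReport
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))

#' @rdname NullEnsemble
#' @export
setGeneric("nullSummary", function(object) standardGeneric("nullSummary"))

#' @rdname NetworkComparison
#' @export
setGeneric("comparisonTable", function(object)
    standardGeneric("comparisonTable"))

#' @rdname NullEnsemble
#' @export
setGeneric("nullReplicates", function(object)
    standardGeneric("nullReplicates"))
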