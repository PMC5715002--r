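#' Construct an InteractionMatrix
#'
#' @param values plant x pollinator matrix with dimnames.
#' @param level resolution level: "group", "species" or "individual".
#' @param provenance data source: "obs" (visit survey) or "seq"
#'   (metabarcoding).
#' @param threshold read threshold used to call links, or NA.
#' @return an \linkS4class{InteractionMatrix}.
#' @examples
#' m <- InteractionMatrix(matrix(c(2, 1, 0, 3), 2, 2,
#'     dimnames = list(c("p1", "p2"), c("a1", "a2"))))
#' interactionValues(m)
#' @export
InteractionMatrix <- function(values, level = "species", provenance = "obs",
                              threshold = NA_real_) {
    storage.mode(values) <- "double"
    new("InteractionMatrix", values = values, level = level,
        provenance = provenance, threshold = as.numeric(threshold))
}

#' @rdname InteractionMatrix
#' @export
setMethod("interactionValues", "InteractionMatrix",
          function(object) object@values)

#' @rdname InteractionMatrix
#' @export
setMethod("networkLevel", "InteractionMatrix", function(object) object@level)

#' @rdname InteractionMatrix
#' @export
setMethod("provenance", "InteractionMatrix", function(object)
    object@provenance)

#' @rdname InteractionMatrix
#' @export
setMethod("thresholdUsed", "InteractionMatrix", function(object)
    object@threshold)

#' @rdname InteractionMatrix
#' @export
setMethod("dim", "InteractionMatrix", function(x) dim(x@values))

setMethod("show", "InteractionMatrix", function(object) {
    v <- object@values
    cat(sprintf("InteractionMatrix: %d plants x %d pollinators (%s, %s)\n",
                nrow(v), ncol(v), object@level, object@provenance))
    if (!is.na(object@threshold))
        cat(sprintf("  read threshold: %g\n", object@threshold))
    cat(sprintf("  links: %d, total interactions: %g\n",
                sum(v > 0), sum(v)))
})

#' Construct a TaxonRegistry
#'
#' @param plants data.frame with columns taxon, rank, pollination_mode,
#'   morph_group, on_site.
#' @param insects data.frame with columns individual, species, group.
#' @return a \linkS4class{TaxonRegistry}.
#' @export
TaxonRegistry <- function(plants, insects) {
    plants$taxon <- as.character(plants$taxon)
    plants$on_site <- as.logical(plants$on_site)
    insects$individual <- as.character(insects$individual)
    new("TaxonRegistry", plants = as.data.frame(plants),
        insects = as.data.frame(insects))
}

#' @rdname TaxonRegistry
#' @param object a TaxonRegistry.
#' @export
setMethod("plantInfo", "TaxonRegistry", function(object) object@plants)

#' @rdname TaxonRegistry
#' @export
setMethod("insectInfo", "TaxonRegistry", function(object) object@insects)

setMethod("show", "TaxonRegistry", function(object) {
    cat(sprintf("TaxonRegistry: %d plant taxa (%d insect-pollinated), %d insect individuals, %d species\n",
                nrow(object@plants),
                sum(object@plants$pollination_mode == "insect"),
                nrow(object@insects),
                length(unique(object@insects$species))))
})

#' @rdname IndexReport
#' @param object an IndexReport.
#' @export
setMethod("indexValues", "IndexReport", function(object) object@values)

setMethod("show", "IndexReport", function(object) {
    cat(sprintf("IndexReport (%s-level, %s):\n", object@level,
                object@provenance))
    print(round(object@values, 4))
})

#' @rdname NullEnsemble
#' @param object a NullEnsemble.
#' @export
setMethod("nullSummary", "NullEnsemble", function(object) object@summary)

#' @rdname NullEnsemble
#' @export
setMethod("nullReplicates", "NullEnsemble", function(object)
    object@replicates)

setMethod("show", "NullEnsemble", function(object) {
    cat(sprintf("NullEnsemble: %d Patefield replicates (%s CI)\n",
                object@nReplicates, object@ciType))
    print(object@summary, digits = 4)
})

#' @rdname NetworkComparison
#' @param object a NetworkComparison.
#' @export
setMethod("comparisonTable", "NetworkComparison", function(object)
    object@table)

setMethod("show", "NetworkComparison", function(object) {
    cat(sprintf("NetworkComparison: %d rarefied replicates\n",
                object@nReplicates))
    print(object@table, digits = 4)
})
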