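# Network construction: interaction calling from read counts, visit
# matrices, aggregation to species/group level, per-species individual
# networks, contamination profiling and threshold sensitivity.

# Validate a sequence-count table (or a named list of per-marker tables)
# against the registry; returns the list-of-markers form.
.checkSeqTable <- function(seqTable, registry) {
    tables <- if (is.list(seqTable)) seqTable else list(seqTable)
    plants <- plantInfo(registry)
    for (tb in tables) {
        if (any(tb < 0)) {
            bad <- which(tb < 0, arr.ind = TRUE)[1, ]
            stop("negative read count for insect '",
                 rownames(tb)[bad[1]], "', taxon '",
                 colnames(tb)[bad[2]], "'")
        }
        unknown <- setdiff(colnames(tb), plants$taxon)
        if (length(unknown))
            stop("taxa missing from registry: ",
                 paste(unknown, collapse = ", "))
    }
    tables
}

#' Call interactions from a sequence-count table
#'
#' Applies the contamination-motivated read threshold: a link between
#' insect j and plant i is called when more than \code{threshold} reads of
#' taxon i (strictly greater, for either marker when per-marker tables are
#' supplied) were found in j's pollen load. Wind-pollinated taxa (the
#' airborne-contamination background) and taxa resolved above genus level
#' are removed before thresholding; insects with no super-threshold taxon
#' are dropped, as are plants linked to no insect.
#'
#' @param seqTable individual x taxon integer count matrix, or a named
#'   list of such matrices (one per marker, e.g. trnL and ITS1); a link is
#'   called when either marker exceeds the threshold — counts are never
#'   summed across markers.
#' @param registry a \linkS4class{TaxonRegistry} covering all taxa.
#' @param threshold read threshold (default 1000; link iff count > threshold).
#' @return an individual-level binary \linkS4class{InteractionMatrix}
#'   (plants in rows, insect individuals in columns).
#' @examples
#' sc <- simulateScenario(communitySpec(seed = 5))
#' callInteractions(sc$seqTable, sc$registry)
#' @export
callInteractions <- function(seqTable, registry, threshold = 1000) {
    stopifnot(is(registry, "TaxonRegistry"), threshold >= 0)
    tables <- .checkSeqTable(seqTable, registry)
    plants <- plantInfo(registry)
    keep <- plants$taxon[plants$pollination_mode == "insect" &
                         plants$rank %in% c("species", "genus")]
    link <- NULL
    for (tb in tables) {
        cols <- intersect(colnames(tb), keep)
        b <- tb[, cols, drop = FALSE] > threshold
        if (is.null(link)) link <- b
        else {
            stopifnot(identical(dimnames(b), dimnames(link)))
            link <- link | b        # either marker suffices
        }
    }
    m <- t(link) * 1L               # plants in rows, pollinators in columns
    m <- dropEmpty(m)
    if (nrow(m) == 0 || ncol(m) == 0)
        stop("no interaction exceeds the threshold")
    InteractionMatrix(m, level = "individual", provenance = "seq",
                      threshold = threshold)
}

#' Build the individual-level visit matrix
#'
#' Binary plant x insect-individual matrix from the visit table; rows from
#' all communities are merged.
#'
#' @param visits visit table (columns individual, plant at minimum).
#' @return an individual-level binary \linkS4class{InteractionMatrix} with
#'   provenance \code{"obs"}.
#' @export
buildObsMatrix <- function(visits) {
    if (is.null(visits) || nrow(visits) == 0) stop("empty visit table")
    plants <- sort(unique(visits$plant))
    inds <- unique(visits$individual)
    m <- matrix(0L, length(plants), length(inds),
                dimnames = list(plants, inds))
    m[cbind(match(visits$plant, plants),
            match(visits$individual, inds))] <- 1L
    InteractionMatrix(dropEmpty(m), level = "individual",
                      provenance = "obs")
}

#' Aggregate an individual-level network to species or group level
#'
#' At species level the cell (plant, insect species) counts the number of
#' individuals of that species linked to the plant, turning link counts
#' into interaction frequencies. At group level plants are additionally
#' collapsed to the four floral morph groups and insects to the nine
#' pollinator groups. Aggregation conserves the total number of
#' individual-level links.
#'
#' @param m an individual-level \linkS4class{InteractionMatrix}.
#' @param registry a \linkS4class{TaxonRegistry}.
#' @param level \code{"species"} or \code{"group"}.
#' @return an aggregated \linkS4class{InteractionMatrix}.
#' @export
aggregateNetwork <- function(m, registry, level = c("species", "group")) {
    level <- match.arg(level)
    stopifnot(is(m, "InteractionMatrix"), is(registry, "TaxonRegistry"))
    if (networkLevel(m) != "individual")
        stop("aggregation starts from an individual-level matrix")
    v <- interactionValues(m)
    ins <- insectInfo(registry)
    idx <- match(colnames(v), ins$individual)
    if (anyNA(idx))
        stop("insect individuals missing from registry: ",
             paste(colnames(v)[is.na(idx)], collapse = ", "))
    key <- if (level == "species") ins$species[idx] else ins$group[idx]
    agg <- t(rowsum(t(v), group = key))
    if (level == "group") {
        pl <- plantInfo(registry)
        pidx <- match(rownames(agg), pl$taxon)
        if (anyNA(pidx))
            stop("plant taxa missing from registry: ",
                 paste(rownames(agg)[is.na(pidx)], collapse = ", "))
        agg <- rowsum(agg, group = pl$morph_group[pidx])
        agg <- agg[intersect(.MORPH_GROUPS, rownames(agg)),
                   intersect(.INSECT_GROUPS, colnames(agg)), drop = FALSE]
    }
    InteractionMatrix(dropEmpty(agg), level = level,
                      provenance = provenance(m),
                      threshold = thresholdUsed(m))
}

#' Individual-level networks of the most abundant insect species
#'
#' One individual x plant network per insect species with at least
#' \code{minIndividuals} captured individuals in the matrix, each
#' restricted to the plants that species contacts (no all-zero rows or
#' columns).
#'
#' @param m an individual-level \linkS4class{InteractionMatrix}.
#' @param registry a \linkS4class{TaxonRegistry}.
#' @param minIndividuals minimum number of individuals per species.
#' @return named list of \linkS4class{InteractionMatrix} objects, ordered
#'   by decreasing species abundance.
#' @export
perSpeciesNetworks <- function(m, registry, minIndividuals = 10L) {
    stopifnot(is(m, "InteractionMatrix"),
              networkLevel(m) == "individual")
    v <- interactionValues(m)
    ins <- insectInfo(registry)
    sp <- ins$species[match(colnames(v), ins$individual)]
    counts <- sort(table(sp), decreasing = TRUE)
    keep <- names(counts)[counts >= minIndividuals]
    out <- lapply(keep, function(s) {
        sub <- dropEmpty(v[, sp == s, drop = FALSE])
        InteractionMatrix(sub, level = "individual",
                          provenance = provenance(m),
                          threshold = thresholdUsed(m))
    })
    names(out) <- keep
    out
}

#' Profile the airborne-grass contamination
#'
#' Reports the fraction of insects with zero grass reads, with fewer than
#' 100, and with more than the threshold (totals over all wind-pollinated
#' taxa), the maximum per-insect grass total, and the fraction of all
#' grass reads that thresholding removes from the matrices (reads in cells
#' at or below the threshold; super-threshold grass cells are excluded
#' anyway as wind-pollinated).
#'
#' @param seqTable individual x taxon count matrix.
#' @param registry a \linkS4class{TaxonRegistry} flagging grasses as
#'   wind-pollinated.
#' @param threshold read threshold.
#' @return list with elements \code{fractionZero}, \code{fractionBelow100},
#'   \code{fractionAboveThreshold}, \code{maxGrassReads},
#'   \code{fractionReadsRemoved} (NA when there are no grass reads).
#' @export
contaminationProfile <- function(seqTable, registry, threshold = 1000) {
    .checkSeqTable(seqTable, registry)
    if (is.list(seqTable)) seqTable <- seqTable[[1]]
    plants <- plantInfo(registry)
    grass <- plants$taxon[plants$pollination_mode == "wind"]
    g <- seqTable[, intersect(colnames(seqTable), grass), drop = FALSE]
    if (ncol(g) == 0)
        return(list(fractionZero = 0, fractionBelow100 = 0,
                    fractionAboveThreshold = 0, maxGrassReads = 0,
                    fractionReadsRemoved = NA_real_))
    totals <- rowSums(g)
    total_reads <- sum(g)
    removed <- sum(g[g <= threshold])
    list(fractionZero = mean(totals == 0),
         fractionBelow100 = mean(totals < 100),
         fractionAboveThreshold = mean(totals > threshold),
         maxGrassReads = max(totals),
         fractionReadsRemoved = if (total_reads > 0)
             removed / total_reads else NA_real_)
}

#' Sensitivity of the called network to the read threshold
#'
#' Re-calls interactions at each candidate threshold and tabulates network
#' size; the number of links is non-increasing in the threshold.
#'
#' @param seqTable individual x taxon count matrix.
#' @param registry a \linkS4class{TaxonRegistry}.
#' @param thresholds numeric vector of thresholds (> 0 reduction of the
#'   default; 0 means every nonzero count becomes a link).
#' @return data.frame with columns threshold, n_links, n_plants, n_insects.
#' @export
thresholdSensitivity <- function(seqTable, registry,
                                 thresholds = c(250, 500, 1000, 2000, 4000)) {
    stopifnot(all(thresholds >= 0))
    rows <- lapply(sort(thresholds), function(th) {
        m <- tryCatch(callInteractions(seqTable, registry, th),
                      error = function(e) NULL)
        if (is.null(m))
            data.frame(threshold = th, n_links = 0L, n_plants = 0L,
                       n_insects = 0L)
        else {
            v <- interactionValues(m)
            data.frame(threshold = th, n_links = sum(v > 0),
                       n_plants = nrow(v), n_insects = ncol(v))
        }
    })
    do.call(rbind, rows)
}
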