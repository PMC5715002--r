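#' @import methods
NULL

.LEVELS <- c("group", "species", "individual")
.PROVENANCES <- c("obs", "seq")
.MORPH_GROUPS <- c("zygomorphic", "tubular", "ligulate", "actinomorphic")
.INSECT_GROUPS <- c("Apis mellifera", "bumblebees", "wild bees",
                    "other Hymenoptera", "Syrphidae", "Empididae",
                    "other Diptera", "Coleoptera", "Lepidoptera")
.RANKS <- c("species", "genus", "family", "order")

#' InteractionMatrix: a bipartite plant x pollinator network
#'
#' The central container of the package: a non-negative integer matrix with
#' plants in rows and pollinators (groups, species or individual insects)
#' in columns, tagged with its resolution level, its provenance (visit
#' survey \code{"obs"} or metabarcoding \code{"seq"}) and, for sequence
#' networks, the read threshold used to call links.
#'
#' Validity enforces the construction invariants: unique row and column
#' labels, integer non-negative cells, and no all-zero row or column.
#'
#' @slot values plant x pollinator matrix of link counts (binary at the
#'   individual level, individual counts at the species level).
#' @slot level one of \code{"group"}, \code{"species"}, \code{"individual"}.
#' @slot provenance \code{"obs"} or \code{"seq"}.
#' @slot threshold read threshold used to call links (\code{NA} for obs).
#'
#' @aliases InteractionMatrix
#' @exportClass InteractionMatrix
setClass("InteractionMatrix",
    representation(values = "matrix", level = "character",
                   provenance = "character", threshold = "numeric"),
    prototype(values = matrix(1L, 1, 1, dimnames = list("p", "a")),
              level = "species", provenance = "obs", threshold = NA_real_))

setValidity("InteractionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    else {
        if (any(v < 0)) msg <- c(msg, "negative cell values")
        if (any(v != round(v))) msg <- c(msg, "non-integer cell values")
        if (nrow(v) > 0 && ncol(v) > 0) {
            if (any(rowSums(v) == 0)) msg <- c(msg, "all-zero plant row")
            if (any(colSums(v) == 0)) msg <- c(msg, "all-zero pollinator column")
        }
    }
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
        msg <- c(msg, "plant labels must exist and be unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
        msg <- c(msg, "pollinator labels must exist and be unique")
    if (length(object@level) != 1L || !object@level %in% .LEVELS)
        msg <- c(msg, "level must be one of group/species/individual")
    if (length(object@provenance) != 1L ||
        !object@provenance %in% .PROVENANCES)
        msg <- c(msg, "provenance must be 'obs' or 'seq'")
    if (length(msg)) msg else TRUE
})

#' TaxonRegistry: plant and insect metadata
#'
#' Registry of every taxon a network may reference. Plants carry their
#' taxonomic rank, pollination mode (wind vs insect; wind-pollinated grasses
#' are the contamination background and are excluded from networks), floral
#' morphology group, and whether the taxon grows on the surveyed site.
#' Insects carry species and functional group for each captured individual.
#'
#' @slot plants data.frame with columns \code{taxon}, \code{rank},
#'   \code{pollination_mode}, \code{morph_group}, \code{on_site}.
#' @slot insects data.frame with columns \code{individual}, \code{species},
#'   \code{group}.
#'
#' @aliases TaxonRegistry
#' @exportClass TaxonRegistry
setClass("TaxonRegistry",
    representation(plants = "data.frame", insects = "data.frame"))

setValidity("TaxonRegistry", function(object) {
    msg <- character()
    p <- object@plants
    i <- object@insects
    need_p <- c("taxon", "rank", "pollination_mode", "morph_group", "on_site")
    need_i <- c("individual", "species", "group")
    if (!all(need_p %in% names(p)))
        msg <- c(msg, paste("plants needs columns:",
                            paste(need_p, collapse = ", ")))
    else {
        if (anyDuplicated(p$taxon)) msg <- c(msg, "duplicated plant taxon")
        if (!all(p$rank %in% .RANKS))
            msg <- c(msg, "unknown plant rank")
        if (!all(p$pollination_mode %in% c("wind", "insect")))
            msg <- c(msg, "pollination_mode must be wind/insect")
        bad <- !p$morph_group %in% c(.MORPH_GROUPS, NA)
        if (any(bad)) msg <- c(msg, "unknown morph_group")
        if (!is.logical(p$on_site)) msg <- c(msg, "on_site must be logical")
    }
    if (!all(need_i %in% names(i)))
        msg <- c(msg, paste("insects needs columns:",
                            paste(need_i, collapse = ", ")))
    else {
        if (anyDuplicated(i$individual))
            msg <- c(msg, "duplicated insect individual ID")
        if (!all(i$group %in% .INSECT_GROUPS))
            msg <- c(msg, "unknown insect group")
    }
    if (length(msg)) msg else TRUE
})

#' IndexReport: the network-index suite for one matrix
#'
#' Named numeric vector of the standard index suite (species counts,
#' links, connectance, nestedness, modularity, interaction density,
#' linkage levels, H2', evenness, mean d', extreme specialization) for one
#' \linkS4class{InteractionMatrix}, plus the level/provenance tags of the
#' matrix it was computed on.
#'
#' @slot values named numeric vector of indices.
#' @slot level,provenance tags inherited from the source matrix.
#'
#' @aliases IndexReport
#' @exportClass IndexReport
setClass("IndexReport",
    representation(values = "numeric", level = "character",
                   provenance = "character"))

#' NullEnsemble: fixed-marginal null-model distribution of indices
#'
#' Holds the per-replicate index values computed on Patefield-resampled
#' matrices (identical row and column totals as the observed network), the
#' observed values, and the derived 95% confidence intervals with
#' significance flags (observed value outside the CI).
#'
#' @slot observed named numeric vector of observed indices.
#' @slot replicates replicate x index matrix of null values.
#' @slot summary data.frame: index, observed, null_mean, ci_lower, ci_upper,
#'   significant.
#' @slot nReplicates,seed bookkeeping.
#' @slot ciType "percentile" or "normal".
#'
#' @aliases NullEnsemble
#' @exportClass NullEnsemble
setClass("NullEnsemble",
    representation(observed = "numeric", replicates = "matrix",
                   summary = "data.frame", nReplicates = "integer",
                   seed = "integer", ciType = "character"))

setValidity("NullEnsemble", function(object) {
    s <- object@summary
    if (nrow(s) && any(s$ci_lower > s$ci_upper, na.rm = TRUE))
        return("CI bounds out of order")
    TRUE
})

#' NetworkComparison: rarefaction-based obs vs seq comparison
#'
#' Result of the size- and effort-matched comparison between a metabarcoding
#' network and a visit-survey network: both matrices restricted to shared
#' species, the seq network repeatedly downsampled by a multinomial draw to
#' the obs interaction total, and each index compared against the rarefied
#' distribution by an empirical two-tailed p-value with Bonferroni
#' correction.
#'
#' @slot table data.frame: index, obs value, seq value, rarefied mean,
#'   direction, p, p_adj, letters.
#' @slot replicates replicate x index matrix of rarefied values.
#' @slot nReplicates,seed bookkeeping.
#'
#' @aliases NetworkComparison
#' @exportClass NetworkComparison
setClass("NetworkComparison",
    representation(table = "data.frame", replicates = "matrix",
                   nReplicates = "integer", seed = "integer"))

setValidity("NetworkComparison", function(object) {
    t <- object@table
    msg <- character()
    if (nrow(t)) {
        p_ok <- is.na(t$p) | (t$p > 0 & t$p <= 1)
        if (!all(p_ok)) msg <- c(msg, "p-values must lie in (0, 1]")
        adj_ok <- is.na(t$p_adj) | (t$p_adj >= t$p - 1e-12 & t$p_adj <= 1)
        if (!all(adj_ok)) msg <- c(msg, "adjusted p must satisfy p <= p_adj <= 1")
    }
    if (length(msg)) msg else TRUE
})

#' CommunitySpec: parameters of the synthetic plant-pollinator community
#'
#' Describes the community the synthetic-data generator draws from: numbers
#' of plant taxa, insect species and captured individuals, the lognormal
#' skew of the plant rank-abundance curve (few common, many rare taxa), the
#' insect-group x floral-morph visit-propensity matrix (bees concentrate on
#' zygomorphic flowers, hoverflies on actinomorphic ones), and the fraction
#' of plant taxa growing off the surveyed site (reachable by foraging
#' insects, hence visible to metabarcoding but never to the visit survey).
#'
#' @slot nPlantSpecies,nInsectSpecies,nInsectIndividuals community sizes.
#' @slot plantAbundanceShape sdlog of the lognormal rank-abundance law.
#' @slot groupPreference insect-group x morph-group propensity matrix;
#'   rows sum to 1.
#' @slot groupShare expected share of captured individuals per insect group.
#' @slot offSiteFraction proportion of plant taxa flagged off-site.
#' @slot higherRankFraction proportion of plant taxa resolved only above
#'   genus level (discarded during interaction calling).
#' @slot genusRankFraction proportion of plant taxa resolved at genus level
#'   (kept as genus nodes).
#' @slot meanVisits mean of the zero-truncated Poisson latent visit-history
#'   length per insect.
#' @slot seed integer seed.
#'
#' @aliases CommunitySpec
#' @exportClass CommunitySpec
setClass("CommunitySpec",
    representation(nPlantSpecies = "integer", nInsectSpecies = "integer",
                   nInsectIndividuals = "integer",
                   plantAbundanceShape = "numeric",
                   groupPreference = "matrix", groupShare = "numeric",
                   offSiteFraction = "numeric",
                   higherRankFraction = "numeric",
                   genusRankFraction = "numeric",
                   meanVisits = "numeric", seed = "integer"))

setValidity("CommunitySpec", function(object) {
    msg <- character()
    if (object@nPlantSpecies < 1L || object@nInsectSpecies < 1L ||
        object@nInsectIndividuals < 1L)
        msg <- c(msg, "all community counts must be > 0")
    gp <- object@groupPreference
    if (!identical(sort(rownames(gp)), sort(.INSECT_GROUPS)) ||
        !identical(sort(colnames(gp)), sort(.MORPH_GROUPS)))
        msg <- c(msg, "groupPreference must be insect-group x morph-group")
    else {
        if (any(gp < 0)) msg <- c(msg, "propensities must be >= 0")
        if (any(abs(rowSums(gp) - 1) > 1e-8))
            msg <- c(msg, "each groupPreference row must sum to 1")
    }
    if (object@offSiteFraction < 0 || object@offSiteFraction > 1)
        msg <- c(msg, "offSiteFraction must lie in [0, 1]")
    if (object@plantAbundanceShape <= 0)
        msg <- c(msg, "plantAbundanceShape must be > 0")
    if (object@meanVisits < 1)
        msg <- c(msg, "meanVisits must be >= 1")
    if (length(msg)) msg else TRUE
})

#' ContaminationSpec: airborne-grass background contamination
#'
#' Parameters of the background read contamination by wind-pollinated
#' grasses that motivates the read threshold: the probability an insect
#' carries no grass reads at all, a heavy-tailed (lognormal) law for the
#' total grass read count of contaminated insects, and the probability
#' that a true visit leaves only a sub-threshold read count (carryover
#' loss).
#'
#' @slot nGrassTaxa number of wind-pollinated grass taxa.
#' @slot pZeroGrass probability an insect carries zero grass reads.
#' @slot grassMeanlog,grassSdlog lognormal parameters of the total grass
#'   read count of contaminated insects.
#' @slot carryoverRate probability a true visit yields only sub-threshold
#'   reads.
#'
#' @aliases ContaminationSpec
#' @exportClass ContaminationSpec
setClass("ContaminationSpec",
    representation(nGrassTaxa = "integer", pZeroGrass = "numeric",
                   grassMeanlog = "numeric", grassSdlog = "numeric",
                   carryoverRate = "numeric"))

setValidity("ContaminationSpec", function(object) {
    msg <- character()
    probs <- c(object@pZeroGrass, object@carryoverRate)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@nGrassTaxa < 0) msg <- c(msg, "nGrassTaxa must be >= 0")
    if (object@grassSdlog <= 0) msg <- c(msg, "grassSdlog must be > 0")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: the known interaction structure behind a synthetic scenario
#'
#' @slot plants data.frame of plant taxa (taxon, rank, morph_group,
#'   on_site, abundance).
#' @slot insects data.frame of captured individuals (individual, species,
#'   group).
#' @slot propensity plant x individual matrix of visit propensities; each
#'   column sums to 1.
#' @slot spec the \linkS4class{CommunitySpec} used.
#'
#' @aliases GroundTruth
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(plants = "data.frame", insects = "data.frame",
                   propensity = "matrix", spec = "CommunitySpec"))

setValidity("GroundTruth", function(object) {
    msg <- character()
    pr <- object@propensity
    if (nrow(pr) != nrow(object@plants))
        msg <- c(msg, "propensity rows must match plant taxa")
    if (ncol(pr) != nrow(object@insects))
        msg <- c(msg, "propensity columns must match insect individuals")
    if (ncol(pr) && any(abs(colSums(pr) - 1) > 1e-8))
        msg <- c(msg, "each propensity column must sum to 1")
    if (length(msg)) msg else TRUE
})
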