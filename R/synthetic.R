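#' Default insect-group x floral-morph visit propensities
#'
#' Rows are the nine pollinator groups, columns the four floral morphology
#' groups (ordered by decreasing reward restriction: zygomorphic, tubular,
#' ligulate, actinomorphic). Bees concentrate on zygomorphic flowers
#' (86% of bee visits), hoverflies and other flies on open actinomorphic
#' flowers; values are package defaults emulating a subalpine heathland
#' community and can be overridden per scenario.
#'
#' @return a 9 x 4 row-stochastic matrix.
#' @export
defaultGroupPreference <- function() {
    m <- rbind(
        "Apis mellifera"    = c(0.86, 0.05, 0.04, 0.05),
        "bumblebees"        = c(0.86, 0.05, 0.04, 0.05),
        "wild bees"         = c(0.86, 0.05, 0.04, 0.05),
        "other Hymenoptera" = c(0.40, 0.10, 0.10, 0.40),
        "Syrphidae"         = c(0.05, 0.05, 0.20, 0.70),
        "Empididae"         = c(0.47, 0.05, 0.08, 0.40),
        "other Diptera"     = c(0.10, 0.05, 0.20, 0.65),
        "Coleoptera"        = c(0.03, 0.02, 0.25, 0.70),
        "Lepidoptera"       = c(0.20, 0.60, 0.05, 0.15))
    colnames(m) <- .MORPH_GROUPS
    m
}

# Expected share of captured individuals per pollinator group: Empididae
# and Syrphidae dominate (24% and 20% of captures), bumblebees 26%.
defaultGroupShare <- function() {
    c("Apis mellifera" = 0.03, "bumblebees" = 0.26, "wild bees" = 0.08,
      "other Hymenoptera" = 0.03, "Syrphidae" = 0.20, "Empididae" = 0.24,
      "other Diptera" = 0.08, "Coleoptera" = 0.05, "Lepidoptera" = 0.03)
}

#' Create a CommunitySpec
#'
#' Defaults describe a study-scale scenario: 402 captured insect
#' individuals, a lognormal plant rank-abundance curve (few common, many
#' rare taxa), one third of plant taxa growing off-site (invisible to the
#' visit survey but reachable by foraging insects), a small fraction of
#' taxa only resolvable above genus level, and a mean latent foraging
#' history of four visits per insect, which drives the roughly fourfold
#' link inflation of metabarcoding networks over single-capture visit
#' records.
#'
#' @param nPlantSpecies number of insect-pollinated plant taxa.
#' @param nInsectSpecies number of insect species.
#' @param nInsectIndividuals number of captured individuals.
#' @param plantAbundanceShape sdlog of the lognormal abundance law.
#' @param groupPreference insect-group x morph propensity matrix.
#' @param groupShare expected capture share per insect group.
#' @param offSiteFraction fraction of plant taxa off-site.
#' @param higherRankFraction fraction of taxa resolved above genus.
#' @param genusRankFraction fraction of taxa resolved at genus rank.
#' @param meanVisits mean zero-truncated-Poisson visit-history length.
#' @param seed integer seed for the scenario.
#' @return a \linkS4class{CommunitySpec}.
#' @examples
#' sp <- communitySpec(seed = 7)
#' @export
communitySpec <- function(nPlantSpecies = 60L, nInsectSpecies = 80L,
                          nInsectIndividuals = 402L,
                          plantAbundanceShape = 1.5,
                          groupPreference = defaultGroupPreference(),
                          groupShare = defaultGroupShare(),
                          offSiteFraction = 1 / 3,
                          higherRankFraction = 0.05,
                          genusRankFraction = 0.15,
                          meanVisits = 4, seed = 1L) {
    new("CommunitySpec",
        nPlantSpecies = as.integer(nPlantSpecies),
        nInsectSpecies = as.integer(nInsectSpecies),
        nInsectIndividuals = as.integer(nInsectIndividuals),
        plantAbundanceShape = plantAbundanceShape,
        groupPreference = groupPreference[.INSECT_GROUPS, .MORPH_GROUPS],
        groupShare = groupShare[.INSECT_GROUPS],
        offSiteFraction = offSiteFraction,
        higherRankFraction = higherRankFraction,
        genusRankFraction = genusRankFraction,
        meanVisits = meanVisits, seed = as.integer(seed))
}

#' Create a ContaminationSpec
#'
#' Defaults reproduce the stated airborne-grass contamination profile:
#' 35% of insects carry no grass reads at all, 60% fewer than 100, and
#' 11.5% more than 1,000. For contaminated insects the total grass read
#' count is lognormal with meanlog 5.159 and sdlog 1.887, the parameters
#' solving P(total < 100) = 0.385 and P(total > 1000) = 0.177
#' conditional on contamination, which combined with the 35% zero class
#' yield the three marginal fractions above.
#'
#' @param nGrassTaxa number of wind-pollinated grass taxa.
#' @param pZeroGrass probability of a grass-free insect.
#' @param grassMeanlog,grassSdlog lognormal parameters of the total grass
#'   read count of contaminated insects.
#' @param carryoverRate probability a true visit leaves only a
#'   sub-threshold read count.
#' @return a \linkS4class{ContaminationSpec}.
#' @export
contaminationSpec <- function(nGrassTaxa = 5L, pZeroGrass = 0.35,
                              grassMeanlog = 5.159, grassSdlog = 1.887,
                              carryoverRate = 0.1) {
    new("ContaminationSpec", nGrassTaxa = as.integer(nGrassTaxa),
        pZeroGrass = pZeroGrass, grassMeanlog = grassMeanlog,
        grassSdlog = grassSdlog, carryoverRate = carryoverRate)
}

# Zero-truncated Poisson sampler by inversion of the conditional CDF.
rztpois <- function(n, lambda) {
    if (lambda < 1e-8) return(rep(1L, n))
    u <- stats::runif(n, stats::dpois(0, lambda), 1)
    pmax(1L, stats::qpois(u, lambda))
}

# Rate of a zero-truncated Poisson with the requested mean m >= 1.
ztpoisRate <- function(m) {
    if (m <= 1 + 1e-9) return(0)
    stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                   c(1e-8, 1000), tol = 1e-10)$root
}

#' Generate the ground-truth interaction structure of a synthetic community
#'
#' Draws plant taxa (lognormal abundances, floral morph groups, on/off-site
#' and taxonomic-rank flags), insect species with their pollinator groups,
#' assigns every captured individual a species, and derives each
#' individual's plant-preference vector as its group's morph propensities
#' modulated by plant abundance. Taxa only resolvable above genus level are
#' placed off-site: they surface in pollen loads but never in the visit
#' survey, and are discarded during interaction calling.
#'
#' Deterministic under the spec's seed.
#'
#' @param spec a \linkS4class{CommunitySpec}.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' tr <- generateTruth(communitySpec(seed = 3))
#' @export
generateTruth <- function(spec) {
    stopifnot(is(spec, "CommunitySpec"))
    validObject(spec)
    withSeed(spec@seed, {
        nP <- spec@nPlantSpecies
        taxa <- sprintf("Plant_%03d", seq_len(nP))
        morph <- sample(.MORPH_GROUPS, nP, replace = TRUE,
                        prob = c(0.20, 0.15, 0.15, 0.50))
        abundance <- stats::rlnorm(nP, 0, spec@plantAbundanceShape)
        abundance <- abundance / sum(abundance)

        nOff <- round(nP * spec@offSiteFraction)
        off <- sample(nP, nOff)
        on_site <- !(seq_len(nP) %in% off)
        # higher-than-genus taxa cannot be visit-recorded: drawn from the
        # off-site pool so they only ever appear in pollen loads
        rank <- rep("species", nP)
        nHigher <- min(round(nP * spec@higherRankFraction), nOff)
        if (nHigher > 0)
            rank[sample(off, nHigher)] <- "family"
        nGenus <- round(nP * spec@genusRankFraction)
        genus_pool <- which(rank == "species")
        if (nGenus > 0)
            rank[sample(genus_pool, min(nGenus, length(genus_pool)))] <-
                "genus"
        plants <- data.frame(taxon = taxa, rank = rank,
                             morph_group = morph, on_site = on_site,
                             abundance = abundance,
                             stringsAsFactors = FALSE)

        nS <- spec@nInsectSpecies
        sp_names <- sprintf("Insect_%02d", seq_len(nS))
        sp_group <- sample(.INSECT_GROUPS, nS, replace = TRUE,
                           prob = spec@groupShare)
        sp_abund <- stats::rlnorm(nS, 0, 1.2)
        sp_abund <- sp_abund / sum(sp_abund)
        nI <- spec@nInsectIndividuals
        ind_sp <- sample(nS, nI, replace = TRUE, prob = sp_abund)
        insects <- data.frame(
            individual = sprintf("ind_%04d", seq_len(nI)),
            species = sp_names[ind_sp], group = sp_group[ind_sp],
            stringsAsFactors = FALSE)

        # group-level preference over plants: the morph propensity sets
        # the realized share per morph group, abundance distributes it
        # among that morph's taxa (absent morphs renormalize away)
        morphTot <- tapply(abundance, morph, sum)
        groupPref <- sapply(.INSECT_GROUPS, function(g) {
            w <- spec@groupPreference[g, morph] * abundance /
                as.numeric(morphTot[morph])
            if (sum(w) == 0) w <- abundance
            w / sum(w)
        })
        propensity <- groupPref[, insects$group, drop = FALSE]
        dimnames(propensity) <- list(taxa, insects$individual)

        new("GroundTruth", plants = plants, insects = insects,
            propensity = propensity, spec = spec)
    })
}

#' Simulate the visit survey
#'
#' One recorded visit per captured individual (capture-on-flower design):
#' the plant is drawn from the individual's preference vector restricted to
#' on-site taxa, since surveyors only observe visits on the study site.
#' Individuals are spread over four merged communities.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param seed optional seed; defaults to the scenario seed + 1.
#' @return a data.frame (the visit table) with columns individual,
#'   species, group, plant, community.
#' @examples
#' tr <- generateTruth(communitySpec(seed = 3))
#' head(simulateVisits(tr))
#' @export
simulateVisits <- function(truth, seed = NULL) {
    stopifnot(is(truth, "GroundTruth"))
    seed <- seed %||% (truth@spec@seed + 1L)
    withSeed(seed, {
        onsite <- truth@plants$on_site
        pr <- truth@propensity[onsite, , drop = FALSE]
        taxa <- truth@plants$taxon[onsite]
        nI <- nrow(truth@insects)
        plant <- vapply(seq_len(nI), function(j) {
            w <- pr[, j]
            taxa[sample.int(length(taxa), 1L, prob = w)]
        }, character(1))
        data.frame(individual = truth@insects$individual,
                   species = truth@insects$species,
                   group = truth@insects$group,
                   plant = plant,
                   community = sample(paste0("C", 1:4), nI, replace = TRUE),
                   stringsAsFactors = FALSE)
    })
}

#' Simulate pollen loads as a sequence-count table
#'
#' Pollen accumulates on insect bodies across a latent foraging history: a
#' zero-truncated-Poisson number of visits ending in the recorded capture
#' visit, with earlier visits drawn from the individual's full preference
#' vector (on- and off-site taxa alike). Each visited plant leaves a
#' super-threshold read count with probability 1 - carryoverRate (lognormal
#' shifted above the threshold) and a sub-threshold geometric count
#' otherwise. Wind-pollinated grass taxa add background contamination reads
#' following the \linkS4class{ContaminationSpec}.
#'
#' With contamination disabled, \code{carryoverRate = 0} and
#' \code{meanVisits = 1}, the thresholded table reduces exactly to the
#' visit matrix (full-reduction property).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param contamination a \linkS4class{ContaminationSpec}.
#' @param visits visit table from \code{\link{simulateVisits}}; generated
#'   on the fly if missing.
#' @param threshold the read threshold the scenario is built around.
#' @param seed optional seed; defaults to the scenario seed + 2.
#' @return integer matrix, insect individuals in rows, plant taxa
#'   (insect-pollinated and grass) in columns.
#' @examples
#' tr <- generateTruth(communitySpec(seed = 3))
#' v <- simulateVisits(tr)
#' sq <- simulatePollenLoads(tr, contaminationSpec(), v)
#' @export
simulatePollenLoads <- function(truth, contamination = contaminationSpec(),
                                visits = NULL, threshold = 1000,
                                seed = NULL) {
    stopifnot(is(truth, "GroundTruth"), is(contamination, "ContaminationSpec"))
    validObject(contamination)
    if (is.null(visits)) visits <- simulateVisits(truth)
    seed <- seed %||% (truth@spec@seed + 2L)
    withSeed(seed, {
        taxa <- truth@plants$taxon
        nI <- nrow(truth@insects)
        nG <- contamination@nGrassTaxa
        grass <- if (nG > 0) sprintf("Grass_%d", seq_len(nG)) else character()
        counts <- matrix(0L, nI, length(taxa) + nG,
                         dimnames = list(truth@insects$individual,
                                         c(taxa, grass)))
        lambda <- ztpoisRate(truth@spec@meanVisits)
        nVisits <- rztpois(nI, lambda)
        capture <- match(visits$plant[match(rownames(counts),
                                            visits$individual)], taxa)
        for (j in seq_len(nI)) {
            extra <- if (nVisits[j] > 1)
                sample.int(length(taxa), nVisits[j] - 1L, replace = TRUE,
                           prob = truth@propensity[, j])
            else integer()
            visited <- unique(c(capture[j], extra))
            lost <- stats::runif(length(visited)) < contamination@carryoverRate
            n_hi <- sum(!lost)
            if (n_hi > 0)
                counts[j, visited[!lost]] <- threshold + 1L +
                    as.integer(round(stats::rlnorm(n_hi, log(3000), 1.2)))
            n_lo <- sum(lost)
            if (n_lo > 0)
                counts[j, visited[lost]] <-
                    pmin(as.integer(threshold),
                         1L + stats::rgeom(n_lo, 1 / 50))
        }
        if (nG > 0) {
            # skewed grass community: one dominant taxon carries most reads
            gw <- stats::rlnorm(nG, 0, 2)
            contaminated <- stats::runif(nI) >= contamination@pZeroGrass
            totals <- integer(nI)
            totals[contaminated] <- pmax(1L, as.integer(round(
                stats::rlnorm(sum(contaminated), contamination@grassMeanlog,
                              contamination@grassSdlog))))
            for (j in which(contaminated))
                counts[j, length(taxa) + seq_len(nG)] <-
                    as.integer(stats::rmultinom(1, totals[j], gw))
        }
        storage.mode(counts) <- "integer"
        counts
    })
}

#' Build the taxon registry of a synthetic scenario
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param contamination the \linkS4class{ContaminationSpec} used for the
#'   pollen loads (its grass taxa are registered as wind-pollinated).
#' @return a \linkS4class{TaxonRegistry}.
#' @export
scenarioRegistry <- function(truth, contamination = contaminationSpec()) {
    p <- truth@plants
    plants <- data.frame(taxon = p$taxon, rank = p$rank,
                         pollination_mode = "insect",
                         morph_group = p$morph_group, on_site = p$on_site,
                         stringsAsFactors = FALSE)
    nG <- contamination@nGrassTaxa
    if (nG > 0)
        plants <- rbind(plants, data.frame(
            taxon = sprintf("Grass_%d", seq_len(nG)), rank = "species",
            pollination_mode = "wind", morph_group = "actinomorphic",
            on_site = TRUE, stringsAsFactors = FALSE))
    TaxonRegistry(plants = plants, insects = truth@insects)
}

#' Simulate a complete paired scenario
#'
#' Convenience wrapper chaining \code{\link{generateTruth}},
#' \code{\link{simulateVisits}}, \code{\link{simulatePollenLoads}} and
#' \code{\link{scenarioRegistry}}.
#'
#' @param spec a \linkS4class{CommunitySpec}.
#' @param contamination a \linkS4class{ContaminationSpec}.
#' @param threshold scenario read threshold.
#' @return list with elements \code{truth}, \code{visits}, \code{seqTable},
#'   \code{registry}.
#' @examples
#' sc <- simulateScenario(communitySpec(seed = 11))
#' sc$registry
#' @export
simulateScenario <- function(spec = communitySpec(),
                             contamination = contaminationSpec(),
                             threshold = 1000) {
    truth <- generateTruth(spec)
    visits <- simulateVisits(truth)
    seqTable <- simulatePollenLoads(truth, contamination, visits, threshold)
    list(truth = truth, visits = visits, seqTable = seqTable,
         registry = scenarioRegistry(truth, contamination))
}

#' Write / read a scenario as tab-separated files
#'
#' Three TSVs: \code{visits.tsv} (one row per recorded visit, carrying the
#' insect individual, species and group), \code{sequence_counts.tsv}
#' (individual x taxon read counts) and \code{taxa.tsv} (the plant
#' registry: taxon, rank, pollination_mode, morph_group, on_site).
#'
#' @param scenario list as returned by \code{\link{simulateScenario}}.
#' @param dir output directory, created if needed.
#' @return \code{writeScenario}: the directory, invisibly;
#'   \code{readScenario}: a scenario list (without \code{truth}).
#' @export
writeScenario <- function(scenario, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(scenario$visits, file.path(dir, "visits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts <- data.frame(individual = rownames(scenario$seqTable),
                         scenario$seqTable, check.names = FALSE,
                         stringsAsFactors = FALSE)
    utils::write.table(counts, file.path(dir, "sequence_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(plantInfo(scenario$registry),
                       file.path(dir, "taxa.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeScenario
#' @export
readScenario <- function(dir) {
    visits <- utils::read.table(file.path(dir, "visits.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
    counts <- utils::read.table(file.path(dir, "sequence_counts.tsv"),
                                sep = "\t", header = TRUE,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
    seqTable <- as.matrix(counts[, -1, drop = FALSE])
    rownames(seqTable) <- counts$individual
    storage.mode(seqTable) <- "integer"
    plants <- utils::read.table(file.path(dir, "taxa.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
    insects <- unique(visits[, c("individual", "species", "group")])
    list(visits = visits, seqTable = seqTable,
         registry = TaxonRegistry(plants = plants, insects = insects))
}
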