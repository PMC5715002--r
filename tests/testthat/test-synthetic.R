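# Synthetic-data generator: determinism, structural invariants,
# distributional oracles, and the end-to-end reduction property.

test_that("fixed seed gives bit-identical scenarios", {
    a <- simulateScenario(communitySpec(seed = 42L))
    b <- simulateScenario(communitySpec(seed = 42L))
    expect_identical(a$visits, b$visits)
    expect_identical(a$seqTable, b$seqTable)
    expect_identical(plantInfo(a$registry), plantInfo(b$registry))
    c <- simulateScenario(communitySpec(seed = 43L))
    expect_false(identical(a$seqTable, c$seqTable))
})

test_that("visit table has one capture row per individual and valid taxa", {
    sc <- simulateScenario(communitySpec(seed = 7L))
    expect_equal(nrow(sc$visits), 402L)
    expect_equal(anyDuplicated(sc$visits$individual), 0L)
    expect_true(all(sc$visits$plant %in% plantInfo(sc$registry)$taxon))
    expect_true(all(colnames(sc$seqTable) %in%
                    plantInfo(sc$registry)$taxon))
    expect_true(all(sc$seqTable >= 0))
    expect_type(sc$seqTable[1, 1], "integer")
    # visits only land on on-site taxa resolvable by the survey
    pl <- plantInfo(sc$registry)
    visited <- pl[match(sc$visits$plant, pl$taxon), ]
    expect_true(all(visited$on_site))
    expect_true(all(visited$pollination_mode == "insect"))
})

test_that("degenerate community specs are rejected", {
    expect_error(communitySpec(nPlantSpecies = 0), "counts")
    expect_error(communitySpec(offSiteFraction = 1.5), "offSiteFraction")
    gp <- defaultGroupPreference()
    gp[1, ] <- c(2, 0, 0, 0)
    expect_error(communitySpec(groupPreference = gp), "sum to 1")
})

test_that("uniform preferences on an even community give flat propensities", {
    gp <- defaultGroupPreference()
    gp[] <- 0.25
    tr <- generateTruth(communitySpec(nPlantSpecies = 20,
                                      plantAbundanceShape = 1e-6,
                                      groupPreference = gp,
                                      offSiteFraction = 0,
                                      higherRankFraction = 0,
                                      genusRankFraction = 0, seed = 2))
    pr <- tr@propensity[, 1]
    morph <- tr@plants$morph_group
    # per-morph share is 0.25 split evenly among that morph's taxa
    expect_equal(max(pr / (0.25 / table(morph)[morph])), 1, tolerance = 1e-3)
    expect_equal(colSums(tr@propensity), rep(1, ncol(tr@propensity)),
                 ignore_attr = TRUE)
})

test_that("bee zygomorphic propensity 0.86 is realized in visit shares", {
    # binomial oracle: share of a large sample within 2 SE of 0.86
    n <- 20000L
    share <- defaultGroupShare()
    share[] <- 0; share["bumblebees"] <- 1
    tr <- generateTruth(communitySpec(nInsectIndividuals = n,
                                      groupShare = share,
                                      offSiteFraction = 0,
                                      higherRankFraction = 0, seed = 3))
    v <- simulateVisits(tr)
    morph <- tr@plants$morph_group[match(v$plant, tr@plants$taxon)]
    p <- 0.86
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(morph == "zygomorphic") - p), 2 * se)
})

test_that("capture visits follow the individual preference vector", {
    # preference (0.9, 0.1) over two plants, n = 10,000: binomial oracle
    n <- 10000L
    plants <- data.frame(taxon = c("X", "Y"), rank = "species",
                         morph_group = "actinomorphic", on_site = TRUE,
                         abundance = c(0.9, 0.1), stringsAsFactors = FALSE)
    insects <- data.frame(individual = sprintf("i%05d", 1:n),
                          species = "S1", group = "Empididae",
                          stringsAsFactors = FALSE)
    pr <- matrix(c(0.9, 0.1), 2, n,
                 dimnames = list(plants$taxon, insects$individual))
    tr <- new("GroundTruth", plants = plants, insects = insects,
              propensity = pr, spec = communitySpec(seed = 1))
    v <- simulateVisits(tr, seed = 9)
    se <- sqrt(0.9 * 0.1 / n)
    expect_lt(abs(mean(v$plant == "X") - 0.9), 3 * se)
})

test_that("grass contamination profile converges to its parameters", {
    n <- 10000L
    tr <- generateTruth(communitySpec(nPlantSpecies = 20,
                                      nInsectIndividuals = n, seed = 4))
    cont <- contaminationSpec()
    sq <- simulatePollenLoads(tr, cont)
    reg <- scenarioRegistry(tr, cont)
    prof <- contaminationProfile(sq, reg, 1000)
    se <- function(p) sqrt(p * (1 - p) / n)
    expect_lt(abs(prof$fractionZero - 0.35), 3 * se(0.35))
    expect_lt(abs(prof$fractionBelow100 - 0.60), 3 * se(0.60))
    expect_lt(abs(prof$fractionAboveThreshold - 0.115), 3 * se(0.115))
})

test_that("mean latent history of 4 visits inflates links about fourfold", {
    # oracle: with near-uniform preferences over nP plants the expected
    # number of distinct plants in a zero-truncated-Poisson(mean 4)
    # history is computable by simulation from the known truth
    nP <- 60L; n <- 2000L
    gp <- defaultGroupPreference(); gp[] <- 0.25
    tr <- generateTruth(communitySpec(nPlantSpecies = nP,
                                      nInsectIndividuals = n,
                                      plantAbundanceShape = 1e-6,
                                      groupPreference = gp,
                                      offSiteFraction = 0,
                                      higherRankFraction = 0,
                                      genusRankFraction = 0,
                                      meanVisits = 4, seed = 5))
    cont <- contaminationSpec(nGrassTaxa = 0, carryoverRate = 0)
    visits <- simulateVisits(tr)
    sq <- simulatePollenLoads(tr, cont, visits)
    linkPerInsect <- mean(rowSums(sq > 1000))
    set.seed(99)   # independent oracle: occupancy of uniform draws
    lam <- uniroot(function(l) l / (1 - exp(-l)) - 4, c(0.1, 20))$root
    k <- qpois(runif(5e4, dpois(0, lam), 1), lam)
    oracle <- mean(vapply(k, function(m)
        length(unique(sample.int(nP, m, replace = TRUE))), numeric(1)))
    expect_lt(abs(linkPerInsect - oracle), 0.15)
    expect_gt(linkPerInsect, 3.4)   # the qualitative x4 inflation
})

test_that("degenerate settings reduce the seq pipeline to the obs pipeline", {
    # no contamination, single-visit histories, no carryover: the
    # thresholded count table must reproduce the visit matrix exactly
    sc <- simulateScenario(
        communitySpec(meanVisits = 1, offSiteFraction = 0,
                      higherRankFraction = 0, seed = 6),
        contaminationSpec(nGrassTaxa = 0, carryoverRate = 0))
    obs <- buildObsMatrix(sc$visits)
    seqm <- callInteractions(sc$seqTable, sc$registry)
    vo <- interactionValues(obs)
    vs <- interactionValues(seqm)
    expect_setequal(rownames(vs), rownames(vo))
    expect_setequal(colnames(vs), colnames(vo))
    expect_identical(vs[rownames(vo), colnames(vo)], vo)
    so <- indexValues(networkIndices(aggregateNetwork(obs, sc$registry,
                                                      "species")))
    ss <- indexValues(networkIndices(aggregateNetwork(seqm, sc$registry,
                                                      "species")))
    expect_equal(so, ss[names(so)], tolerance = 1e-12)
})

test_that("scenario TSV round-trip preserves the tables", {
    sc <- simulateScenario(communitySpec(nInsectIndividuals = 50, seed = 8))
    dir <- withr::local_tempdir()
    writeScenario(sc, dir)
    back <- readScenario(dir)
    expect_equal(back$visits, sc$visits)
    expect_equal(back$seqTable, sc$seqTable)
    expect_equal(plantInfo(back$registry), plantInfo(sc$registry))
})
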