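# Interaction calling, visit matrices, aggregation, per-species networks,
# contamination profile and threshold sensitivity.

seqFixture <- function() {
    counts <- rbind(
        i01 = c(Herb_A = 26952L, Herb_B = 0L, GenusOnly = 0L,
                FamilyOnly = 0L, Grass_X = 0L),
        i02 = c(1000L, 1001L, 0L, 0L, 0L),       # boundary pair
        i03 = c(0L, 5000L, 2000L, 9999L, 0L),    # higher-rank discarded
        i04 = c(0L, 0L, 0L, 0L, 26952L),         # grass only -> dropped
        i05 = c(5000L, 0L, 0L, 0L, 26952L),      # grass excluded, herb kept
        i06 = c(0L, 0L, 0L, 0L, 0L))             # all-zero -> dropped
    colnames(counts) <- c("Herb_A", "Herb_B", "GenusOnly", "FamilyOnly",
                          "Grass_X")
    counts
}

test_that("interaction calling applies the strict > threshold rule", {
    m <- callInteractions(seqFixture(), tinyRegistry(), 1000)
    v <- interactionValues(m)
    expect_false("i02" %in% colnames(v) && v["Herb_A", "i02"] == 1)
    expect_equal(unname(v["Herb_B", "i02"]), 1)      # 1001 > 1000
    expect_equal(unname(v["Herb_A", "i01"]), 1)
    expect_equal(thresholdUsed(m), 1000)
    expect_equal(networkLevel(m), "individual")
    expect_equal(provenance(m), "seq")
})

test_that("wind-pollinated and higher-rank taxa are removed before thresholding", {
    v <- interactionValues(callInteractions(seqFixture(), tinyRegistry()))
    expect_false("Grass_X" %in% rownames(v))
    expect_false("FamilyOnly" %in% rownames(v))
    expect_true("GenusOnly" %in% rownames(v))        # genus nodes kept
    # i05: grass 26,952 reads excluded, single link to the herb remains
    expect_equal(sum(v[, "i05"]), 1)
    expect_equal(unname(v["Herb_A", "i05"]), 1)
    # insects with no super-threshold insect-pollinated taxon are dropped
    expect_false("i04" %in% colnames(v))
    expect_false("i06" %in% colnames(v))
})

test_that("interaction calling rejects bad inputs by name", {
    counts <- seqFixture()
    counts[2, 1] <- -5L
    expect_error(callInteractions(counts, tinyRegistry()), "i02")
    counts <- seqFixture()
    colnames(counts)[3] <- "Mystery_taxon"
    expect_error(callInteractions(counts, tinyRegistry()), "Mystery_taxon")
})

test_that("a link is called when either marker exceeds the threshold", {
    trnL <- rbind(i01 = c(Herb_A = 1500L, Herb_B = 0L),
                  i02 = c(Herb_A = 400L, Herb_B = 800L))
    its1 <- rbind(i01 = c(Herb_A = 0L, Herb_B = 200L),
                  i02 = c(Herb_A = 0L, Herb_B = 900L))
    reg <- tinyRegistry()
    v <- interactionValues(callInteractions(list(trnL = trnL, its1 = its1),
                                            reg, 1000))
    expect_equal(unname(v["Herb_A", "i01"]), 1)
    # 800 + 900 > 1000 but counts are never summed across markers
    expect_false("i02" %in% colnames(v))
})

test_that("visit matrices are binary with one link per captured individual", {
    sc <- simulateScenario(communitySpec(seed = 21))
    m <- buildObsMatrix(sc$visits)
    v <- interactionValues(m)
    expect_equal(ncol(v), 402)
    expect_true(all(colSums(v) == 1))
    expect_true(all(v %in% c(0, 1)))
    expect_error(buildObsMatrix(sc$visits[0, ]), "empty")
})

test_that("aggregation conserves totals and counts individuals", {
    visits <- data.frame(
        individual = c("i01", "i02", "i03", "i04", "i05"),
        plant = c("Herb_A", "Herb_A", "Herb_A", "Herb_B", "Herb_A"),
        stringsAsFactors = FALSE)
    m <- buildObsMatrix(visits)
    reg <- tinyRegistry()
    sp <- aggregateNetwork(m, reg, "species")
    vs <- interactionValues(sp)
    expect_equal(sum(vs), sum(interactionValues(m)))
    expect_equal(unname(vs["Herb_A", "S1"]), 3)   # 3 individuals of S1
    expect_equal(unname(vs["Herb_B", "S2"]), 1)
    gp <- aggregateNetwork(m, reg, "group")
    vg <- interactionValues(gp)
    expect_equal(sum(vg), sum(interactionValues(m)))
    expect_equal(unname(vg["zygomorphic", "bumblebees"]), 3)
    expect_true(all(rownames(vg) %in% c("zygomorphic", "tubular",
                                        "ligulate", "actinomorphic")))
})

test_that("two individuals of one species visiting X and Y give links X:1 Y:1", {
    visits <- data.frame(individual = c("i01", "i02"),
                         plant = c("Herb_A", "Herb_B"),
                         stringsAsFactors = FALSE)
    vs <- interactionValues(aggregateNetwork(buildObsMatrix(visits),
                                             tinyRegistry(), "species"))
    expect_equal(unname(vs["Herb_A", "S1"]), 1)
    expect_equal(unname(vs["Herb_B", "S1"]), 1)
})

test_that("aggregation rejects unmapped individuals", {
    visits <- data.frame(individual = "ghost", plant = "Herb_A",
                         stringsAsFactors = FALSE)
    expect_error(aggregateNetwork(buildObsMatrix(visits), tinyRegistry(),
                                  "species"), "ghost")
})

test_that("per-species individual networks subset columns and drop zeros", {
    sc <- simulateScenario(communitySpec(seed = 22))
    m <- buildObsMatrix(sc$visits)
    nets <- perSpeciesNetworks(m, sc$registry, minIndividuals = 10)
    expect_gt(length(nets), 2)
    ins <- insectInfo(sc$registry)
    for (s in names(nets)) {
        v <- interactionValues(nets[[s]])
        expect_true(all(rowSums(v) > 0))
        expect_true(all(colSums(v) > 0))
        expect_true(all(ins$species[match(colnames(v), ins$individual)]
                        == s))
    }
    # the i-sp network is the column subset of that species' individuals
    s1 <- names(nets)[1]
    full <- interactionValues(m)
    sub <- full[, colnames(full) %in%
                ins$individual[ins$species == s1], drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    expect_identical(interactionValues(nets[[s1]]), sub)
    expect_length(perSpeciesNetworks(m, sc$registry,
                                     minIndividuals = 10000), 0)
})

test_that("contamination profile reports the documented fractions", {
    reg <- tinyRegistry()
    counts <- seqFixture()
    prof <- contaminationProfile(counts, reg, 1000)
    expect_equal(prof$fractionZero, 4 / 6)
    expect_equal(prof$fractionAboveThreshold, 2 / 6)
    expect_equal(prof$maxGrassReads, 26952)
    expect_equal(prof$fractionReadsRemoved, 0)   # all grass reads > 1000
    # single insect with 500 sub-threshold grass reads: all removed
    one <- matrix(c(2000L, 500L), 1, 2,
                  dimnames = list("i01", c("Herb_A", "Grass_X")))
    expect_equal(contaminationProfile(one, reg, 1000)$fractionReadsRemoved,
                 1)
    # no grass taxa at all
    nog <- matrix(2000L, 1, 1, dimnames = list("i01", "Herb_A"))
    p0 <- contaminationProfile(nog, reg, 1000)
    expect_equal(p0$fractionZero, 0)
    expect_true(is.na(p0$fractionReadsRemoved))
})

test_that("threshold sensitivity is monotone and matches a constructed fixture", {
    sc <- simulateScenario(communitySpec(seed = 23))
    tab <- thresholdSensitivity(sc$seqTable, sc$registry,
                                c(500, 1000, 2000))
    expect_equal(tab$threshold, c(500, 1000, 2000))
    expect_true(all(diff(tab$n_links) <= 0))
    # threshold 0: every nonzero count of a kept taxon becomes a link
    reg <- tinyRegistry()
    counts <- seqFixture()
    t0 <- thresholdSensitivity(counts, reg, 0)
    kept <- counts[, c("Herb_A", "Herb_B", "GenusOnly")]
    expect_equal(t0$n_links, sum(kept > 0))
    # fixture with exactly 20% of super-1000 counts in (1000, 2000]
    v <- matrix(0L, 10, 10,
                dimnames = list(sprintf("P%02d", 1:10),
                                sprintf("i%02d", 1:10)))
    diag(v) <- 5000L                     # 10 safely super-threshold links
    v[3, 4] <- 5000L; v[4, 5] <- 5000L   # 2 more
    v[1, 2] <- 1500L; v[2, 3] <- 1800L   # 3 of the 15 links fall in
    v[6, 7] <- 1200L                     # (1000, 2000]: 20% of the total
    reg2 <- TaxonRegistry(
        plants = data.frame(taxon = rownames(v), rank = "species",
                            pollination_mode = "insect",
                            morph_group = "actinomorphic", on_site = TRUE,
                            stringsAsFactors = FALSE),
        insects = data.frame(individual = colnames(v), species = "S",
                             group = "Empididae", stringsAsFactors = FALSE))
    tab2 <- thresholdSensitivity(t(v), reg2, c(1000, 2000))
    expect_equal(tab2$n_links, c(15L, 12L))      # 20% link reduction
})

test_that("taxon filtering commutes with thresholding", {
    withr::local_seed(31)
    reg <- tinyRegistry()
    for (rep in 1:10) {
        counts <- matrix(rpois(30, 900), 6, 5,
                         dimnames = list(sprintf("i%02d", 1:6),
                                         plantInfo(reg)$taxon))
        counts[sample(30, 5)] <- 0L
        counts[1, 1] <- 5000L            # guarantee a survivor
        storage.mode(counts) <- "integer"
        kept <- c("Herb_A", "Herb_B", "GenusOnly")
        pre <- callInteractions(counts[, kept], reg, 800)
        post <- callInteractions(counts, reg, 800)
        expect_identical(interactionValues(pre), interactionValues(post))
    }
})
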