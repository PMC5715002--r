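# Size/ratio indices, evenness, extreme specialization, degree fits and
# the frequency-connectivity regression.

test_that("basic indices reproduce the printed arithmetic of both networks", {
    # obs: 76 insect species, 26 plants, 153 links, 46/9 single-partner
    obs <- arithmeticFixture(A = 76, P = 26, I = 153,
                             singleInsects = 46, singlePlants = 9)
    b <- basicIndices(obs)
    expect_equal(round(b$connectance, 3), 0.077)
    expect_equal(round(b$interaction_density, 2), 1.5)
    expect_equal(round(b$mean_plant_linkage, 2), 5.88)
    expect_equal(round(b$mean_insect_linkage, 2), 2.01)
    expect_equal(round(extremeSpecialization(obs, "insect"), 2), 60.53)
    expect_equal(round(extremeSpecialization(obs, "plant"), 1), 34.6)
    # seq: 66 insect species, 68 plant taxa, 612 links, 7/8 single-partner
    seqm <- arithmeticFixture(A = 66, P = 68, I = 612,
                              singleInsects = 7, singlePlants = 8)
    s <- basicIndices(seqm)
    expect_equal(round(s$connectance, 3), 0.136)
    expect_equal(round(s$interaction_density, 2), 4.57)
    expect_equal(round(s$mean_plant_linkage, 2), 9.00)
    expect_equal(round(s$mean_insect_linkage, 2), 9.27)
    expect_equal(round(extremeSpecialization(seqm, "insect"), 1), 10.6)
    expect_equal(round(extremeSpecialization(seqm, "plant"), 1), 11.8)
})

test_that("connectance of a full matrix is 1 and empty input errors", {
    full <- nameMatrix(matrix(1, 3, 4))
    expect_equal(basicIndices(full)$connectance, 1)
    expect_error(basicIndices(matrix(0, 2, 2)), "empty")
})

test_that("evenness matches hand computations and its limits", {
    expect_equal(interactionEvenness(nameMatrix(matrix(1, 3, 3))), 1)
    one <- nameMatrix(matrix(c(5, 0, 0, 0), 2, 2))
    expect_equal(interactionEvenness(one), 0)
    # cells (2,1,1,0): H = 1.0397, Hmax = ln 4
    expect_equal(interactionEvenness(matrix(c(2, 1, 1, 0), 2, 2)), 0.75,
                 tolerance = 1e-4)
})

test_that("extreme specialization is 0 when every species has 2+ partners", {
    v <- nameMatrix(matrix(1, 4, 4))
    expect_equal(extremeSpecialization(v, "insect"), 0)
    expect_equal(extremeSpecialization(v, "plant"), 0)
})

test_that("transposing the matrix swaps the plant/insect roles", {
    withr::local_seed(17)
    for (i in 1:5) {
        v <- randomCountMatrix(6, 9)
        b <- basicIndices(v); bt <- basicIndices(t(v))
        expect_equal(b$mean_plant_linkage, bt$mean_insect_linkage)
        expect_equal(b$connectance, bt$connectance)
        expect_equal(interactionEvenness(v), interactionEvenness(t(v)))
        expect_equal(extremeSpecialization(v, "plant"),
                     extremeSpecialization(t(v), "insect"))
        expect_equal(h2Prime(v), h2Prime(t(v)), tolerance = 1e-10)
        expect_equal(nestednessTemperature(v)$temperature,
                     nestednessTemperature(t(v))$temperature,
                     tolerance = 1e-5)
    }
})

test_that("degree fits recover the generating law", {
    withr::local_seed(5)
    # geometric degrees decay exponentially in the cumulative tail
    deg <- rgeom(250, 0.25) + 1
    v <- matrix(0, max(deg), length(deg))
    for (j in seq_along(deg)) v[seq_len(deg[j]), j] <- 1
    fit <- degreeDistributionFit(nameMatrix(v), "insect")
    expect_true(fit$fitted)
    expect_lt(fit$fits$exponential$aic, fit$fits$power_law$aic)
    expect_true(fit$best %in% c("exponential", "truncated_power_law"))
    expect_true(all(diff(fit$cumulative) <= 0))
    # truncated power law degrees
    s <- 1:40
    w <- s^(-0.8) * exp(-s / 10)
    deg2 <- sample(s, 600, replace = TRUE, prob = w)
    v2 <- matrix(0, max(deg2), length(deg2))
    for (j in seq_along(deg2)) v2[seq_len(deg2[j]), j] <- 1
    fit2 <- degreeDistributionFit(nameMatrix(v2), "insect")
    expect_equal(fit2$best, "truncated_power_law")
    # too few distinct degrees
    flat <- nameMatrix(matrix(1, 2, 6))
    expect_false(degreeDistributionFit(flat, "insect")$fitted)
})

test_that("fs regression is the identity on strictly binary single visits", {
    # every species' frequency equals its link count: slope exactly 1
    v <- nameMatrix(matrix(0, 5, 12))
    v[1, 1:6] <- 1; v[2, 7:9] <- 1; v[3, 10:11] <- 1
    v[4, 12] <- 1; v[5, 12] <- 1
    fit <- suppressWarnings(fsRegression(v, "plant"))  # perfect fit
    expect_equal(fit$slope, 1, tolerance = 1e-12)
    expect_lt(fit$p_value, 1e-6)
})

test_that("fs regression recovers a planted exponent of 0.5", {
    withr::local_seed(8)
    f <- round(10^runif(40, 0.5, 3))
    s <- pmax(1, round(f^0.5 * 10^rnorm(40, 0, 0.05)))
    v <- matrix(0, 80, length(f))
    for (j in seq_along(f)) {
        links <- sample(80, s[j])
        v[links, j] <- 1
        # top up the first linked row so the column total equals f
        v[links[1], j] <- f[j] - s[j] + 1
    }
    fit <- fsRegression(nameMatrix(v), "insect")
    expect_equal(fit$slope, 0.5, tolerance = 3 * fit$se)
    # relabeling species leaves the slope unchanged
    perm <- sample(ncol(v))
    expect_equal(fsRegression(nameMatrix(v[, perm]), "insect")$slope,
                 fit$slope)
})

test_that("the full suite keeps every bounded index in range", {
    withr::local_seed(13)
    for (i in 1:15) {
        v <- randomCountMatrix(sample(3:8, 1), sample(3:8, 1))
        x <- indexValues(networkIndices(v, modularityRestarts = 3,
                                        seed = i))
        expect_true(x["connectance"] > 0 && x["connectance"] <= 1)
        expect_true(x["nestedness"] >= 0 && x["nestedness"] <= 1)
        expect_true(x["H2prime"] >= 0 && x["H2prime"] <= 1)
        expect_true(x["evenness"] >= 0 && x["evenness"] <= 1)
        expect_true(all(x[c("mean_plant_dprime", "mean_insect_dprime")]
                        >= 0))
        expect_true(all(x[c("mean_plant_dprime", "mean_insect_dprime")]
                        <= 1))
        expect_true(x["extreme_plant_spec"] >= 0 &&
                    x["extreme_plant_spec"] <= 100)
        expect_equal(unname(x["I"]), sum(v > 0))
    }
})
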