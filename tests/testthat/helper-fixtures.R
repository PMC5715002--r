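# Fixture builders and independent oracles used across the test files.
# Everything here is generated in code; no stored data.

# name a plain matrix so it satisfies InteractionMatrix invariants
nameMatrix <- function(v) {
    dimnames(v) <- list(sprintf("p%02d", seq_len(nrow(v))),
                        sprintf("a%02d", seq_len(ncol(v))))
    v
}

# random count matrix without empty rows/columns (seeded by caller)
randomCountMatrix <- function(P, A, total = ceiling(4 * P * A / 3)) {
    repeat {
        v <- matrix(stats::rmultinom(1, total, rep(1, P * A) *
                                     stats::rgamma(P * A, 0.5)), P, A)
        if (all(rowSums(v) > 0) && all(colSums(v) > 0))
            return(nameMatrix(v))
    }
}

# --- oracle: Shannon entropy of a count matrix's cell frequencies -------
oracleEntropy <- function(a) {
    p <- a[a > 0] / sum(a)
    -sum(p * log(p))
}

# --- oracle: enumerate all non-negative integer matrices with the given
# row and column totals (tiny cases only) --------------------------------
enumerateTables <- function(r, c) {
    out <- list()
    recurse <- function(rows_left, c_left, acc) {
        if (length(rows_left) == 0) {
            if (all(c_left == 0)) out[[length(out) + 1]] <<- acc
            return(invisible())
        }
        target <- rows_left[1]
        cells <- length(c_left)
        fillRow <- function(j, row_acc, left) {
            if (j > cells) {
                if (left == 0)
                    recurse(rows_left[-1], c_left - row_acc,
                            rbind(acc, row_acc))
                return(invisible())
            }
            for (x in 0:min(left, c_left[j])) {
                row_acc[j] <- x
                fillRow(j + 1, row_acc, left - x)
            }
        }
        fillRow(1, numeric(cells), target)
    }
    recurse(r, c, NULL)
    out
}

# --- oracle: enumerate binary matrices with the given margins -----------
enumerateBinary <- function(r, c) {
    A <- length(c)
    patterns <- function(k) {
        combs <- utils::combn(A, k)
        lapply(seq_len(ncol(combs)), function(i) {
            z <- numeric(A); z[combs[, i]] <- 1; z
        })
    }
    rowsets <- lapply(r, patterns)
    out <- list()
    recurse <- function(i, acc) {
        if (i > length(r)) {
            if (all(colSums(acc) == c)) out[[length(out) + 1]] <<- acc
            return(invisible())
        }
        for (p in rowsets[[i]]) recurse(i + 1, rbind(acc, p))
    }
    recurse(1, NULL)
    out
}

# --- oracle: Barber modularity from a partition -------------------------
oracleBarberQ <- function(v, gp, ga) {
    F <- sum(v)
    B <- v - outer(rowSums(v), colSums(v)) / F
    q <- 0
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        if (gp[i] == ga[j]) q <- q + B[i, j]
    q / F
}

# --- deterministic binary fixture with prescribed marginal structure ----
# P plants x A insects, exactly I links, exactly singleInsects insects and
# singlePlants plants with one partner, no empty rows/columns.
arithmeticFixture <- function(A, P, I, singleInsects, singlePlants) {
    v <- matrix(0L, P, A)
    multiIns <- (singleInsects + 1):A      # insects allowed >= 2 links
    multiPl <- (singlePlants + 1):P        # plants allowed >= 2 links
    h1 <- multiPl[1]; h2 <- multiPl[2]     # hub plants
    i1 <- multiIns[1]; i2 <- multiIns[2]   # hub insects
    v[h1, seq_len(singleInsects)] <- 1L    # single-partner insects -> hub
    v[seq_len(singlePlants), i1] <- 1L     # single-partner plants <- hub
    for (a in setdiff(multiIns, i1)) v[c(h1, h2), a] <- 1L
    for (p in setdiff(multiPl, c(h1, h2))) v[p, c(i1, i2)] <- 1L
    need <- I - sum(v)
    stopifnot(need >= 0)
    # pad with unused multi-multi cells, row-major for determinism
    free <- which(v[multiPl, multiIns, drop = FALSE] == 0, arr.ind = TRUE)
    stopifnot(nrow(free) >= need)
    if (need > 0)
        v[cbind(multiPl[free[seq_len(need), 1]],
                multiIns[free[seq_len(need), 2]])] <- 1L
    v <- nameMatrix(v)
    stopifnot(sum(v) == I,
              sum(colSums(v) == 1) == singleInsects,
              sum(rowSums(v) == 1) == singlePlants,
              all(rowSums(v) > 0), all(colSums(v) > 0))
    v
}

# small registry + count-table fixture for interaction-calling tests
tinyRegistry <- function() {
    TaxonRegistry(
        plants = data.frame(
            taxon = c("Herb_A", "Herb_B", "GenusOnly", "FamilyOnly",
                      "Grass_X"),
            rank = c("species", "species", "genus", "family", "species"),
            pollination_mode = c("insect", "insect", "insect", "insect",
                                 "wind"),
            morph_group = c("zygomorphic", "actinomorphic", "tubular",
                            "ligulate", "actinomorphic"),
            on_site = TRUE, stringsAsFactors = FALSE),
        insects = data.frame(
            individual = sprintf("i%02d", 1:6),
            species = c("S1", "S1", "S1", "S2", "S2", "S3"),
            group = c("bumblebees", "bumblebees", "bumblebees",
                      "Syrphidae", "Syrphidae", "Empididae"),
            stringsAsFactors = FALSE))
}
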