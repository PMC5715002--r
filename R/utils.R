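# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. All package randomness
# funnels through this so that a scenario seed determines every draw.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        has_seed <- exists(".Random.seed", envir = globalenv(),
                           inherits = FALSE)
        if (has_seed)
            old <- get(".Random.seed", envir = globalenv())
        set.seed(as.integer(seed))
        on.exit({
            if (has_seed)
                assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    expr
}

# Drop all-zero rows and columns from a plain matrix, iterating until
# stable (dropping a column can never zero a row for non-negative data,
# so one pass each suffices).
dropEmpty <- function(m) {
    if (nrow(m) == 0 || ncol(m) == 0) return(m)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    m <- m[, colSums(m) > 0, drop = FALSE]
    m
}

# Stable per-row argmax with lowest-index tie-break (determinism).
rowArgmax <- function(x) {
    max.col(x, ties.method = "first")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
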