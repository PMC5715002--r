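# Fixed-marginal (Patefield) null model and index confidence envelopes.

#' Draw a fixed-marginal random matrix (Patefield algorithm)
#'
#' Random integer table with exactly the row and column totals of the
#' input, so null matrices contain common and rare species like the
#' empirical one. Each of the F interaction tokens is placed by the
#' sequential conditional-uniform allocation of Patefield (1981), via
#' \code{stats::r2dtable}.
#'
#' @inheritParams basicIndices
#' @param seed optional seed (deterministic ensemble under a fixed seed).
#' @return an integer matrix with the same dimnames and marginals as
#'   \code{m}.
#' @examples
#' m <- matrix(c(2, 0, 0, 1), 2, 2)
#' colSums(patefieldSample(m, seed = 1)) == colSums(m)
#' @export
patefieldSample <- function(m, seed = NULL) {
    v <- .asMatrix(m)
    if (sum(v) <= 0) stop("zero-total matrix")
    if (nrow(v) == 1 || ncol(v) == 1) return(v)   # forced by marginals
    withSeed(seed, {
        out <- stats::r2dtable(1, rowSums(v), colSums(v))[[1]]
        dimnames(out) <- dimnames(v)
        out
    })
}

# apply the index suite to a plain matrix, dropping rows/columns emptied
# by resampling; returns NULL on failure (recorded by the caller)
.suiteValues <- function(v, modularityRestarts, seed, slopes) {
    v <- dropEmpty(v)
    if (nrow(v) == 0 || ncol(v) == 0) return(NULL)
    tryCatch(indexValues(networkIndices(v,
                                        modularityRestarts = modularityRestarts,
                                        seed = seed, slopes = slopes)),
             error = function(e) NULL)
}

#' Null-model confidence envelope for the index suite
#'
#' Computes every index on \code{nReplicates} Patefield resamples of the
#' observed matrix and derives 95% confidence intervals — empirical
#' 2.5/97.5 percentiles by default, or a normal approximation
#' (mean +/- 1.96 sd). An observed index is flagged significant when it
#' falls strictly outside its CI. Replicates on which an index fails are
#' excluded for that index with a warning.
#'
#' @inheritParams basicIndices
#' @param nReplicates number of null networks (default 100).
#' @param seed integer seed for the ensemble.
#' @param ciType \code{"percentile"} (default) or \code{"normal"}.
#' @param modularityRestarts restarts of the modularity search per
#'   replicate.
#' @param slopes include fs-regression slopes in the suite.
#' @param observedReport optional precomputed \linkS4class{IndexReport}
#'   of \code{m}, reused as the observed values (avoids re-running the
#'   stochastic modularity search under a different seed).
#' @return a \linkS4class{NullEnsemble}.
#' @examples
#' sc <- simulateScenario(communitySpec(seed = 5))
#' sp <- aggregateNetwork(buildObsMatrix(sc$visits), sc$registry, "species")
#' ne <- nullEnvelope(sp, nReplicates = 20, seed = 1)
#' nullSummary(ne)
#' @export
nullEnvelope <- function(m, nReplicates = 100L, seed = 1L,
                         ciType = c("percentile", "normal"),
                         modularityRestarts = 4L, slopes = FALSE,
                         observedReport = NULL) {
    ciType <- match.arg(ciType)
    stopifnot(nReplicates >= 2)
    v <- .asMatrix(m)
    observed <- if (!is.null(observedReport)) indexValues(observedReport)
                else .suiteValues(v, modularityRestarts = 10L, seed = seed,
                                  slopes = slopes)
    if (is.null(observed)) stop("index suite failed on the observed matrix")
    withSeed(seed, {
        reps <- matrix(NA_real_, nReplicates, length(observed),
                       dimnames = list(NULL, names(observed)))
        failed <- 0L
        degenerate <- nrow(v) == 1 || ncol(v) == 1
        for (r in seq_len(nReplicates)) {
            null_m <- if (degenerate) v
                      else stats::r2dtable(1, rowSums(v), colSums(v))[[1]]
            vals <- .suiteValues(null_m, modularityRestarts,
                                 seed = seed + r, slopes = slopes)
            if (is.null(vals)) failed <- failed + 1L
            else reps[r, names(vals)] <- vals
        }
        if (failed > 0)
            warning(failed, " null replicate(s) failed and were excluded")
        summ <- do.call(rbind, lapply(colnames(reps), function(ix) {
            x <- reps[, ix]
            x <- x[is.finite(x)]
            if (length(x) < 2)
                return(data.frame(index = ix, observed = observed[ix],
                                  null_mean = NA_real_, ci_lower = NA_real_,
                                  ci_upper = NA_real_, significant = NA))
            ci <- if (ciType == "percentile")
                unname(stats::quantile(x, c(0.025, 0.975), type = 7))
            else mean(x) + c(-1.96, 1.96) * stats::sd(x)
            data.frame(index = ix, observed = observed[ix],
                       null_mean = mean(x), ci_lower = ci[1],
                       ci_upper = ci[2],
                       significant = observed[ix] < ci[1] |
                           observed[ix] > ci[2])
        }))
        rownames(summ) <- NULL
        new("NullEnsemble", observed = observed, replicates = reps,
            summary = summ, nReplicates = as.integer(nReplicates),
            seed = as.integer(seed), ciType = ciType)
    })
}
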