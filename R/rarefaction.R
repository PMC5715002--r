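# Size- and effort-matched comparison of the metabarcoding network with
# the visit-survey network: shared-species restriction, multinomial
# downsampling of the seq matrix to the obs interaction total, empirical
# two-tailed p-values with Bonferroni correction.

#' Restrict two networks to their shared species
#'
#' Keeps only the plant and insect species present in both matrices so the
#' two networks are of the same size; rows or columns emptied by the
#' restriction in either matrix are dropped from both (symmetrically).
#'
#' @param mSeq,mObs species-level \linkS4class{InteractionMatrix} objects
#'   (or plain matrices) with overlapping labels.
#' @return list with elements \code{seq} and \code{obs}, matrices of
#'   identical dimension and dimnames.
#' @export
sharedRestriction <- function(mSeq, mObs) {
    vs <- .asMatrix(mSeq); vo <- .asMatrix(mObs)
    plants <- intersect(rownames(vs), rownames(vo))
    insects <- intersect(colnames(vs), colnames(vo))
    if (length(plants) == 0 || length(insects) == 0)
        stop("no shared species between the two networks")
    vs <- vs[plants, insects, drop = FALSE]
    vo <- vo[plants, insects, drop = FALSE]
    repeat {
        keep_p <- rowSums(vs) > 0 & rowSums(vo) > 0
        keep_a <- colSums(vs) > 0 & colSums(vo) > 0
        if (all(keep_p) && all(keep_a)) break
        vs <- vs[keep_p, keep_a, drop = FALSE]
        vo <- vo[keep_p, keep_a, drop = FALSE]
        if (nrow(vs) == 0 || ncol(vs) == 0)
            stop("shared restriction emptied the networks")
    }
    list(seq = vs, obs = vo)
}

#' One multinomial rarefaction draw
#'
#' Downsamples (or resamples) a count matrix to \code{targetTotal}
#' interactions: cell counts are one multinomial draw with probabilities
#' proportional to the observed frequencies a_ij / F, so the grand total
#' of every draw is exactly \code{targetTotal}.
#'
#' @inheritParams basicIndices
#' @param targetTotal interaction total of the rarefied matrix (the obs
#'   total when matching sampling intensity).
#' @param seed optional seed.
#' @return integer matrix with the same dimnames as \code{m}.
#' @export
rarefyOnce <- function(m, targetTotal, seed = NULL) {
    v <- .asMatrix(m)
    F <- sum(v)
    if (F <= 0) stop("zero-total source matrix")
    stopifnot(targetTotal >= 1)
    withSeed(seed, {
        draw <- stats::rmultinom(1, targetTotal, as.vector(v) / F)
        out <- matrix(as.integer(draw), nrow(v), ncol(v),
                      dimnames = dimnames(v))
        out
    })
}

#' Compare two networks by rarefaction
#'
#' Restricts both species-level networks to their shared species, draws
#' \code{nReplicates} multinomial rarefactions of the seq network at the
#' obs interaction total, computes the index suite (including, optionally,
#' the frequency-connectivity regression slopes) on every rarefied matrix
#' (after dropping rows/columns emptied by chance), and derives for each
#' index an empirical two-tailed p-value: the add-one estimator
#' (1 + #more extreme) / (nReplicates + 1) on the smaller tail, with
#' Bonferroni correction over the indices tested. The direction of the
#' difference is reported alongside. Indices whose obs and seq values
#' differ significantly are lettered \code{a}/\code{b}, others
#' \code{a}/\code{a}.
#'
#' @param mSeq,mObs species-level networks (seq and obs provenance).
#' @param nReplicates number of rarefied matrices (default 1000).
#' @param seed integer seed.
#' @param slopes include fs-regression slopes.
#' @param modularityRestarts restarts of the modularity search per
#'   replicate.
#' @param alpha significance level applied to the Bonferroni-adjusted p.
#' @return a \linkS4class{NetworkComparison}.
#' @examples
#' sc <- simulateScenario(communitySpec(seed = 5))
#' obs <- aggregateNetwork(buildObsMatrix(sc$visits), sc$registry, "species")
#' seqm <- aggregateNetwork(callInteractions(sc$seqTable, sc$registry),
#'                          sc$registry, "species")
#' cmp <- compareNetworks(seqm, obs, nReplicates = 50, seed = 1)
#' comparisonTable(cmp)
#' @export
compareNetworks <- function(mSeq, mObs, nReplicates = 1000L, seed = 1L,
                            slopes = TRUE, modularityRestarts = 3L,
                            alpha = 0.05) {
    stopifnot(nReplicates >= 1)
    shared <- sharedRestriction(mSeq, mObs)
    targetTotal <- sum(shared$obs)
    obsVals <- .suiteValues(shared$obs, modularityRestarts = 10L,
                            seed = seed, slopes = slopes)
    seqVals <- .suiteValues(shared$seq, modularityRestarts = 10L,
                            seed = seed, slopes = slopes)
    if (is.null(obsVals) || is.null(seqVals))
        stop("index suite failed on a restricted matrix")
    withSeed(seed, {
        pmat <- as.vector(shared$seq) / sum(shared$seq)
        reps <- matrix(NA_real_, nReplicates, length(obsVals),
                       dimnames = list(NULL, names(obsVals)))
        failed <- 0L
        for (r in seq_len(nReplicates)) {
            draw <- matrix(as.integer(stats::rmultinom(1, targetTotal, pmat)),
                           nrow(shared$seq), ncol(shared$seq),
                           dimnames = dimnames(shared$seq))
            vals <- .suiteValues(draw, modularityRestarts,
                                 seed = seed + r, slopes = slopes)
            if (is.null(vals)) failed <- failed + 1L
            else reps[r, names(vals)] <- vals
        }
        if (failed > 0)
            warning(failed, " rarefied replicate(s) failed and were excluded")
        mIdx <- length(obsVals)    # Bonferroni family: this table's rows
        rows <- lapply(names(obsVals), function(ix) {
            x <- reps[, ix]
            x <- x[is.finite(x)]
            obs <- obsVals[ix]
            if (length(x) < 1 || !is.finite(obs))
                return(data.frame(index = ix, obs = obs,
                                  seq = seqVals[ix],
                                  rarefied_mean = NA_real_,
                                  direction = NA_character_, p = NA_real_,
                                  p_adj = NA_real_, letters = NA_character_))
            n_above <- sum(x >= obs)
            n_below <- sum(x <= obs)
            # smaller one-sided proportion, add-one estimator
            p <- (1 + min(n_above, n_below)) / (length(x) + 1)
            p_adj <- min(1, mIdx * p)
            dir <- if (mean(x) >= obs) "seq_higher" else "seq_lower"
            data.frame(index = ix, obs = obs, seq = seqVals[ix],
                       rarefied_mean = mean(x), direction = dir, p = p,
                       p_adj = p_adj,
                       letters = if (p_adj < alpha) "a/b" else "a/a")
        })
        tab <- do.call(rbind, rows)
        rownames(tab) <- NULL
        new("NetworkComparison", table = tab, replicates = reps,
            nReplicates = as.integer(nReplicates), seed = as.integer(seed))
    })
}
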