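# Barber bipartite modularity
#   Q = (1/F) * sum_ij (a_ij - k_i d_j / F) delta(g_i, g_j)
# maximized by weighted label propagation (LPAb-style sweeps alternating
# between the two node sets) followed by agglomerative merging of module
# pairs whenever merging does not decrease Q, restarted from several
# seeded random initial partitions; the best partition is reported.

# Q of a partition, from the modularity matrix B = a - k d'/F
.barberQ <- function(B, F, gp, ga) {
    labs <- union(gp, ga)
    q <- 0
    for (l in labs) {
        ip <- gp == l; ja <- ga == l
        if (any(ip) && any(ja))
            q <- q + sum(B[ip, ja, drop = FALSE])
    }
    q / F
}

# one label-propagation + agglomeration pass from an initial plant labeling
.lpaRun <- function(B, F, gp0) {
    P <- nrow(B); A <- ncol(B)
    gp <- gp0
    ga <- rep(NA_integer_, A)
    repeat {
        moved <- FALSE
        for (sweep in 1:50) {
            labs <- sort(unique(gp))
            ind <- outer(gp, labs, "==") * 1            # P x L
            ga_new <- labs[rowArgmax(crossprod(B, ind))] # A side
            labs2 <- sort(unique(ga_new))
            ind2 <- outer(ga_new, labs2, "==") * 1
            gp_new <- labs2[rowArgmax(B %*% ind2)]       # P side
            if (identical(gp_new, gp) && identical(ga_new, ga)) break
            moved <- TRUE
            gp <- gp_new; ga <- ga_new
        }
        # agglomeration: merge the module pair with the largest
        # non-negative gain; repeat until no such pair remains
        merged <- FALSE
        repeat {
            labs <- sort(unique(c(gp, ga)))
            L <- length(labs)
            if (L < 2) break
            indP <- outer(gp, labs, "==") * 1
            indA <- outer(ga, labs, "==") * 1
            E <- crossprod(indP, B %*% indA)    # L x L module cross-sums
            gain <- E + t(E)
            diag(gain) <- -Inf
            best <- which(gain == max(gain), arr.ind = TRUE)[1, ]
            if (gain[best[1], best[2]] < -1e-12) break
            from <- labs[max(best)]; to <- labs[min(best)]
            gp[gp == from] <- to
            ga[ga == from] <- to
            merged <- TRUE
        }
        if (!merged || !moved) break
    }
    list(gp = gp, ga = ga, Q = .barberQ(B, F, gp, ga))
}

#' Barber bipartite modularity
#'
#' Maximizes Barber's bipartite modularity Q by label propagation with
#' agglomerative merging, restarted \code{nRestarts} times from seeded
#' random partitions (the first restart uses singleton plant modules).
#' Deterministic under \code{seed}. Module labels are renumbered
#' contiguously in the returned assignment.
#'
#' @inheritParams basicIndices
#' @param nRestarts number of random restarts.
#' @param seed integer seed.
#' @return list with \code{Q}, \code{nModules}, \code{plantModules},
#'   \code{insectModules} (named integer vectors).
#' @examples
#' blocks <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
#'                 cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
#' dimnames(blocks) <- list(paste0("p", 1:6), paste0("a", 1:6))
#' bipartiteModularity(blocks)$Q   # 0.5 for two equal blocks
#' @export
bipartiteModularity <- function(m, nRestarts = 10L, seed = 1L) {
    v <- .asMatrix(m)
    F <- sum(v)
    if (F == 0) stop("zero-total matrix")
    P <- nrow(v); A <- ncol(v)
    B <- v - outer(rowSums(v), colSums(v)) / F
    withSeed(seed, {
        best <- .lpaRun(B, F, seq_len(P))
        if (nRestarts > 1) {
            for (r in seq_len(nRestarts - 1L)) {
                k <- sample(2:max(2, min(P, A)), 1)
                cand <- .lpaRun(B, F, sample.int(k, P, replace = TRUE))
                if (cand$Q > best$Q + 1e-12) best <- cand
            }
        }
        labs <- sort(unique(c(best$gp, best$ga)))
        gp <- match(best$gp, labs)
        ga <- match(best$ga, labs)
        names(gp) <- rownames(v) %||% as.character(seq_len(P))
        names(ga) <- colnames(v) %||% as.character(seq_len(A))
        list(Q = best$Q, nModules = length(labs),
             plantModules = gp, insectModules = ga)
    })
}
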