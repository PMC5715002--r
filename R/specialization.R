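# Network-level (H2') and species-level (d') specialization, following
# the standardized two-dimensional Shannon-entropy approach: H2' rescales
# the observed interaction entropy between the marginal-constrained
# extremes; d' is the Kullback-Leibler divergence of a species'
# interaction profile from partner availability, standardized by its
# analytic maximum given the marginals.

.entropy <- function(a) {
    F <- sum(a)
    p <- a[a > 0] / F
    -sum(p * log(p))
}

# greedy integer fill with the given marginals; maximize = TRUE spreads
# counts toward independence (max entropy), FALSE concentrates them
# (min entropy)
.greedyFill <- function(r, c, maximize) {
    F <- sum(r)
    a <- matrix(0, length(r), length(c))
    if (maximize) {
        e <- outer(r, c) / F
        a <- floor(e)
        # floor(e) has rowSums <= r and colSums <= c; distribute the
        # leftover tokens over cells in decreasing fractional-remainder
        # order (largest-remainder rounding toward independence)
        rr <- r - rowSums(a); cc <- c - colSums(a)
        ord <- order(e - a, decreasing = TRUE)
        ij <- arrayInd(ord, dim(a))
        while (sum(rr) > 0) {
            placed <- FALSE
            for (k in seq_len(nrow(ij))) {
                i <- ij[k, 1]; j <- ij[k, 2]
                if (rr[i] > 0 && cc[j] > 0) {
                    a[i, j] <- a[i, j] + 1
                    rr[i] <- rr[i] - 1
                    cc[j] <- cc[j] - 1
                    placed <- TRUE
                }
            }
            if (!placed) break   # cannot happen: sum(rr) == sum(cc)
        }
    } else {
        rr <- r; cc <- c
        while (sum(rr) > 0) {
            i <- which.max(rr); j <- which.max(cc)
            t <- min(rr[i], cc[j])
            a[i, j] <- a[i, j] + t
            rr[i] <- rr[i] - t
            cc[j] <- cc[j] - t
        }
    }
    a
}

# exhaustive 2x2-swap local search; moves one interaction token at a time
# while the entropy improves in the requested direction. The entropy
# change of a move touches only four cells, so it is computed
# incrementally from the -x log x cell terms.
.swapOptimize <- function(a, maximize, maxMoves = 2000L) {
    P <- nrow(a); A <- ncol(a)
    sgn <- if (maximize) 1 else -1
    xlx <- function(x) if (x > 0) x * log(x) else 0
    for (mv in seq_len(maxMoves)) {
        bestDelta <- 1e-12
        best <- NULL
        for (i in seq_len(P)) for (k in seq_len(P)) {
            if (i == k) next
            for (j in seq_len(A)) for (l in seq_len(A)) {
                if (j == l) next
                o3 <- a[i, l]; o4 <- a[k, j]
                if (o3 > 0 && o4 > 0) {
                    o1 <- a[i, j]; o2 <- a[k, l]
                    # unnormalized -sum x log x delta (F is constant)
                    delta <- sgn * (xlx(o1) + xlx(o2) + xlx(o3) + xlx(o4) -
                                    xlx(o1 + 1) - xlx(o2 + 1) -
                                    xlx(o3 - 1) - xlx(o4 - 1))
                    if (delta > bestDelta) {
                        bestDelta <- delta
                        best <- list(i = i, j = j, k = k, l = l)
                    }
                }
            }
        }
        if (is.null(best)) break
        a[best$i, best$j] <- a[best$i, best$j] + 1
        a[best$k, best$l] <- a[best$k, best$l] + 1
        a[best$i, best$l] <- a[best$i, best$l] - 1
        a[best$k, best$j] <- a[best$k, best$j] - 1
    }
    a
}

#' Network-level specialization H2'
#'
#' Two-dimensional Shannon entropy of the interaction frequencies,
#' standardized between the maximum and minimum entropies attainable by
#' integer matrices with the observed row and column totals:
#' H2' = (H2max - H2) / (H2max - H2min), 0 for a network indistinguishable
#' from the independence expectation, 1 for perfect specialization.
#' Extremal entropies come from greedy marginal filling, refined by an
#' exhaustive 2x2-swap local search on small matrices
#' (\code{<= swapCells} cells).
#'
#' @inheritParams basicIndices
#' @param swapCells cell-count limit below which the swap refinement runs.
#' @return H2' in [0, 1].
#' @examples
#' h2Prime(diag(3) * 2)   # 1: perfectly specialized
#' @export
h2Prime <- function(m, swapCells = 120L) {
    v <- .asMatrix(m)
    F <- sum(v)
    if (F <= 0) stop("zero-total matrix")
    r <- rowSums(v); c <- colSums(v)
    H2 <- .entropy(v)
    small <- length(v) <= swapCells
    amax <- .greedyFill(r, c, maximize = TRUE)
    amin <- .greedyFill(r, c, maximize = FALSE)
    if (small) {
        amax <- .swapOptimize(amax, maximize = TRUE)
        amin <- .swapOptimize(amin, maximize = FALSE)
    }
    H2max <- max(.entropy(amax), H2)
    H2min <- min(.entropy(amin), H2)
    if (H2max - H2min < 1e-12) return(0)
    min(1, max(0, (H2max - H2) / (H2max - H2min)))
}

#' Species-level specialization d'
#'
#' Kullback-Leibler divergence of each species' interaction proportions
#' from partner availability (the partner marginal divided by the network
#' total), standardized to [0, 1] by the analytic extremes given the
#' marginals: d_min = 0 (a profile matching availability), d_max from
#' concentrating the species' total on the least available partners
#' (filling min(own total, partner total) in order of increasing
#' availability).
#'
#' @inheritParams basicIndices
#' @param axis \code{"insect"} (columns, default) or \code{"plant"} (rows).
#' @return list with \code{d} (raw KL divergences), \code{dprime}
#'   (standardized) and \code{mean} (mean d').
#' @export
dPrime <- function(m, axis = c("insect", "plant")) {
    axis <- match.arg(axis)
    v <- .asMatrix(m)
    if (axis == "plant") v <- t(v)
    F <- sum(v)
    if (F <= 0) stop("zero-total matrix")
    rs <- rowSums(v)
    avail <- rs / F                   # availability of partners (rows)
    totals <- colSums(v)
    d <- dmax <- numeric(ncol(v))
    ord <- order(avail)
    for (j in seq_len(ncol(v))) {
        if (totals[j] == 0) next
        p <- v[, j] / totals[j]
        pos <- p > 0
        d[j] <- sum(p[pos] * log(p[pos] / avail[pos]))
        remaining <- totals[j]
        dm <- 0
        for (i in ord) {
            t <- min(remaining, rs[i])
            if (t > 0) {
                q <- t / totals[j]
                dm <- dm + q * log(q / avail[i])
                remaining <- remaining - t
            }
            if (remaining == 0) break
        }
        dmax[j] <- dm
    }
    dprime <- ifelse(dmax > 1e-12, pmin(1, pmax(0, d / dmax)), 0)
    names(d) <- names(dprime) <- colnames(v)
    list(d = d, dprime = dprime, mean = mean(dprime))
}
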