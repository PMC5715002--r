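# Nestedness temperature of a binary matrix. The classic temperature
# calculator is under-specified, so the convention here is fully
# documented and validated by limit cases:
#   * packing: rows and columns sorted by decreasing marginal totals,
#     ties broken lexicographically by label;
#   * cell (i, j) of the packed P x A matrix maps to the unit square at
#     x = (j - 1/2)/A, y = (i - 1/2)/P (generalists at the origin);
#   * the isocline of perfect nestedness is the fill-matched member of
#     the family y = (1 - x^p)^(1/p), the curve from (0,1) to (1,0)
#     whose enclosed area equals the fill; presences of a perfectly
#     nested matrix occupy the region below it;
#   * unexpectedness u of a presence above the isocline (or an absence
#     below it) is its distance to the isocline along the cell's
#     positive diagonal, divided by the length of that diagonal inside
#     the unit square; expected cells have u = 0;
#   * T = 100 * mean(u^2) / 0.04145, clamped to [0, 100] (0.04145 is the
#     classic normalization constant for a maximally unexpected matrix).

# area under (1 - x^p)^(1/p) on [0, 1], trapezoid rule
.isoArea <- function(p, xg) {
    y <- (1 - xg^p)^(1 / p)
    sum((y[-1] + y[-length(y)]) / 2 * diff(xg))
}

# fill-matched isocline as a vectorized function of x
.isocline <- function(fill, ngrid = 1024L) {
    xg <- seq(0, 1, length.out = ngrid + 1L)
    lo <- 0.005; hi <- 200
    fill <- min(max(fill, .isoArea(lo, xg) + 1e-9),
                .isoArea(hi, xg) - 1e-9)
    p <- stats::uniroot(function(q) .isoArea(q, xg) - fill,
                        c(lo, hi), tol = 1e-9)$root
    yg <- (1 - xg^p)^(1 / p)
    stats::approxfun(xg, yg, rule = 2)
}

#' Nestedness temperature
#'
#' Disorder of the packed binary interaction matrix on a 0 (perfectly
#' nested) to 100 (maximally unexpected) scale, and the derived nestedness
#' score (100 - T)/100 in [0, 1]. See the package vignette for the exact
#' packing, isocline and normalization conventions. Degenerate matrices
#' (a single row or column) have T = 0 by convention.
#'
#' @inheritParams basicIndices
#' @return list with elements \code{temperature} and \code{score}.
#' @examples
#' stair <- outer(4:1, 1:4, function(r, j) as.integer(j <= r))
#' dimnames(stair) <- list(paste0("p", 1:4), paste0("a", 1:4))
#' nestednessTemperature(stair)$score
#' @export
nestednessTemperature <- function(m) {
    b <- .asMatrix(m) > 0
    P <- nrow(b); A <- ncol(b)
    if (P <= 1 || A <= 1 || all(b) )
        return(list(temperature = 0, score = 1))
    rn <- rownames(b) %||% as.character(seq_len(P))
    cn <- colnames(b) %||% as.character(seq_len(A))
    b <- b[order(-rowSums(b), rn), order(-colSums(b), cn), drop = FALSE]
    fill <- sum(b) / (P * A)
    g <- .isocline(fill)

    ij <- which(b | !b, arr.ind = TRUE)   # all cells
    y <- (ij[, 1] - 0.5) / P
    x <- (ij[, 2] - 0.5) / A
    gy <- g(x)
    present <- b[ij]
    unexpected <- (present & y > gy) | (!present & y < gy)
    u2sum <- 0
    if (any(unexpected)) {
        xu <- x[unexpected]; yu <- y[unexpected]
        t0 <- -pmin(xu, yu)
        t1 <- 1 - pmax(xu, yu)
        D <- t1 - t0
        h <- function(t) (yu + t) - g(xu + t)   # increasing in t
        h0 <- h(t0); h1 <- h(t1)
        lo <- t0; hi <- t1
        # bisection for the crossing; clamp when the diagonal misses it
        for (k in 1:40) {
            mid <- (lo + hi) / 2
            hm <- h(mid)
            below <- hm < 0
            lo[below] <- mid[below]
            hi[!below] <- mid[!below]
        }
        tstar <- (lo + hi) / 2
        tstar[h0 >= 0] <- t0[h0 >= 0]
        tstar[h1 <= 0] <- t1[h1 <= 0]
        u <- abs(tstar) / D
        u2sum <- sum(u^2)
    }
    temp <- min(100, 100 * (u2sum / (P * A)) / 0.04145)
    list(temperature = temp, score = (100 - temp) / 100)
}
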