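# Size, link-count and entropy-based indices computed directly from the
# matrix. Throughout, P = number of plant rows, A = number of pollinator
# columns, I = number of nonzero cells, F = total interaction count.

.asMatrix <- function(m) {
    if (is(m, "InteractionMatrix")) interactionValues(m) else as.matrix(m)
}

#' Basic network indices
#'
#' Sizes and link-derived ratios: number of pollinators A and plants P,
#' network size A*P, number of links I (nonzero cells), connectance
#' C = I/(A*P), interaction density I/(A+P), and the mean linkage levels
#' I/P (links per plant) and I/A (links per pollinator).
#'
#' @param m an \linkS4class{InteractionMatrix} or plain matrix (plants in
#'   rows).
#' @return named list with A, P, size, I, connectance,
#'   interaction_density, mean_plant_linkage, mean_insect_linkage.
#' @examples
#' m <- matrix(c(1, 1, 0, 1), 2, 2)
#' basicIndices(m)$connectance
#' @export
basicIndices <- function(m) {
    v <- .asMatrix(m)
    if (length(v) == 0 || sum(v) == 0) stop("empty matrix")
    P <- nrow(v); A <- ncol(v); I <- sum(v > 0)
    list(A = A, P = P, size = A * P, I = I,
         connectance = I / (A * P),
         interaction_density = I / (A + P),
         mean_plant_linkage = I / P,
         mean_insect_linkage = I / A)
}

#' Interaction evenness
#'
#' Shannon entropy of the interaction frequencies over all cells divided
#' by its maximum ln(A*P): E2 = H2'' / Hmax, with Hmax attained only by
#' the full uniform matrix. Measures the skewness of the distribution of
#' interaction frequencies.
#'
#' @inheritParams basicIndices
#' @return evenness in [0, 1].
#' @examples
#' interactionEvenness(matrix(c(2, 1, 1, 0), 2, 2))  # 0.75
#' @export
interactionEvenness <- function(m) {
    v <- .asMatrix(m)
    total <- sum(v)
    if (total <= 0) stop("zero-total matrix")
    p <- v[v > 0] / total
    H <- -sum(p * log(p))
    Hmax <- log(nrow(v) * ncol(v))
    if (Hmax == 0) return(0)
    min(1, H / Hmax)
}

#' Extreme specialization
#'
#' Percentage of species on one axis with exactly one interaction partner.
#'
#' @inheritParams basicIndices
#' @param axis \code{"plant"} (rows) or \code{"insect"} (columns).
#' @return percentage in [0, 100].
#' @export
extremeSpecialization <- function(m, axis = c("plant", "insect")) {
    axis <- match.arg(axis)
    v <- .asMatrix(m)
    deg <- if (axis == "plant") rowSums(v > 0) else colSums(v > 0)
    if (length(deg) == 0) return(0)
    100 * mean(deg == 1)
}
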