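# Connectivity pattern: the cumulative degree distribution P(k >= s)
# fitted by least squares against exponential, power-law and truncated
# power-law decay, and the log-log regression of links per species on
# interaction frequency.

#' Fit the cumulative degree distribution
#'
#' Computes P(k >= s) over the distinct positive degrees s of one axis
#' and fits three candidate decay laws by nonlinear least squares:
#' exponential exp(-s/gamma), power law s^(-gamma), and truncated power
#' law s^(-gamma) exp(-s/kx). Reports per-model parameters, R-squared and
#' AIC (Gaussian, n log(RSS/n) + 2(k+1)) and the AIC-best model.
#'
#' @inheritParams basicIndices
#' @param axis \code{"insect"} (columns) or \code{"plant"} (rows).
#' @param minDegrees minimum number of distinct degree values required.
#' @return list with \code{s}, \code{cumulative}, \code{fits} (per-model
#'   list of parameters, r_squared, aic), \code{best}, and \code{fitted}
#'   flag (FALSE when too few distinct degrees).
#' @export
degreeDistributionFit <- function(m, axis = c("insect", "plant"),
                                  minDegrees = 5L) {
    axis <- match.arg(axis)
    v <- .asMatrix(m)
    deg <- if (axis == "insect") colSums(v > 0) else rowSums(v > 0)
    deg <- deg[deg > 0]
    s <- sort(unique(deg))
    y <- vapply(s, function(k) mean(deg >= k), numeric(1))
    if (length(s) < minDegrees)
        return(list(s = s, cumulative = y, fits = list(), best = NA_character_,
                    fitted = FALSE))
    dat <- data.frame(s = s, y = y)
    n <- nrow(dat)
    tss <- sum((y - mean(y))^2)
    aic <- function(rss, k) n * log(rss / n) + 2 * (k + 1)

    fits <- list()
    # starting values from linearized fits
    lin_exp <- stats::lm(log(y) ~ s, dat)
    lin_pow <- stats::lm(log(y) ~ log(s), dat)
    lin_tpl <- stats::lm(log(y) ~ log(s) + s, dat)

    tryFit <- function(formula, start, k) {
        fit <- tryCatch(stats::nls(formula, dat, start = start,
                                   control = stats::nls.control(
                                       maxiter = 200, warnOnly = TRUE)),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        rss <- sum(stats::residuals(fit)^2)
        list(parameters = stats::coef(fit),
             r_squared = 1 - rss / tss, aic = aic(rss, k))
    }
    g0 <- max(0.1, -1 / stats::coef(lin_exp)[2])
    fits$exponential <- tryFit(y ~ exp(-s / gamma), list(gamma = g0), 1)
    p0 <- max(0.05, -stats::coef(lin_pow)[2])
    fits$power_law <- tryFit(y ~ s^(-gamma), list(gamma = p0), 1)
    t0 <- stats::coef(lin_tpl)
    kx0 <- if (is.finite(t0[3]) && t0[3] < 0) -1 / t0[3] else max(s)
    fits$truncated_power_law <- tryFit(
        y ~ s^(-gamma) * exp(-s / kx),
        list(gamma = max(0.01, -t0[2]), kx = max(kx0, 0.5)), 2)

    fits <- Filter(Negate(is.null), fits)
    best <- if (length(fits))
        names(fits)[which.min(vapply(fits, `[[`, numeric(1), "aic"))]
    else NA_character_
    list(s = s, cumulative = y, fits = fits, best = best, fitted = TRUE)
}

#' Frequency-connectivity regression
#'
#' Ordinary least squares of log10(number of links per species) on
#' log10(interaction frequency f = marginal total), characterizing how
#' connectivity grows with sampling of a species' interactions.
#'
#' @inheritParams basicIndices
#' @param axis \code{"insect"} (columns) or \code{"plant"} (rows).
#' @return list with \code{slope}, \code{intercept}, \code{se},
#'   \code{p_value}, \code{n}.
#' @export
fsRegression <- function(m, axis = c("insect", "plant")) {
    axis <- match.arg(axis)
    v <- .asMatrix(m)
    f <- if (axis == "insect") colSums(v) else rowSums(v)
    s <- if (axis == "insect") colSums(v > 0) else rowSums(v > 0)
    keep <- f > 0
    f <- f[keep]; s <- s[keep]
    if (length(f) < 2) stop("regression needs at least two species")
    fit <- stats::lm(log10(s) ~ log10(f))
    # binary matrices have s == f: the fit is exact and summary.lm warns
    cf <- suppressWarnings(summary(fit))$coefficients
    list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
         se = unname(cf[2, 2]),
         p_value = unname(cf[2, 4]), n = length(f))
}
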