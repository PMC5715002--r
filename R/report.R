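# The full index suite for one network, mirroring the standard
# characteristics table of bipartite pollination-network studies.

.INDEX_ORDER <- c("A", "P", "size", "I", "connectance", "nestedness",
                  "modularity", "n_modules", "interaction_density",
                  "mean_plant_linkage", "mean_insect_linkage", "H2prime",
                  "evenness", "mean_plant_dprime", "mean_insect_dprime",
                  "extreme_plant_spec", "extreme_insect_spec")

#' Compute the full network-index suite
#'
#' Assembles the standard characteristics of a bipartite pollination
#' network into an \linkS4class{IndexReport}: species counts A and P,
#' size A*P, links I, connectance I/(A*P), nestedness (100 - T)/100,
#' Barber modularity and module count, interaction density I/(A+P), mean
#' plant and insect linkage levels I/P and I/A, network specialization
#' H2', interaction evenness, mean plant and insect d', and extreme
#' specialization percentages (species with a single partner). Optionally
#' adds the log-log frequency-connectivity regression slopes on both
#' axes.
#'
#' @inheritParams basicIndices
#' @param modularityRestarts restarts for the modularity search (reduce
#'   for null/rarefaction replicates).
#' @param seed seed for the modularity search.
#' @param slopes include fs-regression slopes (species-level matrices).
#' @return an \linkS4class{IndexReport}.
#' @examples
#' sc <- simulateScenario(communitySpec(seed = 5))
#' obs <- aggregateNetwork(buildObsMatrix(sc$visits), sc$registry, "species")
#' networkIndices(obs)
#' @export
networkIndices <- function(m, modularityRestarts = 10L, seed = 1L,
                           slopes = FALSE) {
    v <- .asMatrix(m)
    b <- basicIndices(v)
    nest <- nestednessTemperature(v)
    mod <- bipartiteModularity(v, nRestarts = modularityRestarts,
                               seed = seed)
    vals <- c(A = b$A, P = b$P, size = b$size, I = b$I,
              connectance = b$connectance,
              nestedness = nest$score,
              modularity = mod$Q, n_modules = mod$nModules,
              interaction_density = b$interaction_density,
              mean_plant_linkage = b$mean_plant_linkage,
              mean_insect_linkage = b$mean_insect_linkage,
              H2prime = h2Prime(v),
              evenness = interactionEvenness(v),
              mean_plant_dprime = dPrime(v, "plant")$mean,
              mean_insect_dprime = dPrime(v, "insect")$mean,
              extreme_plant_spec = extremeSpecialization(v, "plant"),
              extreme_insect_spec = extremeSpecialization(v, "insect"))
    if (slopes) {
        si <- tryCatch(fsRegression(v, "insect")$slope,
                       error = function(e) NA_real_)
        sp <- tryCatch(fsRegression(v, "plant")$slope,
                       error = function(e) NA_real_)
        vals <- c(vals, fs_slope_insect = si, fs_slope_plant = sp)
    }
    lv <- if (is(m, "InteractionMatrix")) networkLevel(m) else "species"
    pv <- if (is(m, "InteractionMatrix")) provenance(m) else "obs"
    new("IndexReport", values = vals, level = lv, provenance = pv)
}

#' Serialize an IndexReport
#'
#' One TSV row per network plus a JSON document mirroring the report.
#'
#' @param report an \linkS4class{IndexReport}.
#' @param file base path without extension; writes \code{<file>.tsv} and
#'   \code{<file>.json}.
#' @return invisibly, the paths written.
#' @export
writeIndexReport <- function(report, file) {
    df <- as.data.frame(t(indexValues(report)))
    df <- cbind(level = report@level, provenance = report@provenance, df)
    tsv <- paste0(file, ".tsv"); js <- paste0(file, ".json")
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(list(level = report@level,
                              provenance = report@provenance,
                              indices = as.list(indexValues(report))),
                         js, auto_unbox = TRUE, digits = NA)
    invisible(c(tsv, js))
}
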