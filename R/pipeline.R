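# End-to-end pipeline: simulate (or read) -> build -> indices -> null
# envelopes -> rarefaction comparison -> side-by-side report, with a run
# log recording the seed and filter tallies.

.defaultConfig <- function() {
    list(inputDir = NULL, community = list(), contamination = list(),
         threshold = 1000, levels = c("group", "species", "individual"),
         nNull = 100L, nRarefy = 1000L, minIndividuals = 10L, seed = 1L)
}

#' Read a pipeline configuration file
#'
#' JSON with nested sections mirroring \code{runPipeline}'s config list:
#' \code{community} and \code{contamination} parameter overrides (or
#' \code{inputDir} pointing at scenario TSVs), \code{threshold},
#' \code{levels}, \code{nNull}, \code{nRarefy}, \code{minIndividuals},
#' \code{seed}.
#'
#' @param path JSON file path.
#' @return config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- .defaultConfig()
    cfg[names(user)] <- user
    cfg
}

.validateConfig <- function(cfg) {
    if (cfg$nNull < 1 || cfg$nRarefy < 1)
        stop("replicate counts (nNull, nRarefy) must be >= 1")
    if (cfg$threshold < 0) stop("threshold must be >= 0")
    if (!all(cfg$levels %in% .LEVELS)) stop("unknown level requested")
    cfg
}

.writeMatrix <- function(m, dir, name) {
    v <- interactionValues(m)
    utils::write.table(data.frame(plant = rownames(v), v,
                                  check.names = FALSE),
                       file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(level = networkLevel(m),
                              provenance = provenance(m),
                              threshold = thresholdUsed(m),
                              n_plants = nrow(v), n_pollinators = ncol(v),
                              n_links = sum(v > 0)),
                         file.path(dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Chains scenario simulation (or TSV input), network construction at the
#' requested levels, the index suite with Patefield null-model envelopes
#' for the species-level obs and seq networks, degree-distribution fits,
#' the rarefaction comparison, and the side-by-side characteristics
#' table. All outputs are written as TSV/JSON under \code{outDir} (when
#' given) together with a run log; the same config and seed reproduce
#' byte-identical outputs.
#'
#' @param config named list (see \code{\link{readRunConfig}}); missing
#'   entries take defaults.
#' @param configFile optional JSON config path (overridden by
#'   \code{config} entries).
#' @param seed overrides the config seed when given.
#' @param outDir output directory; no files are written when NULL.
#' @return (invisibly) a list with the scenario, matrices, reports, null
#'   ensembles, comparison, degree fits, contamination profile, threshold
#'   sensitivity and the rendered table.
#' @examples
#' \donttest{
#' res <- runPipeline(list(nNull = 20, nRarefy = 50, seed = 2))
#' res$table1
#' }
#' @export
runPipeline <- function(config = list(), configFile = NULL, seed = NULL,
                        outDir = NULL) {
    cfg <- if (!is.null(configFile)) readRunConfig(configFile)
           else .defaultConfig()
    cfg[names(config)] <- config
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    cfg <- .validateConfig(cfg)
    log <- c(sprintf("pollinet %s", as.character(utils::packageVersion("pollinet"))),
             sprintf("seed: %d", cfg$seed),
             sprintf("threshold: %g", cfg$threshold))

    # --- data stage ------------------------------------------------------
    if (!is.null(cfg$inputDir)) {
        sc <- readScenario(cfg$inputDir)
        log <- c(log, sprintf("input: %s", cfg$inputDir))
    } else {
        cspec <- do.call(communitySpec,
                         c(cfg$community, list(seed = cfg$seed)))
        cont <- do.call(contaminationSpec, cfg$contamination)
        sc <- simulateScenario(cspec, cont, threshold = cfg$threshold)
        log <- c(log, "input: synthetic scenario")
    }

    # --- build stage -----------------------------------------------------
    obsInd <- buildObsMatrix(sc$visits)
    seqInd <- callInteractions(sc$seqTable, sc$registry, cfg$threshold)
    nDropped <- nrow(sc$seqTable) - ncol(interactionValues(seqInd))
    pl <- plantInfo(sc$registry)
    nExcluded <- sum(pl$pollination_mode == "wind" |
                     !pl$rank %in% c("species", "genus"))
    log <- c(log,
             sprintf("insects dropped by thresholding: %d", nDropped),
             sprintf("plant taxa excluded (wind/higher-rank): %d", nExcluded))

    matrices <- list(obs_individual = obsInd, seq_individual = seqInd)
    if ("species" %in% cfg$levels) {
        matrices$obs_species <- aggregateNetwork(obsInd, sc$registry,
                                                 "species")
        matrices$seq_species <- aggregateNetwork(seqInd, sc$registry,
                                                 "species")
    }
    if ("group" %in% cfg$levels) {
        matrices$obs_group <- aggregateNetwork(obsInd, sc$registry, "group")
        matrices$seq_group <- aggregateNetwork(seqInd, sc$registry, "group")
    }
    perSpecies <- if ("individual" %in% cfg$levels)
        list(obs = perSpeciesNetworks(obsInd, sc$registry,
                                      cfg$minIndividuals),
             seq = perSpeciesNetworks(seqInd, sc$registry,
                                      cfg$minIndividuals))
    else NULL

    profile <- contaminationProfile(sc$seqTable, sc$registry, cfg$threshold)
    sensitivity <- thresholdSensitivity(
        sc$seqTable, sc$registry,
        thresholds = cfg$threshold * c(1 / 4, 1 / 2, 1, 2, 4))

    # --- indices & nulls (species level) --------------------------------
    reports <- nulls <- list()
    fits <- comparison <- table1 <- NULL
    if ("species" %in% cfg$levels) {
        reports$obs <- networkIndices(matrices$obs_species, seed = cfg$seed)
        reports$seq <- networkIndices(matrices$seq_species, seed = cfg$seed)
        nulls$obs <- nullEnvelope(matrices$obs_species,
                                  nReplicates = cfg$nNull,
                                  seed = cfg$seed,
                                  observedReport = reports$obs)
        nulls$seq <- nullEnvelope(matrices$seq_species,
                                  nReplicates = cfg$nNull,
                                  seed = cfg$seed + 1L,
                                  observedReport = reports$seq)
        fits <- list(
            obs_insect = degreeDistributionFit(matrices$obs_species,
                                               "insect"),
            seq_insect = degreeDistributionFit(matrices$seq_species,
                                               "insect"),
            obs_plant = degreeDistributionFit(matrices$obs_species,
                                              "plant"),
            seq_plant = degreeDistributionFit(matrices$seq_species,
                                              "plant"),
            obs_fs_insect = fsRegression(matrices$obs_species, "insect"),
            seq_fs_insect = fsRegression(matrices$seq_species, "insect"),
            obs_fs_plant = fsRegression(matrices$obs_species, "plant"),
            seq_fs_plant = fsRegression(matrices$seq_species, "plant"))
        comparison <- compareNetworks(matrices$seq_species,
                                      matrices$obs_species,
                                      nReplicates = cfg$nRarefy,
                                      seed = cfg$seed + 2L)
        table1 <- renderTable1(reports$obs, reports$seq, nulls$obs,
                               nulls$seq, comparison)
    }

    # --- emission --------------------------------------------------------
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeScenario(sc, file.path(outDir, "scenario"))
        for (nm in names(matrices))
            .writeMatrix(matrices[[nm]], outDir, nm)
        if (!is.null(table1))
            utils::write.table(table1, file.path(outDir, "table1.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        if (!is.null(comparison))
            utils::write.table(comparisonTable(comparison),
                               file.path(outDir, "comparison.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        for (nm in names(reports))
            writeIndexReport(reports[[nm]],
                             file.path(outDir, paste0("indices_", nm)))
        utils::write.table(sensitivity,
                           file.path(outDir, "threshold_sensitivity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(profile,
                             file.path(outDir, "contamination_profile.json"),
                             auto_unbox = TRUE, digits = NA)
        writeLines(log, file.path(outDir, "run_log.txt"))
    }

    invisible(list(config = cfg, scenario = sc, matrices = matrices,
                   perSpecies = perSpecies, reports = reports,
                   nulls = nulls, fits = fits, comparison = comparison,
                   contamination = profile, sensitivity = sensitivity,
                   table1 = table1, log = log))
}

#' Render the side-by-side characteristics table
#'
#' Combines the obs and seq index reports, their null-model confidence
#' intervals with significance stars, and the rarefaction-comparison
#' letters into one table in the standard row order.
#'
#' @param obsReport,seqReport \linkS4class{IndexReport}s of the two
#'   networks.
#' @param obsNull,seqNull matching \linkS4class{NullEnsemble}s.
#' @param comparison the \linkS4class{NetworkComparison} of the pair.
#' @return data.frame with one row per index.
#' @export
renderTable1 <- function(obsReport, seqReport, obsNull, seqNull,
                         comparison) {
    stopifnot(is(obsReport, "IndexReport"), is(seqReport, "IndexReport"))
    if (obsReport@provenance != "obs" || seqReport@provenance != "seq")
        stop("reports must come from an obs and a seq network")
    ov <- indexValues(obsReport); sv <- indexValues(seqReport)
    if (!isTRUE(all.equal(obsNull@observed[.INDEX_ORDER],
                          ov[.INDEX_ORDER], tolerance = 1e-6)) ||
        !isTRUE(all.equal(seqNull@observed[.INDEX_ORDER],
                          sv[.INDEX_ORDER], tolerance = 1e-6)))
        stop("null ensembles do not match the reports (mismatched runs)")
    os <- nullSummary(obsNull); ss <- nullSummary(seqNull)
    ct <- comparisonTable(comparison)
    rows <- lapply(.INDEX_ORDER, function(ix) {
        o <- os[os$index == ix, ]; s <- ss[ss$index == ix, ]
        cmp <- ct[ct$index == ix, ]
        fmt_ci <- function(z) if (nrow(z) && is.finite(z$ci_lower))
            sprintf("%.3g-%.3g", z$ci_lower, z$ci_upper) else ""
        star <- function(z) if (nrow(z) && isTRUE(z$significant)) "*"
            else "ns"
        data.frame(index = ix, obs = unname(ov[ix]),
                   obs_ci = fmt_ci(o), obs_flag = star(o),
                   seq = unname(sv[ix]), seq_ci = fmt_ci(s),
                   seq_flag = star(s),
                   letters = if (nrow(cmp)) cmp$letters else "",
                   p_adj = if (nrow(cmp)) cmp$p_adj else NA_real_)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
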