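#' Default pipeline configuration
#'
#' All stage parameters in one nested list. Paths to YAML files with the
#' same structure are accepted wherever a config is expected. The seed is
#' mandatory and drives every stage (per-stage seeds are derived from it by
#' fixed offsets).
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
    list(
        seed = 1,
        synthetic = list(nRil = 64, nPeripheral = 50, noiseSd = 0.15),
        aps = list(),
        structure = list(nBoot = 200, method = "average",
                         subset = c("na_144", "k_144", "na_k_144",
                                    "eli_72", "eli_144")),
        growth = list(kSd = 2, persist = TRUE),
        networks = list(pccMin = 0.95, mrMax = 10, literalMr = FALSE,
                        cohortSize = 20, nBackground = 25, nBaits = 3),
        stages = list(structure = TRUE, growth = TRUE, networks = TRUE),
        outDir = NULL)
}

#' Validate a pipeline configuration
#'
#' Checks every entry (including nested stage blocks) against the known
#' configuration schema before any stage runs; unknown names error.
#'
#' @param config nested list, or path to a YAML file.
#' @return the merged configuration (defaults filled in), invisibly usable
#'   by [runPipeline()].
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config) && length(config) == 1) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    defaults <- defaultConfig()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown configuration entr",
             if (length(unknown) > 1) "ies: " else "y: ",
             paste(unknown, collapse = ", "))
    for (blk in intersect(names(config), names(defaults))) {
        if (is.list(defaults[[blk]]) && length(names(defaults[[blk]]))) {
            bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
            if (length(bad))
                stop("unknown configuration entry in '", blk, "': ",
                     paste(bad, collapse = ", "))
        }
    }
    merged <- utils::modifyList(defaults, config)
    if (!is.numeric(merged$seed))
        stop("seed is mandatory for synthetic runs")
    merged
}

#' Classify genotypes from APS and inverted SES
#'
#' Quantile bins on the inverted SES score give the ordinal classes
#' (Sensitive / Moderate / Tolerant); genotypes beyond both parents'
#' values on both APS and inverted SES are flagged as transgressive
#' outliers ("Super tolerant" above, "Supersensitive" below). Without
#' parents in the cohort the outlier rule is disabled with a warning.
#'
#' @param aps named numeric vector of APS values.
#' @param sesInv named numeric vector of inverted SES scores (same names).
#' @param parents character vector of the two parent ids (optional).
#' @param probs quantile bin edges on inverted SES (default thirds).
#' @return named character vector of class labels.
#' @export
classifyPhenotypes <- function(aps, sesInv, parents = NULL,
                               probs = c(1 / 3, 2 / 3)) {
    if (!identical(names(aps), names(sesInv)))
        stop("aps and sesInv must cover the same genotypes")
    edges <- unique(quantile(sesInv, probs = probs))
    labels <- cut(sesInv, breaks = c(-Inf, edges, Inf),
                  labels = c("Sensitive", "Moderate",
                             "Tolerant")[seq_len(length(edges) + 1)],
                  right = TRUE)
    out <- setNames(as.character(labels), names(aps))
    if (is.null(parents) || !all(parents %in% names(aps))) {
        warning("parents absent; transgressive outlier rule disabled")
        return(out)
    }
    pa <- aps[parents]; ps <- sesInv[parents]
    super <- aps > max(pa) & sesInv > max(ps)
    infer <- aps < min(pa) & sesInv < min(ps)
    out[super] <- "Super tolerant"
    out[infer] <- "Supersensitive"
    out
}

#' Run the full multi-tier analysis pipeline
#'
#' Orchestrates population synthesis, APS scoring and classification,
#' trait-matrix clustering with bootstrap support (full matrix and
#' salt-exclusion subset), growth-fork profiling of a representative panel,
#' and bait-cohort network construction with cross-genotype rewiring
#' statistics. Deterministic under a fixed configuration and seed; all
#' stage outputs are collected into the returned report and, when
#' \code{outDir} is set, written to disk (TSV/CSV/Newick/JSON).
#'
#' @param config nested list or YAML path (see [defaultConfig()],
#'   [validateConfig()]).
#' @return list of class \code{"RunReport"} with elements \code{aps}
#'   (data.frame: genotype, APS, SES, inverted SES, classification),
#'   \code{perParameterR2}, \code{trees} (Newick strings and BP vectors),
#'   \code{forks}, \code{networks} (cohort sizes, median-expression and
#'   shared-cohort matrices, least-similar genotype), \code{population},
#'   and \code{provenance}.
#' @export
runPipeline <- function(config = defaultConfig()) {
    cfg <- validateConfig(if (missing(config)) list() else config)
    seed <- as.integer(cfg$seed)

    pop <- simulatePopulation(nRil = cfg$synthetic$nRil,
                              nPeripheral = cfg$synthetic$nPeripheral,
                              model = defaultEffectModel(
                                  cfg$synthetic$nPeripheral,
                                  noiseSd = cfg$synthetic$noiseSd),
                              seed = seed)
    tm <- populationTraits(pop)
    sm <- scoreTraits(tm)
    aps <- apsScores(sm)
    sesInv <- sesInverted(sm)

    classification <- classifyPhenotypes(aps, sesInv,
                                         parents = parentIds(pop))
    apsTable <- data.frame(genotype = names(aps), APS = unname(aps),
                           SES = unname(sesScores(tm)[names(aps)]),
                           SES_inverted = unname(sesInv),
                           classification = unname(classification))
    r2 <- vapply(colnames(scoreValues(sm)), function(p)
        correlateWithSes(scoreValues(sm)[, p], sesInv)$rSquared,
        numeric(1))

    trees <- NULL
    if (isTRUE(cfg$stages$structure)) {
        full <- bootstrapSupport(sm, nBoot = cfg$structure$nBoot,
                                 method = cfg$structure$method,
                                 seed = seed + 11L)
        sub <- bootstrapSupport(sm, subset = cfg$structure$subset,
                                nBoot = cfg$structure$nBoot,
                                method = cfg$structure$method,
                                seed = seed + 12L)
        ses <- sesScores(tm)
        trees <- list(
            full = list(newick = writeNewick(full, sesSuffix = ses),
                        bp = full$bp),
            saltExclusion = list(newick = writeNewick(sub, sesSuffix = ses),
                                 bp = sub$bp))
    }

    forks <- NULL
    if (isTRUE(cfg$stages$growth)) {
        panel <- unique(c(parentIds(pop), designatedOutliers(pop)))
        tol <- (aps - min(aps)) / (max(aps) - min(aps))
        forks <- lapply(seq_along(panel), function(i) {
            gs <- simulateGrowth(tol[[panel[i]]], seed = seed + 100L + i,
                                 genotype = panel[i])
            fr <- detectFork(gs, kSd = cfg$growth$kSd,
                             persist = cfg$growth$persist)
            list(genotype = panel[i], tolerance = tol[[panel[i]]],
                 forkDay = fr$forkDay, forkAngleDeg = fr$forkAngleDeg,
                 units = fr$units,
                 finalPsaRatio = unname(fr$psaRatio[length(fr$psaRatio)]))
        })
        names(forks) <- panel
    }

    networks <- NULL
    if (isTRUE(cfg$stages$networks)) {
        networks <- .networkStage(pop, cfg, seed + 200L)
    }

    report <- list(aps = apsTable, perParameterR2 = r2, trees = trees,
                   forks = forks, networks = networks, population = pop,
                   provenance = list(seed = seed, config = cfg,
                                     package = "transeg",
                                     version = as.character(
                                         utils::packageVersion("transeg"))))
    class(report) <- "RunReport"
    if (!is.null(cfg$outDir)) .writeReport(report, tm, sm, cfg$outDir)
    report
}

# Rewiring experiment: parents and the tolerant outlier share planted
# cohorts; the super-tolerant outlier gets disjoint (rewired) cohorts over
# the same gene universe.
.networkStage <- function(pop, cfg, seed) {
    ncfg <- cfg$networks
    baits <- sprintf("BAIT%d", seq_len(ncfg$nBaits))
    shared <- split(sprintf("C%03d", seq_len(ncfg$cohortSize * ncfg$nBaits)),
                    rep(seq_len(ncfg$nBaits), each = ncfg$cohortSize))
    rewired <- split(sprintf("R%03d", seq_len(ncfg$cohortSize * ncfg$nBaits)),
                     rep(seq_len(ncfg$nBaits), each = ncfg$cohortSize))
    names(shared) <- names(rewired) <- baits
    bg <- sprintf("BG%04d", seq_len(ncfg$nBackground))
    universe <- c(unlist(shared), unlist(rewired), bg)
    rewiredId <- unname(designatedOutliers(pop)["super_tolerant"])
    panel <- unique(c(parentIds(pop), designatedOutliers(pop)))
    etcs <- list(); cohorts <- list()
    for (i in seq_along(panel)) {
        g <- panel[i]
        planted <- if (g == rewiredId) rewired else shared
        etc <- simulateExpression(
            g, planted,
            backgroundGenes = setdiff(universe,
                                      unlist(planted, use.names = FALSE)),
            seed = seed + i)
        etcs[[g]] <- etc
        rec <- lapply(baits, function(b)
            cohortGenes(buildNetwork(etc, pccMin = ncfg$pccMin,
                                     mrMax = ncfg$mrMax,
                                     literalMr = ncfg$literalMr,
                                     bait = b)))
        cohorts[[g]] <- sort(unique(unlist(rec)))
    }
    medCor <- compareMedianExpression(cohorts, etcs)
    shr <- sharedCohortMatrix(cohorts)
    offDiag <- function(m) {
        diag(m) <- NA
        rowMeans(m, na.rm = TRUE)
    }
    list(cohortSizes = lengths(cohorts),
         medianExpressionCor = medCor,
         sharedCounts = shr$counts, sharedJaccard = shr$jaccard,
         leastSimilar = names(which.min(offDiag(medCor))),
         rewiredGenotype = rewiredId)
}

.writeReport <- function(report, tm, sm, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTraitMatrix(tm, file.path(outDir, "traits.tsv"))
    writeDirections(tm, file.path(outDir, "directions.yaml"))
    writeScoreMatrix(sm, file.path(outDir, "scores.tsv"))
    writeGroundTruth(report$population, file.path(outDir,
                                                  "ground_truth.json"))
    if (!is.null(report$trees)) {
        writeLines(report$trees$full$newick,
                   file.path(outDir, "tree_full.nwk"))
        writeLines(report$trees$saltExclusion$newick,
                   file.path(outDir, "tree_salt_exclusion.nwk"))
    }
    summary <- report[c("perParameterR2", "forks")]
    summary$classification <- report$aps
    summary$networks <- report$networks[c("cohortSizes", "leastSimilar",
                                          "rewiredGenotype")]
    summary$provenance <- report$provenance[c("seed", "package", "version")]
    jsonlite::write_json(summary, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(outDir)
}

#' @export
print.RunReport <- function(x, ...) {
    cat("RunReport (seed ", x$provenance$seed, ")\n", sep = "")
    best <- x$aps$genotype[which.max(x$aps$APS)]
    cat("  ", nrow(x$aps), " genotypes; best APS: ", best, " (",
        round(max(x$aps$APS), 1), ")\n", sep = "")
    cat("  classes:", paste(names(table(x$aps$classification)),
                            table(x$aps$classification),
                            sep = "=", collapse = ", "), "\n")
    if (!is.null(x$networks))
        cat("  least-similar network genotype:",
            x$networks$leastSimilar, "\n")
    invisible(x)
}
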