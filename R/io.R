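#' Read and write pipeline artifacts
#'
#' Trait and score matrices travel as TSV (genotypes in rows, header row
#' required), growth series as long-format CSV, trees as Newick, cohort
#' membership and simulator ground truth as JSON sidecars.
#'
#' @param x object to serialize.
#' @param path file path.
#' @name transeg-io
NULL

#' @rdname transeg-io
#' @export
writeTraitMatrix <- function(x, path) {
    stopifnot(is(x, "TraitMatrix"))
    df <- data.frame(genotype = rownames(traitValues(x)),
                     traitValues(x), check.names = FALSE)
    if (length(sesScores(x)))
        df$SES <- sesScores(x)[df$genotype]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname transeg-io
#' @param directions named character vector of per-parameter orientations,
#'   or the path of a YAML file mapping parameter -> direction.
#' @export
readTraitMatrix <- function(path, directions) {
    df <- utils::read.delim(path, check.names = FALSE)
    if (is.character(directions) && length(directions) == 1 &&
        file.exists(directions))
        directions <- unlist(yaml::read_yaml(directions))
    ses <- numeric()
    if ("SES" %in% colnames(df))
        ses <- setNames(df$SES, df$genotype)
    params <- setdiff(colnames(df), c("genotype", "SES"))
    values <- as.matrix(df[, params, drop = FALSE])
    rownames(values) <- df$genotype
    TraitMatrix(values, directions[params], ses = ses)
}

#' @rdname transeg-io
#' @export
writeDirections <- function(x, path) {
    stopifnot(is(x, "TraitMatrix"))
    yaml::write_yaml(as.list(traitDirections(x)), path)
    invisible(path)
}

#' @rdname transeg-io
#' @export
writeScoreMatrix <- function(x, path) {
    stopifnot(is(x, "ScoreMatrix"))
    df <- data.frame(genotype = rownames(scoreValues(x)), scoreValues(x),
                     APS = apsScores(x), check.names = FALSE)
    if (length(sesInverted(x)))
        df$SES_inverted <- sesInverted(x)[df$genotype]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname transeg-io
#' @export
writeGrowthSeries <- function(x, path) {
    stopifnot(is(x, "GrowthSeries"))
    rows <- do.call(rbind, lapply(c("control", "stress"), function(arm)
        data.frame(genotype = x@genotype, condition = arm,
                   day = growthDays(x),
                   area_cm2 = armSeries(x, arm, "area", "mean"),
                   area_cm2_sd = armSeries(x, arm, "area", "sd"),
                   height_cm = armSeries(x, arm, "height", "mean"),
                   height_cm_sd = armSeries(x, arm, "height", "sd"),
                   n_plants = x@nPlants)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname transeg-io
#' @export
readGrowthSeries <- function(path) {
    df <- utils::read.csv(path)
    need <- c("genotype", "condition", "day", "area_cm2", "height_cm")
    if (!all(need %in% colnames(df)))
        stop("growth CSV must have columns ", paste(need, collapse = ", "))
    if (!"area_cm2_sd" %in% colnames(df)) df$area_cm2_sd <- 0
    if (!"height_cm_sd" %in% colnames(df)) df$height_cm_sd <- 0
    df <- df[order(df$day), ]
    ctl <- df[df$condition == "control", ]
    str <- df[df$condition == "stress", ]
    if (!identical(ctl$day, str$day))
        stop("control and stress arms must cover identical days")
    mk <- function(d, trait) cbind(mean = d[[trait]],
                                   sd = d[[paste0(trait, "_sd")]])
    new("GrowthSeries", genotype = as.character(df$genotype[1]),
        days = as.integer(ctl$day),
        controlArea = mk(ctl, "area_cm2"), stressArea = mk(str, "area_cm2"),
        controlHeight = mk(ctl, "height_cm"),
        stressHeight = mk(str, "height_cm"),
        nPlants = as.integer(if ("n_plants" %in% colnames(df))
                             df$n_plants[1] else 0L),
        metadata = list())
}

#' @rdname transeg-io
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "ExpressionTimeCourse"))
    m <- exprValues(x)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname transeg-io
#' @export
readExpression <- function(path, genotype = "NA") {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    hours <- as.numeric(gsub("[^0-9.]", "", colnames(m)))
    ExpressionTimeCourse(m, timeH = hours, genotype = genotype)
}

#' @rdname transeg-io
#' @export
writeEdgeList <- function(x, path) {
    stopifnot(is(x, "CoexpressionNetwork"))
    utils::write.table(networkEdges(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Serialize a tree as Newick
#'
#' Bootstrap proportions (when present) are written as internal node
#' labels; tip labels can be suffixed with each genotype's SES rating.
#'
#' @param x a \code{phylo}, or a \code{"BootstrapDendrogram"} from
#'   [bootstrapSupport()].
#' @param path optional file path; when \code{NULL} the Newick string is
#'   returned.
#' @param sesSuffix optional named numeric (genotype -> SES) appended to tip
#'   labels as \code{id_SES}.
#' @export
writeNewick <- function(x, path = NULL, sesSuffix = NULL) {
    tree <- if (inherits(x, "BootstrapDendrogram")) x$tree else x
    if (!is.null(sesSuffix)) {
        tree$tip.label <- paste0(tree$tip.label, "_",
                                 sesSuffix[tree$tip.label])
    }
    if (is.null(path)) return(ape::write.tree(tree))
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' @rdname transeg-io
#' @export
writeGroundTruth <- function(x, path) {
    truth <- if (is(x, "SyntheticPopulation"))
        list(outliers = as.list(designatedOutliers(x)),
             parents = parentIds(x), seed = x@seed)
    else x
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
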