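#' @import methods
#' @importFrom stats cor cov dist hclust as.dist median quantile rnorm runif
#'   var sd setNames lm coef prcomp rbinom aggregate complete.cases
NULL

.DIRECTIONS <- c("higher_better", "lower_better")

#' TraitMatrix: genotype x parameter raw measurements
#'
#' Holds raw physio-morphometric measurements for a cohort of genotypes, the
#' per-parameter orientation (whether a larger raw value indicates better
#' performance), and optionally the visual salinity-injury SES rating
#' (1--9 scale, 1 = most tolerant) per genotype.
#'
#' @slot values numeric matrix, genotypes in rows, parameters in columns,
#'   both dimensions named.
#' @slot directions named character vector, one of \code{"higher_better"} or
#'   \code{"lower_better"} per parameter.
#' @slot ses named numeric vector of SES ratings in [1, 9]; may be empty.
#' @exportClass TraitMatrix
setClass("TraitMatrix",
    representation(values = "matrix", directions = "character",
                   ses = "numeric"))

setValidity("TraitMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have genotype rownames and parameter colnames")
    else {
        if (anyDuplicated(rownames(v)))
            msg <- c(msg, "duplicated genotype ids")
        miss <- setdiff(colnames(v), names(object@directions))
        if (length(miss))
            msg <- c(msg, paste0("no direction for parameter(s): ",
                                 paste(miss, collapse = ", ")))
        bad <- setdiff(object@directions, .DIRECTIONS)
        if (length(bad))
            msg <- c(msg, paste0("unknown direction: ", paste(bad, collapse = ", ")))
        if (length(object@ses)) {
            if (is.null(names(object@ses)) ||
                !all(names(object@ses) %in% rownames(v)))
                msg <- c(msg, "ses must be named by genotype ids present in values")
            if (any(object@ses < 1 | object@ses > 9, na.rm = TRUE))
                msg <- c(msg, "ses values must lie in [1, 9]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TraitMatrix
#'
#' @param values genotype x parameter numeric matrix (dimnames required).
#' @param directions named character vector ("higher_better"/"lower_better")
#'   covering every parameter.
#' @param ses optional named numeric vector of SES ratings in [1, 9].
#' @return A \linkS4class{TraitMatrix}.
#' @export
TraitMatrix <- function(values, directions, ses = numeric()) {
    new("TraitMatrix", values = values,
        directions = directions[colnames(values)], ses = ses)
}

#' ScoreMatrix: 1-10 normalized scores with per-genotype APS
#'
#' Result of min-max scoring a \linkS4class{TraitMatrix}: each parameter is
#' mapped onto [1, 10] with 10 always the best-performing genotype, the
#' Aggregate Phenotypic Score (APS) is the (optionally weighted) sum of the
#' scores, and the SES rating is inverted onto the same 1-10 scale.
#'
#' @slot scores numeric matrix of per-parameter scores in [1, 10].
#' @slot aps named numeric vector, one APS per genotype.
#' @slot sesInverted named numeric vector (may be empty).
#' @slot weights named numeric vector of parameter weights used for APS.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
    representation(scores = "matrix", aps = "numeric",
                   sesInverted = "numeric", weights = "numeric"))

setValidity("ScoreMatrix", function(object) {
    s <- object@scores
    msg <- character()
    if (is.null(rownames(s)) || is.null(colnames(s)))
        msg <- c(msg, "scores must carry genotype and parameter dimnames")
    if (any(s < 1 - 1e-9 | s > 10 + 1e-9, na.rm = TRUE))
        msg <- c(msg, "scores must lie in [1, 10]")
    if (!identical(names(object@aps), rownames(s)))
        msg <- c(msg, "aps must be named to match score rows")
    if (length(msg)) msg else TRUE
})

#' ExpressionTimeCourse: per-genotype time-course expression
#'
#' A \linkS4class{SummarizedExperiment} with genes in rows and timepoints
#' (optionally timepoint x replicate) in columns. \code{colData} carries
#' \code{time_h} (hours after stress onset) and \code{replicate}. The
#' genotype id and any planted ground truth (cohort membership from the
#' synthetic generator) live in \code{metadata()}.
#'
#' @exportClass ExpressionTimeCourse
#' @import SummarizedExperiment
setClass("ExpressionTimeCourse", contains = "SummarizedExperiment")

setValidity("ExpressionTimeCourse", function(object) {
    msg <- character()
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    cd <- SummarizedExperiment::colData(object)
    if (!"time_h" %in% colnames(cd))
        msg <- c(msg, "colData must contain time_h")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionTimeCourse
#'
#' @param values gene x column numeric matrix of normalized abundances.
#'   Columns are timepoints, or timepoint/replicate combinations when
#'   \code{replicate} is given.
#' @param timeH numeric vector of hours, one per column of \code{values}.
#' @param genotype genotype id.
#' @param replicate optional integer vector, one per column.
#' @param groundTruth optional list recorded in \code{metadata()} (e.g.
#'   planted cohort membership).
#' @return An \linkS4class{ExpressionTimeCourse}.
#' @export
ExpressionTimeCourse <- function(values, timeH, genotype = "NA",
                                 replicate = NULL, groundTruth = NULL) {
    if (anyDuplicated(rownames(values)))
        stop("duplicate gene identifiers")
    if (length(timeH) != ncol(values))
        stop("timeH must have one entry per column")
    if (is.null(replicate)) replicate <- rep(1L, ncol(values))
    cd <- S4Vectors::DataFrame(time_h = timeH, replicate = replicate)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = values), colData = cd,
        metadata = list(genotype = genotype, groundTruth = groundTruth))
    new("ExpressionTimeCourse", se)
}

#' CoexpressionNetwork: thresholded mutual-rank gene graph
#'
#' Undirected gene graph in which an edge is retained when the Pearson
#' correlation of the two genes' temporal profiles passes \code{pccMin} and
#' their mutual rank passes the MR rule for the chosen mode
#' (\code{"mr_le_max"}: MR <= mrMax, the conventional reading;
#' \code{"literal"}: MR >= 10, the printed exclusion rule applied verbatim).
#'
#' @slot nodes character vector of gene ids in the network universe.
#' @slot edges data.frame with columns gene_a, gene_b, pcc, mr.
#' @slot bait bait gene id (may be empty).
#' @slot cohort extracted cohort gene ids (subset of nodes; may be empty).
#' @slot pccMin,mrMax numeric thresholds.
#' @slot mode threshold mode actually applied ("mr_le_max" or "literal").
#' @slot dropped gene ids removed for zero temporal variance.
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork",
    representation(nodes = "character", edges = "data.frame",
                   bait = "character", cohort = "character",
                   pccMin = "numeric", mrMax = "numeric", mode = "character",
                   dropped = "character"))

setValidity("CoexpressionNetwork", function(object) {
    e <- object@edges
    msg <- character()
    need <- c("gene_a", "gene_b", "pcc", "mr")
    if (!all(need %in% colnames(e)))
        msg <- c(msg, "edges must have columns gene_a, gene_b, pcc, mr")
    else if (nrow(e)) {
        if (any(e$gene_a == e$gene_b))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be network nodes")
    }
    if (length(object@cohort) && !all(object@cohort %in% object@nodes))
        msg <- c(msg, "cohort must be a subset of nodes")
    if (length(msg)) msg else TRUE
})

#' GrowthSeries: paired control/stress daily growth trajectories
#'
#' Daily means and standard deviations of projected shoot area (cm^2) and
#' plant height (cm) for one genotype under control and salinity stress, with
#' the number of plants per arm. Ground truth planted by the simulator (the
#' fork day) is kept in \code{metadata}.
#'
#' @slot genotype genotype id.
#' @slot days strictly increasing integer vector of observation days.
#' @slot controlArea,stressArea,controlHeight,stressHeight numeric matrices
#'   with columns \code{mean} and \code{sd}, one row per day.
#' @slot nPlants integer, plants per arm (0 when unknown).
#' @slot metadata list (e.g. \code{forkDay}, \code{tolerance}).
#' @exportClass GrowthSeries
setClass("GrowthSeries",
    representation(genotype = "character", days = "integer",
                   controlArea = "matrix", stressArea = "matrix",
                   controlHeight = "matrix", stressHeight = "matrix",
                   nPlants = "integer", metadata = "list"))

setValidity("GrowthSeries", function(object) {
    msg <- character()
    d <- object@days
    if (length(d) && any(diff(d) <= 0))
        msg <- c(msg, "days must be strictly increasing")
    for (nm in c("controlArea", "stressArea", "controlHeight", "stressHeight")) {
        m <- slot(object, nm)
        if (!all(c("mean", "sd") %in% colnames(m)))
            msg <- c(msg, paste0(nm, " must have columns mean, sd"))
        else {
            if (nrow(m) != length(d))
                msg <- c(msg, paste0(nm, " must have one row per day"))
            if (any(m[, "sd"] < 0, na.rm = TRUE))
                msg <- c(msg, paste0(nm, " sd must be non-negative"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticPopulation: simulated RIL population with ground truth
#'
#' Homozygous-coded allele matrix (column \code{core} plus peripheral loci;
#' 1 = tolerant-parent allele), the simulated \linkS4class{TraitMatrix},
#' the two parents (all-0 and all-1 genomes) and the designated transgressive
#' outliers constructed to carry, respectively, every beneficial allele and
#' no drags (super-tolerant) or every drag and no beneficial allele
#' (super-sensitive).
#'
#' @slot alleles genotype x locus binary matrix, first column "core".
#' @slot traits a \linkS4class{TraitMatrix}.
#' @slot parents character(2): sensitive-parent id, tolerant-parent id.
#' @slot outliers named character(2): super_tolerant, super_sensitive ids.
#' @slot model the effect model used (list, see [defaultEffectModel()]).
#' @slot seed integer seed the population was generated from.
#' @exportClass SyntheticPopulation
setClass("SyntheticPopulation",
    representation(alleles = "matrix", traits = "TraitMatrix",
                   parents = "character", outliers = "character",
                   model = "list", seed = "integer"))

setValidity("SyntheticPopulation", function(object) {
    msg <- character()
    al <- object@alleles
    if (!all(al %in% c(0, 1)))
        msg <- c(msg, "alleles must be homozygous-coded 0/1")
    if (!all(object@parents %in% rownames(al)))
        msg <- c(msg, "parents must be present in the allele matrix")
    if (length(object@parents) != 2 ||
        anyDuplicated(match(object@parents, rownames(al))))
        msg <- c(msg, "exactly one genome per parent")
    if (!all(object@outliers %in% rownames(al)))
        msg <- c(msg, "designated outliers must exist in the population")
    if (length(msg)) msg else TRUE
})
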