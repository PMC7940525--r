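#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("traitValues", "TraitMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("traitDirections", "TraitMatrix", function(x) x@directions)
#' @rdname accessors
#' @export
setMethod("sesScores", "TraitMatrix", function(x) x@ses)

#' @rdname accessors
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("apsScores", "ScoreMatrix", function(x) x@aps)
#' @rdname accessors
#' @export
setMethod("sesInverted", "ScoreMatrix", function(x) x@sesInverted)

#' @rdname accessors
#' @param collapse for \code{exprValues}: \code{"replicate_mean"} (default)
#'   averages replicate columns per timepoint so columns are unique
#'   timepoints; \code{"none"} returns the stored columns;
#'   \code{"concatenate"} returns the stored columns ordered by time then
#'   replicate (replicate-aware correlation mode).
#' @export
setMethod("exprValues", "ExpressionTimeCourse",
    function(x, collapse = c("replicate_mean", "none", "concatenate")) {
    collapse <- match.arg(collapse)
    m <- SummarizedExperiment::assay(x, "abundance")
    tm <- SummarizedExperiment::colData(x)$time_h
    rp <- SummarizedExperiment::colData(x)$replicate
    if (collapse == "none") return(m)
    if (collapse == "concatenate") {
        o <- order(tm, rp)
        m <- m[, o, drop = FALSE]
        colnames(m) <- paste0(tm[o], "h.r", rp[o])
        return(m)
    }
    ut <- sort(unique(tm))
    out <- vapply(ut, function(t)
        rowMeans(m[, tm == t, drop = FALSE]), numeric(nrow(m)))
    out <- matrix(out, nrow = nrow(m),
                  dimnames = list(rownames(m), paste0(ut, "h")))
    out
})

#' @rdname accessors
#' @export
setMethod("timepointHours", "ExpressionTimeCourse",
    function(x) sort(unique(SummarizedExperiment::colData(x)$time_h)))

#' @rdname accessors
#' @export
setMethod("networkNodes", "CoexpressionNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("cohortGenes", "CoexpressionNetwork", function(x) x@cohort)

#' @rdname accessors
#' @export
setMethod("growthDays", "GrowthSeries", function(x) x@days)

#' @rdname accessors
#' @param arm \code{"control"} or \code{"stress"}.
#' @param trait \code{"area"} (cm^2) or \code{"height"} (cm).
#' @param stat \code{"mean"} or \code{"sd"}.
#' @export
setMethod("armSeries", "GrowthSeries",
    function(x, arm = c("control", "stress"), trait = c("area", "height"),
             stat = c("mean", "sd")) {
    arm <- match.arg(arm); trait <- match.arg(trait); stat <- match.arg(stat)
    slot(x, paste0(arm, if (trait == "area") "Area" else "Height"))[, stat]
})

#' @rdname accessors
#' @export
setMethod("alleleMatrix", "SyntheticPopulation", function(x) x@alleles)
#' @rdname accessors
#' @export
setMethod("designatedOutliers", "SyntheticPopulation", function(x) x@outliers)
#' @rdname accessors
#' @export
setMethod("populationTraits", "SyntheticPopulation", function(x) x@traits)
#' @rdname accessors
#' @export
setMethod("parentIds", "SyntheticPopulation", function(x) x@parents)

setMethod("show", "TraitMatrix", function(object) {
    v <- object@values
    cat("TraitMatrix:", nrow(v), "genotypes x", ncol(v), "parameters\n")
    cat("  lower-is-better:",
        sum(object@directions == "lower_better"), "parameters;",
        "SES available for", length(object@ses), "genotypes\n")
})

setMethod("show", "ScoreMatrix", function(object) {
    s <- object@scores
    cat("ScoreMatrix:", nrow(s), "genotypes x", ncol(s), "parameters (1-10)\n")
    top <- names(sort(object@aps, decreasing = TRUE))[1]
    cat("  APS range:", round(min(object@aps), 2), "-",
        round(max(object@aps), 2), "; best:", top, "\n")
})

setMethod("show", "ExpressionTimeCourse", function(object) {
    cat("ExpressionTimeCourse (", S4Vectors::metadata(object)$genotype, "): ",
        nrow(object), " genes x ",
        length(timepointHours(object)), " timepoints (",
        paste(timepointHours(object), collapse = ", "), " h)\n", sep = "")
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork:", length(object@nodes), "genes,",
        nrow(object@edges), "edges",
        "(PCC >=", object@pccMin, "; mode:", object@mode, ")\n")
    if (length(object@bait))
        cat("  bait:", object@bait, "- cohort of", length(object@cohort),
            "genes\n")
})

setMethod("show", "GrowthSeries", function(object) {
    cat("GrowthSeries (", object@genotype, "): days ",
        min(object@days), "-", max(object@days), ", ",
        object@nPlants, " plants/arm\n", sep = "")
})

setMethod("show", "SyntheticPopulation", function(object) {
    cat("SyntheticPopulation:", nrow(object@alleles), "genomes (",
        ncol(object@alleles) - 1, "peripheral loci + core )\n")
    cat("  parents:", paste(object@parents, collapse = ", "),
        "| outliers:", paste(names(object@outliers), object@outliers,
                             sep = "=", collapse = ", "), "\n")
})
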