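#' @include AllClasses.R
NULL

#' Accessors for transeg classes
#'
#' @param object,x an object of the documented class.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitValues", function(x) standardGeneric("traitValues"))
#' @rdname accessors
#' @export
setGeneric("traitDirections", function(x) standardGeneric("traitDirections"))
#' @rdname accessors
#' @export
setGeneric("sesScores", function(x) standardGeneric("sesScores"))
#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setGeneric("apsScores", function(x) standardGeneric("apsScores"))
#' @rdname accessors
#' @export
setGeneric("sesInverted", function(x) standardGeneric("sesInverted"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("timepointHours", function(x) standardGeneric("timepointHours"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("cohortGenes", function(x) standardGeneric("cohortGenes"))
#' @rdname accessors
#' @export
setGeneric("growthDays", function(x) standardGeneric("growthDays"))
#' @rdname accessors
#' @export
setGeneric("armSeries", function(x, ...) standardGeneric("armSeries"))
#' @rdname accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))
#' @rdname accessors
#' @export
setGeneric("designatedOutliers", function(x) standardGeneric("designatedOutliers"))
#' @rdname accessors
#' @export
setGeneric("populationTraits", function(x) standardGeneric("populationTraits"))
#' @rdname accessors
#' @export
setGeneric("parentIds", function(x) standardGeneric("parentIds"))

#' @rdname scoreTraits
#' @export
setGeneric("scoreTraits", function(x, ...) standardGeneric("scoreTraits"))

#' @rdname traitDistance
#' @export
setGeneric("traitDistance", function(x, ...) standardGeneric("traitDistance"))

#' @rdname pccMatrix
#' @export
setGeneric("pccMatrix", function(x, ...) standardGeneric("pccMatrix"))

#' @rdname buildNetwork
#' @export
setGeneric("buildNetwork", function(x, ...) standardGeneric("buildNetwork"))

#' @rdname detectFork
#' @export
setGeneric("detectFork", function(x, ...) standardGeneric("detectFork"))

#' @rdname forkAngle
#' @export
setGeneric("forkAngle", function(x, ...) standardGeneric("forkAngle"))

#' @rdname psaRatio
#' @export
setGeneric("psaRatio", function(x, ...) standardGeneric("psaRatio"))
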