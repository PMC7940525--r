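#' Min-max normalization onto the 1-10 scoring scale
#'
#' Maps raw values linearly onto [1, 10] so the column maximum scores 10 and
#' the minimum scores 1: \code{y = 1 + (x - A) * (10 - 1) / (B - A)} with
#' \code{A} the minimum and \code{B} the maximum. When the range is
#' degenerate (A = B) every value maps to mid-scale 5.5 with a warning.
#'
#' @param x numeric vector of raw values.
#' @param aMin,bMax scale anchors; default to \code{range(x)}.
#' @return numeric vector of scores in [1, 10].
#' @export
minmaxScore <- function(x, aMin = min(x, na.rm = TRUE),
                        bMax = max(x, na.rm = TRUE)) {
    if (aMin > bMax) stop("aMin must not exceed bMax")
    if (aMin == bMax) {
        warning("degenerate range (min == max); returning mid-scale 5.5")
        return(rep(5.5, length(x)))
    }
    1 + (x - aMin) * (10 - 1) / (bMax - aMin)
}

#' Score a trait matrix and aggregate into APS
#'
#' Normalizes every parameter of a \linkS4class{TraitMatrix} onto the 1-10
#' scale with orientation applied first (lower-is-better parameters are
#' sign-flipped before min-max scaling, so 10 is always the best-performing
#' genotype), then sums the scores per genotype into the Aggregate
#' Phenotypic Score (APS; equal weights by default). When SES ratings are
#' present they are inverted onto 1-10 via [invertSes()] and reported
#' alongside.
#'
#' @param x a \linkS4class{TraitMatrix}.
#' @param weights optional named numeric vector of per-parameter weights
#'   (default: equal weight 1 for every parameter).
#' @param naAction \code{"mean"} (default) gives a genotype missing a
#'   parameter that parameter's cohort mean score (with a warning), keeping
#'   APS comparable across genotypes; \code{"error"} fails instead.
#' @return A \linkS4class{ScoreMatrix}.
#' @rdname scoreTraits
#' @export
setMethod("scoreTraits", "TraitMatrix",
    function(x, weights = NULL, naAction = c("mean", "error")) {
    naAction <- match.arg(naAction)
    v <- traitValues(x)
    dirs <- traitDirections(x)
    if (is.null(weights))
        weights <- setNames(rep(1, ncol(v)), colnames(v))
    if (!all(colnames(v) %in% names(weights)))
        stop("weights must cover every parameter")
    scores <- v
    for (p in colnames(v)) {
        col <- v[, p]
        if (dirs[[p]] == "lower_better") col <- -col
        scores[, p] <- minmaxScore(col)
    }
    if (anyNA(scores)) {
        if (naAction == "error") stop("missing scores and naAction = 'error'")
        warning("missing values replaced by the parameter's cohort mean score")
        for (p in colnames(scores)) {
            na <- is.na(scores[, p])
            if (any(na)) scores[na, p] <- mean(scores[, p], na.rm = TRUE)
        }
    }
    w <- weights[colnames(scores)]
    aps <- setNames(as.vector(scores %*% w), rownames(scores))
    sesInv <- numeric()
    ses <- sesScores(x)
    if (length(ses)) {
        sesInv <- setNames(invertSes(ses), names(ses))
        sesInv <- sesInv[rownames(scores)]
        names(sesInv) <- rownames(scores)
    }
    new("ScoreMatrix", scores = scores, aps = aps, sesInverted = sesInv,
        weights = w)
})

#' Squared Pearson correlation with SES
#'
#' Relates a per-genotype score (e.g. one APS component) to the per-genotype
#' SES-derived score by the squared Pearson correlation coefficient, the
#' scale on which individual physio-morphometric parameters are reported to
#' correlate only mildly with visual injury.
#'
#' @param scores,sesScores numeric vectors over the same genotypes
#'   (length >= 3, finite).
#' @return list with \code{rSquared} and \code{n}. Zero variance in either
#'   vector yields \code{rSquared = NA} with a warning.
#' @export
correlateWithSes <- function(scores, sesScores) {
    if (length(scores) != length(sesScores))
        stop("vectors must have equal length")
    keep <- is.finite(scores) & is.finite(sesScores)
    scores <- scores[keep]; sesScores <- sesScores[keep]
    n <- length(scores)
    if (n < 3) stop("need at least 3 genotypes")
    if (sd(scores) == 0 || sd(sesScores) == 0) {
        warning("zero variance; correlation undefined")
        return(list(rSquared = NA_real_, n = n))
    }
    list(rSquared = cor(scores, sesScores)^2, n = n)
}
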