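#' Pearson correlation matrix of temporal expression profiles
#'
#' Correlates every pair of genes across timepoints. Genes with zero
#' temporal variance carry no correlation signal and are excluded; their ids
#' are recorded in the \code{"dropped"} attribute.
#'
#' @param x an \linkS4class{ExpressionTimeCourse} or a gene x timepoint
#'   numeric matrix (>= 3 timepoints).
#' @param collapse replicate handling for \code{ExpressionTimeCourse} input
#'   (see [exprValues()]); the default correlates timepoint means of
#'   replicates, \code{"concatenate"} is the replicate-aware mode.
#' @return symmetric correlation matrix with unit diagonal, attribute
#'   \code{"dropped"} listing excluded genes.
#' @rdname pccMatrix
#' @export
setMethod("pccMatrix", "ExpressionTimeCourse",
    function(x, collapse = c("replicate_mean", "concatenate")) {
    collapse <- match.arg(collapse)
    pccMatrix(exprValues(x, collapse = collapse))
})

#' @rdname pccMatrix
#' @export
setMethod("pccMatrix", "matrix", function(x, ...) {
    if (ncol(x) < 3) stop("need at least 3 timepoints")
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene", seq_len(nrow(x)))
    sds <- apply(x, 1, sd)
    dropped <- rownames(x)[sds == 0]
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) stop("fewer than 2 genes with temporal variance")
    p <- cor(t(x))
    diag(p) <- 1
    attr(p, "dropped") <- dropped
    p
})

#' Directed co-expression ranks
#'
#' For each gene A, every other gene B is ranked by descending correlation
#' with A; \code{Rank_AtoB} is B's 1-based position in that ordering (ties
#' receive the average fractional rank). The matrix is asymmetric in
#' general: A may be B's closest partner while B is only A's tenth.
#'
#' @param pcc a symmetric correlation matrix from [pccMatrix()]
#'   (>= 2 genes).
#' @return matrix R with \code{R[A, B] = Rank_AtoB} and \code{NA} diagonal.
#' @export
coRanks <- function(pcc) {
    n <- nrow(pcc)
    if (is.null(n) || n < 2) stop("need at least 2 genes")
    R <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
    for (i in seq_len(n)) {
        R[i, -i] <- rank(-pcc[i, -i], ties.method = "average")
    }
    R
}

#' Mutual rank of a gene pair
#'
#' Geometric mean of the two directed co-expression ranks:
#' \code{MR_AB = sqrt(Rank_AtoB * Rank_BtoA)}. Symmetric; small values mean
#' the two genes are mutually each other's closest co-expression partners.
#'
#' @param rankAB,rankBA directed ranks (>= 1).
#' @return mutual rank (>= 1).
#' @export
mutualRank <- function(rankAB, rankBA) {
    if (any(rankAB < 1) || any(rankBA < 1)) stop("ranks must be >= 1")
    sqrt(rankAB * rankBA)
}

#' Mutual-rank matrix from a correlation matrix
#'
#' @param pcc symmetric correlation matrix.
#' @return symmetric MR matrix (NA diagonal).
#' @export
mrMatrix <- function(pcc) {
    R <- coRanks(pcc)
    sqrt(R * t(R))
}

#' Build a thresholded mutual-rank co-expression network
#'
#' Computes the all-pairs PCC and mutual-rank matrices of an expression time
#' course and keeps the edges passing both thresholds. The default mode
#' retains pairs with \code{PCC >= pccMin} and \code{MR <= mrMax}
#' (conventional: a small mutual rank marks strong reciprocal
#' co-expression). The \code{literalMr} mode instead applies the exclusion
#' rule "interactions with values < 10 are excluded" verbatim, i.e. keeps
#' \code{MR >= 10}; the mode used is stamped into the returned object.
#'
#' @param x an \linkS4class{ExpressionTimeCourse} or gene x timepoint
#'   matrix.
#' @param pccMin correlation threshold in (0, 1] (default 0.95).
#' @param mrMax mutual-rank threshold >= 1 (default 10).
#' @param literalMr apply the printed exclusion rule verbatim.
#' @param bait optional bait gene; when given, its cohort is extracted with
#'   [extractCohort()] in \code{cohortMode}.
#' @param cohortMode \code{"component"} (default) or \code{"neighbors"}.
#' @param collapse replicate handling (see [pccMatrix()]).
#' @return A \linkS4class{CoexpressionNetwork}.
#' @rdname buildNetwork
#' @export
setMethod("buildNetwork", "ExpressionTimeCourse",
    function(x, pccMin = 0.95, mrMax = 10, literalMr = FALSE, bait = NULL,
             cohortMode = c("component", "neighbors"),
             collapse = c("replicate_mean", "concatenate")) {
    collapse <- match.arg(collapse)
    buildNetwork(exprValues(x, collapse = collapse), pccMin = pccMin,
                 mrMax = mrMax, literalMr = literalMr, bait = bait,
                 cohortMode = cohortMode)
})

#' @rdname buildNetwork
#' @export
setMethod("buildNetwork", "matrix",
    function(x, pccMin = 0.95, mrMax = 10, literalMr = FALSE, bait = NULL,
             cohortMode = c("component", "neighbors")) {
    cohortMode <- match.arg(cohortMode)
    if (nrow(x) == 0) stop("empty gene set")
    if (pccMin <= 0 || pccMin > 1) stop("pccMin must lie in (0, 1]")
    if (mrMax < 1) stop("mrMax must be >= 1")
    pcc <- pccMatrix(x)
    mr <- mrMatrix(pcc)
    genes <- rownames(pcc)
    n <- length(genes)
    keep <- which(upper.tri(pcc) & pcc >= pccMin &
                  (if (literalMr) mr >= 10 else mr <= mrMax),
                  arr.ind = TRUE)
    edges <- data.frame(gene_a = genes[keep[, 1]], gene_b = genes[keep[, 2]],
                        pcc = pcc[keep], mr = mr[keep],
                        stringsAsFactors = FALSE)
    net <- new("CoexpressionNetwork", nodes = genes, edges = edges,
               bait = character(), cohort = character(),
               pccMin = pccMin, mrMax = mrMax,
               mode = if (literalMr) "literal" else "mr_le_max",
               dropped = attr(pcc, "dropped"))
    if (!is.null(bait)) net <- extractCohort(net, bait, mode = cohortMode)
    net
})

#' Extract the cohort of a bait gene
#'
#' Cohort genes are the co-expressed partners recruited by a bait gene in
#' the thresholded network: by default the connected component containing
#' the bait, or alternatively only the bait's direct neighbors.
#'
#' @param net a \linkS4class{CoexpressionNetwork}.
#' @param bait bait gene id (must be a network node).
#' @param mode \code{"component"} (default) or \code{"neighbors"}.
#' @return the network with \code{bait} and \code{cohort} slots filled; the
#'   cohort always contains the bait itself.
#' @export
extractCohort <- function(net, bait, mode = c("component", "neighbors")) {
    mode <- match.arg(mode)
    if (!bait %in% net@nodes) stop("unknown bait gene: ", bait)
    g <- .asIgraph(net)
    cohort <- if (mode == "component") {
        comp <- igraph::components(g)
        names(comp$membership)[comp$membership ==
                               comp$membership[[bait]]]
    } else {
        union(bait, names(igraph::neighbors(g, bait)))
    }
    net@bait <- bait
    net@cohort <- sort(cohort)
    net
}

.asIgraph <- function(net) {
    igraph::graph_from_data_frame(
        net@edges[, c("gene_a", "gene_b")], directed = FALSE,
        vertices = data.frame(name = net@nodes))
}

#' Cross-genotype similarity of cohort median expression
#'
#' For every genotype, the per-gene median abundance across timepoints is
#' taken over the union of all genotypes' cohort genes (genes absent from a
#' genotype's expression matrix are missing). Genotype-genotype similarity
#' is the Pearson correlation of these median vectors over pairwise-complete
#' genes; a genotype whose networks have been rewired shows depressed
#' correlation with every other genotype.
#'
#' @param cohorts named list (per genotype) of cohort gene id vectors.
#' @param etcs named list (same names) of \linkS4class{ExpressionTimeCourse}
#'   objects or gene x timepoint matrices.
#' @return genotype x genotype correlation matrix.
#' @export
compareMedianExpression <- function(cohorts, etcs) {
    if (length(cohorts) < 2) stop("need at least 2 genotypes")
    if (!setequal(names(cohorts), names(etcs)))
        stop("cohorts and etcs must cover the same genotypes")
    genotypes <- names(cohorts)
    universe <- sort(unique(unlist(cohorts)))
    med <- sapply(genotypes, function(g) {
        m <- etcs[[g]]
        if (is(m, "ExpressionTimeCourse")) m <- exprValues(m)
        out <- setNames(rep(NA_real_, length(universe)), universe)
        have <- intersect(universe, rownames(m))
        out[have] <- apply(m[have, , drop = FALSE], 1, median)
        out
    })
    cor(med, use = "pairwise.complete.obs")
}

#' Shared cohort genes across genotypes
#'
#' Pairwise overlap of cohort membership: the count of shared genes and the
#' Jaccard index. Genotypes with an empty cohort are flagged in the
#' \code{"empty"} attribute (their Jaccard entries are 0) rather than
#' erroring.
#'
#' @param cohorts named list (per genotype) of cohort gene id vectors
#'   (>= 2 genotypes).
#' @return list with \code{counts} and \code{jaccard} genotype x genotype
#'   matrices; attribute \code{"empty"} names flagged genotypes. Group
#'   genotypes on \code{as.dist(1 - jaccard)} for a Fig-7-style dendrogram.
#' @export
sharedCohortMatrix <- function(cohorts) {
    if (length(cohorts) < 2) stop("need at least 2 genotypes")
    g <- names(cohorts)
    n <- length(g)
    counts <- matrix(0L, n, n, dimnames = list(g, g))
    jacc <- matrix(0, n, n, dimnames = list(g, g))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        int <- length(intersect(cohorts[[i]], cohorts[[j]]))
        uni <- length(union(cohorts[[i]], cohorts[[j]]))
        counts[i, j] <- int
        jacc[i, j] <- if (uni == 0) 0 else int / uni
    }
    out <- list(counts = counts, jaccard = jacc)
    attr(out, "empty") <- g[lengths(cohorts) == 0]
    out
}
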