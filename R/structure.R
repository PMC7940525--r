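#' Euclidean distance between genotypes on the score matrix
#'
#' Distances are computed on the normalized 1-10 score columns (optionally a
#' subset, e.g. the salt-exclusion components) so every parameter enters on
#' a common scale.
#'
#' @param x a \linkS4class{ScoreMatrix} or a plain numeric matrix
#'   (items x features).
#' @param subset optional character vector of parameter names to restrict to.
#' @return a \code{dist} object (symmetric, zero diagonal).
#' @rdname traitDistance
#' @export
setMethod("traitDistance", "ScoreMatrix", function(x, subset = NULL) {
    traitDistance(scoreValues(x), subset = subset)
})

#' @rdname traitDistance
#' @export
setMethod("traitDistance", "matrix", function(x, subset = NULL) {
    if (nrow(x) < 2) stop("need at least 2 genotypes")
    if (!is.null(subset)) {
        unknown <- setdiff(subset, colnames(x))
        if (length(unknown))
            stop("unknown parameter(s) in subset: ",
                 paste(unknown, collapse = ", "))
        x <- x[, subset, drop = FALSE]
    }
    dist(x)
})

#' Build a genotype dendrogram
#'
#' Agglomerative clustering (average or complete linkage, the default family
#' whose bootstrap-support semantics match column resampling) or
#' neighbor-joining. Rows/columns of the distance matrix are put in
#' lexicographic label order first so the topology does not depend on input
#' order.
#'
#' @param d a \code{dist} or symmetric distance matrix with labels.
#' @param method \code{"average"} (default), \code{"complete"} or \code{"nj"}.
#' @return an \code{ape} \code{phylo} tree (rooted for the agglomerative
#'   methods, unrooted for NJ). Serialize with [writeNewick()].
#' @export
buildTree <- function(d, method = c("average", "complete", "nj")) {
    method <- match.arg(method)
    m <- as.matrix(d)
    if (!isSymmetric(unname(m), tol = 1e-8))
        stop("distance matrix must be symmetric")
    if (is.null(rownames(m)))
        rownames(m) <- colnames(m) <- paste0("g", seq_len(nrow(m)))
    o <- order(rownames(m))
    m <- m[o, o, drop = FALSE]
    if (method == "nj") {
        if (nrow(m) < 3) stop("neighbor-joining needs at least 3 genotypes")
        ape::nj(as.dist(m))
    } else {
        ape::as.phylo(hclust(as.dist(m), method = method))
    }
}

#' Bootstrap support for a genotype dendrogram
#'
#' Resamples parameter columns with replacement (the resampling unit used by
#' pvclust-style phenotype clustering), rebuilds the tree for each resample,
#' and reports for each internal node of the original tree the percentage of
#' bootstrap trees containing the same leaf bipartition (BP).
#'
#' @param x a \linkS4class{ScoreMatrix} or items x features numeric matrix.
#' @param subset optional parameter subset (see [traitDistance()]).
#' @param nBoot number of bootstrap resamples (>= 100).
#' @param method linkage passed to [buildTree()].
#' @param seed integer seed; results are reproducible given the seed.
#' @return list of class \code{"BootstrapDendrogram"}: \code{tree} (phylo
#'   with BP percentages as node labels), \code{bp} (numeric per internal
#'   node), \code{nBoot}, \code{method}.
#' @export
bootstrapSupport <- function(x, subset = NULL, nBoot = 1000,
                             method = c("average", "complete", "nj"),
                             seed = 1) {
    method <- match.arg(method)
    if (nBoot < 100) stop("nBoot must be at least 100")
    m <- if (is(x, "ScoreMatrix")) scoreValues(x) else as.matrix(x)
    if (!is.null(subset)) {
        unknown <- setdiff(subset, colnames(m))
        if (length(unknown))
            stop("unknown parameter(s) in subset: ",
                 paste(unknown, collapse = ", "))
        m <- m[, subset, drop = FALSE]
    }
    if (ncol(m) < 2) stop("need at least 2 parameters to resample")
    tree <- buildTree(dist(m), method = method)
    rooted <- method != "nj"
    boots <- local({
        set.seed(seed)
        lapply(seq_len(nBoot), function(b) {
            cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
            buildTree(dist(m[, cols, drop = FALSE]), method = method)
        })
    })
    counts <- ape::prop.clades(tree, boots, rooted = rooted)
    counts[is.na(counts)] <- 0
    bp <- 100 * counts / nBoot
    tree$node.label <- formatC(bp, format = "f", digits = 0)
    structure(list(tree = tree, bp = bp, nBoot = nBoot, method = method),
              class = "BootstrapDendrogram")
}

#' Bootstrap proportion of the bipartition splitting a genotype set
#'
#' Convenience lookup: the BP of the internal node whose leaf set equals
#' \code{group} (or its complement, for unrooted trees), or \code{NA} when no
#' such node exists in the original tree.
#'
#' @param bd a \code{"BootstrapDendrogram"}.
#' @param group character vector of genotype labels.
#' @return BP percentage or NA.
#' @export
cladeSupport <- function(bd, group) {
    tree <- bd$tree
    tips <- tree$tip.label
    n <- length(tips)
    ids <- seq_len(tree$Nnode) + n
    for (i in seq_along(ids)) {
        clade <- tips[unlist(.cladeTips(tree, ids[i]))]
        if (setequal(clade, group) ||
            (bd$method == "nj" && setequal(setdiff(tips, clade), group)))
            return(bd$bp[i])
    }
    NA_real_
}

.cladeTips <- function(tree, node) {
    n <- length(tree$tip.label)
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, .cladeTips, tree = tree))
}

#' Principal component analysis with fixed sign convention
#'
#' Thin wrapper around the standard singular-value decomposition PCA that
#' reports percent variance explained (summing to 100 over all components)
#' and fixes component signs so the largest-magnitude loading of each
#' component is positive.
#'
#' @param x items x features numeric matrix (>= 2 items, >= 2 features,
#'   finite).
#' @param center,scale. passed to [stats::prcomp()]; scaling a constant
#'   feature is refused with an error naming the feature.
#' @return list with \code{scores}, \code{loadings},
#'   \code{varianceExplained} (percent) and \code{sdev}.
#' @export
pcaAnalysis <- function(x, center = TRUE, scale. = FALSE) {
    x <- as.matrix(x)
    if (nrow(x) < 2 || ncol(x) < 2)
        stop("need at least 2 items and 2 features")
    if (any(!is.finite(x))) stop("non-finite entries")
    if (scale.) {
        sds <- apply(x, 2, sd)
        if (any(sds == 0))
            stop("constant feature(s) cannot be scaled: ",
                 paste(colnames(x)[sds == 0], collapse = ", "))
    }
    p <- prcomp(x, center = center, scale. = scale.)
    flip <- apply(p$rotation, 2, function(l) sign(l[which.max(abs(l))]) < 0)
    p$rotation[, flip] <- -p$rotation[, flip, drop = FALSE]
    p$x[, flip] <- -p$x[, flip, drop = FALSE]
    ve <- 100 * p$sdev^2 / sum(p$sdev^2)
    list(scores = p$x, loadings = p$rotation, varianceExplained = ve,
         sdev = p$sdev)
}

#' K-means clustering with k-means++ seeding
#'
#' Lloyd's algorithm initialized by the k-means++ rule (first center uniform,
#' subsequent centers sampled with probability proportional to squared
#' distance from the nearest chosen center), run for several seeded restarts
#' with the best solution kept by within-cluster sum of squares (inertia).
#' The per-iteration inertia trajectory is recorded; it is non-increasing by
#' construction of the Lloyd updates.
#'
#' @param x items x features numeric matrix.
#' @param k number of clusters (1 <= k <= number of items).
#' @param nRestarts independent seeded restarts (default 10).
#' @param seed integer seed.
#' @param maxIter Lloyd iteration cap (default 300).
#' @param tol convergence threshold on the maximum center shift
#'   (default 1e-8).
#' @return list of class \code{"ClusterAssignment"}: \code{k}, \code{labels}
#'   (1..k per item), \code{centers} (k x features), \code{inertia},
#'   \code{inertiaTrace} (per Lloyd iteration of the winning restart),
#'   \code{iterations}.
#' @export
kmeansPP <- function(x, k, nRestarts = 10, seed = 1, maxIter = 300,
                     tol = 1e-8) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (k > n) stop("k must not exceed the number of items")
    if (k < 1) stop("k must be at least 1")
    if (any(!is.finite(x))) stop("features must be finite")
    set.seed(seed)
    best <- NULL
    for (r in seq_len(nRestarts)) {
        fit <- .lloyd(x, .kppInit(x, k), maxIter, tol)
        if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    best$k <- k
    class(best) <- "ClusterAssignment"
    best
}

.kppInit <- function(x, k) {
    n <- nrow(x)
    centers <- x[sample.int(n, 1), , drop = FALSE]
    while (nrow(centers) < k) {
        d2 <- .minDist2(x, centers)
        if (sum(d2) == 0)
            idx <- sample.int(n, 1)
        else
            idx <- sample.int(n, 1, prob = d2)
        centers <- rbind(centers, x[idx, , drop = FALSE])
    }
    unname(centers)
}

.minDist2 <- function(x, centers) {
    d2 <- .dist2(x, centers)
    if (ncol(d2) == 1) d2[, 1] else apply(d2, 1, min)
}

# squared Euclidean distances, items x centers
.dist2 <- function(x, centers) {
    xs <- rowSums(x^2)
    cs <- rowSums(centers^2)
    d2 <- outer(xs, cs, "+") - 2 * x %*% t(centers)
    pmax(d2, 0)
}

.lloyd <- function(x, centers, maxIter, tol) {
    trace <- numeric()
    labels <- NULL
    for (it in seq_len(maxIter)) {
        d2 <- .dist2(x, centers)
        labels <- max.col(-d2, ties.method = "first")
        trace <- c(trace, sum(d2[cbind(seq_len(nrow(x)), labels)]))
        newCenters <- centers
        for (j in seq_len(nrow(centers))) {
            members <- labels == j
            if (any(members))
                newCenters[j, ] <- colMeans(x[members, , drop = FALSE])
            else  # empty cluster: reseed at the point farthest from its center
                newCenters[j, ] <- x[which.max(.minDist2(x, centers)), ]
        }
        shift <- max(abs(newCenters - centers))
        centers <- newCenters
        if (shift < tol) break
    }
    d2 <- .dist2(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- sum(d2[cbind(seq_len(nrow(x)), labels)])
    list(labels = labels, centers = centers, inertia = inertia,
         inertiaTrace = trace, iterations = length(trace))
}

#' Log-transform and standardize a metabolite abundance matrix
#'
#' Default preprocessing before k-means/PCA structure analysis:
#' \code{log2(x + 1)} to tame the dynamic range of abundances, then
#' feature-wise standardization (zero mean, unit sd; constant features are
#' left centered only).
#'
#' @param x items x features abundance matrix (non-negative).
#' @param log2Transform,standardize toggles for the two steps.
#' @return transformed matrix.
#' @export
prepareAbundance <- function(x, log2Transform = TRUE, standardize = TRUE) {
    x <- as.matrix(x)
    if (log2Transform) {
        if (any(x < 0)) stop("abundances must be non-negative for log2(x + 1)")
        x <- log2(x + 1)
    }
    if (standardize) {
        mu <- colMeans(x)
        sds <- apply(x, 2, sd)
        sds[sds == 0] <- 1
        x <- sweep(sweep(x, 2, mu), 2, sds, "/")
    }
    x
}

#' Pre-filter features by a stress-vs-control t-test
#'
#' Thin utility reproducing the routine differential-abundance screen
#' (two-sided Welch t-test per feature, raw p < alpha).
#'
#' @param control,stress feature x replicate matrices with matching rownames.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of feature names passing the screen.
#' @export
prefilterDifferential <- function(control, stress, alpha = 0.05) {
    if (!identical(rownames(control), rownames(stress)))
        stop("control and stress must share feature rownames")
    p <- vapply(seq_len(nrow(control)), function(i) {
        a <- control[i, ]; b <- stress[i, ]
        if (sd(a) == 0 && sd(b) == 0) return(1)
        stats::t.test(a, b)$p.value
    }, numeric(1))
    rownames(control)[p < alpha]
}
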