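test_that("trait distances are Euclidean on the selected score columns", {
    m <- matrix(c(1, 1, 4, 1, 1, 1), 3, 2,
                dimnames = list(c("a", "b", "c"), c("p", "q")))
    d <- as.matrix(traitDistance(m))
    expect_equal(d["a", "b"], 0)          # identical rows
    expect_equal(d["a", "c"], 3)          # single-column difference of 3
    expect_equal(unname(diag(d)), rep(0, 3))
    expect_true(isSymmetric(d))
    expect_error(traitDistance(m, subset = "zz"), "unknown")
    dsub <- as.matrix(traitDistance(m, subset = "q"))
    expect_false(identical(d, dsub))
    # triangle inequality on random matrices
    set.seed(2)
    r <- matrix(rnorm(24), 6)
    rownames(r) <- paste0("g", 1:6)
    dm <- as.matrix(traitDistance(r))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
        expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
})

test_that("tree building joins the closest pair and ignores input order", {
    d <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- buildTree(d, "average")
    # A and B must form a cherry
    cherry <- ape::prop.part(tr)
    sizes <- lengths(cherry)
    pair <- cherry[[which(sizes == 2)]]
    expect_setequal(tr$tip.label[pair], c("A", "B"))
    # permuting the input leaves the topology unchanged
    perm <- c("C", "A", "B")
    tr2 <- buildTree(d[perm, perm], "average")
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
                 ignore_attr = TRUE)
    expect_error(buildTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ and average linkage agree on ultrametric input", {
    lab <- c("A", "B", "C", "D")
    d <- matrix(6, 4, 4, dimnames = list(lab, lab))
    d["A", "B"] <- d["B", "A"] <- 2
    d["C", "D"] <- d["D", "C"] <- 3
    diag(d) <- 0
    tnj <- buildTree(d, "nj")
    tav <- buildTree(d, "average")
    expect_equal(ape::dist.topo(ape::unroot(tnj), ape::unroot(tav)), 0,
                 ignore_attr = TRUE)
    # exhaustive check: of the 3 unrooted 4-leaf topologies, AB|CD is chosen
    split <- ape::prop.part(ape::unroot(tnj))
    expect_true(any(vapply(split, function(p)
        setequal(tnj$tip.label[p], c("A", "B")) ||
        setequal(tnj$tip.label[p], c("C", "D")), logical(1))))
})

test_that("bootstrap support is high for well-separated planted clusters", {
    set.seed(10)
    base <- matrix(rnorm(8 * 6, sd = 0.5), 8, 6,
                   dimnames = list(paste0("g", 1:8), paste0("p", 1:6)))
    base[1:4, ] <- base[1:4, ] + 10   # between/within ratio >= 10
    bd <- bootstrapSupport(base, nBoot = 200, seed = 3)
    expect_gte(cladeSupport(bd, paste0("g", 1:4)), 95)
    bd2 <- bootstrapSupport(base, nBoot = 200, seed = 3)
    expect_identical(bd$bp, bd2$bp)
    # row order must not matter
    bd3 <- bootstrapSupport(base[sample(1:8), ], nBoot = 200, seed = 3)
    expect_equal(cladeSupport(bd3, paste0("g", 1:4)),
                 cladeSupport(bd, paste0("g", 1:4)))
    expect_error(bootstrapSupport(base[, 1, drop = FALSE], nBoot = 200),
                 "2 parameters")
    expect_error(bootstrapSupport(base, nBoot = 10), "at least 100")
})

test_that("PCA conserves variance and matches a dense eigensolver", {
    set.seed(4)
    x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
    p <- pcaAnalysis(x)
    expect_equal(sum(p$varianceExplained), 100, tolerance = 1e-9)
    ev <- sort(eigen(cov(x), symmetric = TRUE)$values, decreasing = TRUE)
    expect_equal(p$sdev^2, ev, tolerance = 1e-10)
    # rank-1 data: PC1 carries everything
    r1 <- cbind(a = 1:6, b = 2 * (1:6))
    pr <- pcaAnalysis(r1)
    expect_equal(pr$varianceExplained[1], 100, tolerance = 1e-9)
    # fixed sign convention: dominant loading positive
    expect_true(all(apply(p$loadings, 2, function(l)
        l[which.max(abs(l))] > 0)))
    xc <- cbind(x, flat = 1)
    expect_error(pcaAnalysis(xc, scale. = TRUE), "flat")
})

test_that("k-means++ recovers planted blobs and tracks inertia", {
    set.seed(6)
    blob <- function(cx, cy) cbind(rnorm(20, cx, 0.5), rnorm(20, cy, 0.5))
    x <- rbind(blob(0, 0), blob(10, 0), blob(0, 10))  # 10 sigma apart
    truth <- rep(1:3, each = 20)
    fit <- kmeansPP(x, 3, seed = 2)
    tab <- table(fit$labels, truth)
    expect_equal(sum(apply(tab, 2, max)), 60)  # perfect up to permutation
    expect_true(all(diff(fit$inertiaTrace) <= 1e-9))
    # agreement with the reference implementation's optimum
    ref <- stats::kmeans(x, 3, nstart = 10)
    expect_equal(fit$inertia, ref$tot.withinss, tolerance = 1e-6)
    # degenerate cases
    expect_equal(kmeansPP(x, nrow(x), seed = 1)$inertia, 0, tolerance = 1e-9)
    one <- kmeansPP(x, 1, seed = 1)
    expect_equal(as.vector(one$centers), unname(colMeans(x)))
    expect_error(kmeansPP(x, nrow(x) + 1, seed = 1), "exceed")
})

test_that("abundance preprocessing and the t-test screen behave", {
    m <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(NULL, c("f1", "f2")))
    lt <- prepareAbundance(m, standardize = FALSE)
    expect_equal(lt[, "f1"], c(0, 1))
    st <- prepareAbundance(m)
    expect_equal(unname(colMeans(st)), c(0, 0))
    set.seed(8)
    ctl <- matrix(rnorm(40), 4, 10,
                  dimnames = list(paste0("m", 1:4), NULL))
    str <- ctl
    str["m2", ] <- str["m2", ] + 5
    hits <- prefilterDifferential(ctl, str + matrix(rnorm(40, 0, 0.1), 4))
    expect_true("m2" %in% hits)
})
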