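test_that("PCC matrices are exact on duplicated and negated genes", {
    m <- rbind(a = c(1, 3, 2, 5, 4),
               b = c(1, 3, 2, 5, 4),
               c = -c(1, 3, 2, 5, 4),
               d = c(2, 2, 9, 1, 7))
    p <- pccMatrix(m)
    expect_equal(p["a", "b"], 1)
    expect_equal(p["a", "c"], -1)
    expect_true(isSymmetric(p))
    expect_equal(unname(diag(p)), rep(1, 4))
    expect_true(all(p >= -1 - 1e-12 & p <= 1 + 1e-12))
    expect_error(pccMatrix(m[, 1:2]), "3 timepoints")
    mz <- rbind(m, flat = rep(3, 5))
    pz <- pccMatrix(mz)
    expect_equal(attr(pz, "dropped"), "flat")
    expect_false("flat" %in% rownames(pz))
})

test_that("PCC matches the brute-force sum formula on a hand table", {
    m <- rbind(g1 = c(2.0, 3.1, 4.2, 5.0, 7.9),
               g2 = c(1.0, 0.9, 2.2, 3.8, 3.5),
               g3 = c(9.0, 7.2, 6.5, 3.3, 1.0),
               g4 = c(0.5, 4.4, 1.1, 2.2, 6.0))
    p <- pccMatrix(m)
    b <- brutePccMatrix(m)
    expect_lt(max(abs(p - b)), 1e-12)
})

test_that("directed ranks follow descending-PCC enumeration with tie averages", {
    # 3-gene matrix with distinct correlations, enumerable by hand
    p <- matrix(c(1, 0.9, 0.2,
                  0.9, 1, 0.5,
                  0.2, 0.5, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    R <- coRanks(p)
    expect_equal(R["A", "B"], 1)  # B is A's top partner
    expect_equal(R["A", "C"], 2)
    expect_equal(R["B", "A"], 1)
    expect_equal(R["B", "C"], 2)
    expect_equal(R["C", "B"], 1)
    expect_equal(R["C", "A"], 2)
    # ties share the average rank
    pt <- matrix(c(1, 0.7, 0.7,
                   0.7, 1, 0.1,
                   0.7, 0.1, 1), 3, 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    Rt <- coRanks(pt)
    expect_equal(Rt["A", "B"], 1.5)
    expect_equal(Rt["A", "C"], 1.5)
    expect_error(coRanks(p[1, 1, drop = FALSE]), "2 genes")
})

test_that("mutual rank is the geometric mean of directed ranks", {
    expect_equal(mutualRank(1, 1), 1)
    expect_equal(mutualRank(4, 9), 6)
    expect_equal(mutualRank(2, 3), sqrt(6))
    expect_equal(mutualRank(5, 2), mutualRank(2, 5))
    expect_error(mutualRank(0.5, 2), ">= 1")
})

test_that("MR matrices are symmetric with rank-law bounds", {
    set.seed(13)
    for (i in 1:5) {
        n <- sample(4:12, 1)
        m <- matrix(rnorm(n * 6), n)
        rownames(m) <- paste0("g", seq_len(n))
        mr <- mrMatrix(pccMatrix(m))
        expect_equal(mr, t(mr))
        off <- mr[upper.tri(mr)]
        expect_true(all(off >= 1 - 1e-12 & off <= n - 1 + 1e-12))
    }
})

test_that("network building equals brute-force thresholding", {
    m <- plantedPairMatrix(nNoise = 10, seed = 3)
    net <- buildNetwork(m, pccMin = 0.95, mrMax = 10)
    expect_identical(edgeKeys(net), bruteEdges(m, 0.95, 10))
    e <- networkEdges(net)
    pair <- e[e$gene_a %in% c("sig1", "sig2") &
              e$gene_b %in% c("sig1", "sig2"), ]
    expect_equal(nrow(pair), 1)
    expect_equal(pair$mr, 1)   # mutually top-ranked planted pair
    # literal exclusion mode keeps only MR >= 10 and is stamped
    lit <- buildNetwork(m, pccMin = 0.3, mrMax = 10, literalMr = TRUE)
    expect_identical(edgeKeys(lit), bruteEdges(m, 0.3, 10, literal = TRUE))
    expect_equal(lit@mode, "literal")
    if (nrow(networkEdges(lit))) expect_true(all(networkEdges(lit)$mr >= 10))
    # a perfect threshold on noisy data leaves no edges
    set.seed(14)
    noise <- matrix(rnorm(40), 8)
    rownames(noise) <- paste0("n", 1:8)
    expect_equal(nrow(networkEdges(buildNetwork(noise, pccMin = 1))), 0)
    expect_error(buildNetwork(noise[0, , drop = FALSE]), "empty")
})

test_that("adding a background gene can break an MR edge but not the PCC", {
    a <- c(1, 2, 3, 4, 5)
    b <- a + c(0, 0, 0, 0, 0.3)
    x <- a + c(0.1, 0, 0, 0, 0)
    m2 <- rbind(A = a, B = b)
    m3 <- rbind(A = a, B = b, X = x)
    expect_equal(pccMatrix(m3)["A", "B"], pccMatrix(m2)["A", "B"])
    expect_gt(pccMatrix(m3)["A", "X"], pccMatrix(m3)["A", "B"])
    mrMax <- 1.2
    before <- buildNetwork(m2, pccMin = 0.9, mrMax = mrMax)
    after <- buildNetwork(m3, pccMin = 0.9, mrMax = mrMax)
    expect_true("A B" %in% edgeKeys(before))
    expect_false("A B" %in% edgeKeys(after))  # rank_AtoB became 2
})

test_that("cohort extraction walks components or neighborhoods", {
    edges <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                        pcc = c(0.99, 0.99), mr = c(1, 1))
    net <- new("CoexpressionNetwork",
               nodes = c("a", "b", "c", "lone"), edges = edges,
               bait = character(), cohort = character(),
               pccMin = 0.95, mrMax = 10, mode = "mr_le_max",
               dropped = character())
    expect_setequal(cohortGenes(extractCohort(net, "a")), c("a", "b", "c"))
    expect_setequal(cohortGenes(extractCohort(net, "a", "neighbors")),
                    c("a", "b"))
    expect_setequal(cohortGenes(extractCohort(net, "lone")), "lone")
    expect_error(extractCohort(net, "zz"), "unknown bait")
})

test_that("planted cohorts are recovered through the full network path", {
    coh <- list(BAIT = sprintf("c%02d", 1:20))
    etc <- simulateExpression("g", coh, nBackground = 25, seed = 21)
    net <- buildNetwork(etc, bait = "BAIT")
    got <- cohortGenes(net)
    planted <- c("BAIT", coh$BAIT)
    expect_gte(length(intersect(got, planted)), 18)
    expect_gte(jaccard(got, planted), 0.9)
})

test_that("median-expression and shared-cohort similarity expose rewiring", {
    cohA <- list(B1 = sprintf("s%02d", 1:10))
    cohR <- list(B2 = sprintf("r%02d", 1:10))
    bg <- sprintf("bg%02d", 1:10)
    uni <- c("B1", "B2", unlist(cohA), unlist(cohR), bg)
    mk <- function(g, coh, seed) simulateExpression(
        g, coh, backgroundGenes = setdiff(uni, c(names(coh),
                                                 unlist(coh))),
        seed = seed)
    etcs <- list(g1 = mk("g1", cohA, 1), g2 = mk("g2", cohA, 2),
                 g3 = mk("g3", cohR, 3))
    cohorts <- list(g1 = c("B1", cohA$B1), g2 = c("B1", cohA$B1),
                    g3 = c("B2", cohR$B2))
    mc <- compareMedianExpression(cohorts, etcs)
    expect_equal(unname(diag(mc)), rep(1, 3))
    off <- function(g) mean(mc[g, setdiff(colnames(mc), g)])
    expect_true(off("g3") < off("g1") && off("g3") < off("g2"))
    # identical expression implies unit correlation
    etcs2 <- list(g1 = etcs$g1, g2 = etcs$g1)
    mc2 <- compareMedianExpression(cohorts[c("g1", "g2")], etcs2)
    expect_equal(mc2["g1", "g2"], 1)
    expect_error(compareMedianExpression(cohorts["g1"], etcs["g1"]),
                 "2 genotypes")
})

test_that("shared-cohort counts and Jaccard follow set arithmetic", {
    sh <- sharedCohortMatrix(list(x = c("a", "b", "c"), y = c("b", "c", "d")))
    expect_equal(sh$counts["x", "y"], 2)
    expect_equal(sh$jaccard["x", "y"], 0.5)
    dis <- sharedCohortMatrix(list(x = c("a", "b"), y = c("c", "d")))
    expect_equal(dis$counts["x", "y"], 0)
    expect_equal(dis$jaccard["x", "y"], 0)
    same <- sharedCohortMatrix(list(x = letters[1:12], y = letters[1:12]))
    expect_equal(same$counts["x", "y"], 12)
    expect_equal(same$jaccard["x", "y"], 1)
    emp <- sharedCohortMatrix(list(x = character(), y = c("a")))
    expect_equal(attr(emp, "empty"), "x")
})

test_that("genotypes with disjoint planted cohorts share no cohort genes", {
    cohA <- list(B1 = sprintf("a%02d", 1:8))
    cohB <- list(B2 = sprintf("b%02d", 1:8))
    uni <- c("B1", "B2", unlist(cohA), unlist(cohB))
    eA <- simulateExpression("gA", cohA, seed = 4,
                             backgroundGenes = setdiff(uni, c("B1", cohA$B1)))
    eB <- simulateExpression("gB", cohB, seed = 5,
                             backgroundGenes = setdiff(uni, c("B2", cohB$B2)))
    cA <- cohortGenes(buildNetwork(eA, bait = "B1"))
    cB <- cohortGenes(buildNetwork(eB, bait = "B2"))
    # planted membership is disjoint; only chance background attachment at
    # most could overlap, and those genes are never planted cohort members
    sh <- sharedCohortMatrix(list(gA = intersect(cA, c("B1", cohA$B1)),
                                  gB = intersect(cB, c("B2", cohB$B2))))
    expect_equal(sh$counts["gA", "gB"], 0)
})
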