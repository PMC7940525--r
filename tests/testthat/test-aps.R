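test_that("minmax scoring pins the endpoints and midpoint", {
    x <- c(3, 7, 12, 5)
    s <- minmaxScore(x)
    expect_equal(s[which.max(x)], 10)
    expect_equal(s[which.min(x)], 1)
    expect_equal(minmaxScore((3 + 12) / 2, 3, 12), 5.5)
    expect_error(minmaxScore(1, aMin = 2, bMax = 1), "aMin")
    expect_warning(deg <- minmaxScore(c(4, 4)), "degenerate")
    expect_equal(deg, c(5.5, 5.5))
})

test_that("minmax scoring is invariant under positive affine rescaling", {
    set.seed(5)
    for (i in 1:20) {
        x <- rnorm(8)
        c0 <- runif(1, 0.1, 10); d0 <- rnorm(1, 0, 5)
        expect_equal(minmaxScore(c0 * x + d0), minmaxScore(x))
    }
})

mkTm <- function(values, directions, ses = numeric()) {
    TraitMatrix(values, directions, ses = ses)
}

test_that("trait scoring orients parameters so 10 is always best", {
    v <- matrix(c(1, 4, 2, 9), 2, 2,
                dimnames = list(c("gA", "gB"), c("up", "dn")))
    tm <- mkTm(v, c(up = "higher_better", dn = "lower_better"))
    sm <- scoreTraits(tm)
    expect_equal(scoreValues(sm)["gB", "up"], 10)
    expect_equal(scoreValues(sm)["gA", "up"], 1)
    # lower-is-better: the smallest raw value scores 10
    expect_equal(scoreValues(sm)["gA", "dn"], 10)
    expect_equal(scoreValues(sm)["gB", "dn"], 1)
    expect_equal(unname(apsScores(sm)), c(11, 11))
})

test_that("APS is a per-genotype sum with known degenerate behavior", {
    v <- matrix(c(1, 4, 7, 2, 9, 3), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("p1", "p2")))
    dirs <- c(p1 = "higher_better", p2 = "higher_better")
    sm <- scoreTraits(mkTm(v, dirs))
    # adding a constant parameter adds exactly 5.5 to every APS
    v2 <- cbind(v, p3 = 4)
    sm2 <- suppressWarnings(
        scoreTraits(mkTm(v2, c(dirs, p3 = "higher_better"))))
    expect_equal(apsScores(sm2), apsScores(sm) + 5.5)
    # permutation equivariance over genotypes
    perm <- c("g3", "g1", "g2")
    smp <- scoreTraits(mkTm(v[perm, ], dirs))
    expect_equal(apsScores(smp), apsScores(sm)[perm])
    # all-identical genotypes collapse to mid-scale
    veq <- matrix(5, 3, 2, dimnames = dimnames(v))
    smeq <- suppressWarnings(scoreTraits(mkTm(veq, dirs)))
    expect_true(all(scoreValues(smeq) == 5.5))
    expect_equal(unname(apsScores(smeq)), rep(11, 3))
})

test_that("missing trait values are mean-imputed or rejected", {
    v <- matrix(c(1, 4, 7, 2, NA, 3), 3, 2,
                dimnames = list(c("g1", "g2", "g3"), c("p1", "p2")))
    dirs <- c(p1 = "higher_better", p2 = "higher_better")
    expect_error(scoreTraits(mkTm(v, dirs), naAction = "error"), "missing")
    expect_warning(sm <- scoreTraits(mkTm(v, dirs)), "cohort mean")
    got <- scoreValues(sm)["g2", "p2"]
    expect_equal(got, mean(scoreValues(sm)[c("g1", "g3"), "p2"]))
})

test_that("scored matrices carry the inverted SES alongside APS", {
    v <- matrix(c(1, 4, 7), 3, 1,
                dimnames = list(c("g1", "g2", "g3"), "p1"))
    ses <- c(g1 = 9, g2 = 5, g3 = 1.5)
    sm <- scoreTraits(mkTm(v, c(p1 = "higher_better"), ses = ses))
    expect_equal(unname(sesInverted(sm)[c("g1", "g3")]), c(1, 10))
})

test_that("squared SES correlation matches a hand-computed table", {
    expect_equal(correlateWithSes(1:5, 2 * (1:5) + 1)$rSquared, 1)
    # orthogonalized pair: sample correlation zero by construction
    x <- c(-2, -1, 0, 1, 2)
    y <- c(1, -1, 0, -1, 1)
    expect_equal(correlateWithSes(x, y)$rSquared, 0)
    xs <- c(1, 2, 3, 4, 5, 6)
    ys <- c(2.3, 1.9, 3.4, 4.1, 3.9, 5.5)
    got <- correlateWithSes(xs, ys)
    expect_equal(got$n, 6)
    expect_lt(abs(got$rSquared - brutePcc(xs, ys)^2), 1e-12)
    expect_error(correlateWithSes(1:2, 1:2), "3 genotypes")
    expect_warning(flat <- correlateWithSes(c(1, 1, 1), 1:3), "variance")
    expect_true(is.na(flat$rSquared))
})
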