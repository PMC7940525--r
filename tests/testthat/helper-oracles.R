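# Independent brute-force oracles, deliberately written as plain loops over
# textbook formulas so they share no code path with the package.

# Pearson correlation from the sum formula.
brutePcc <- function(a, b) {
    n <- length(a)
    num <- n * sum(a * b) - sum(a) * sum(b)
    den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
    num / den
}

brutePccMatrix <- function(m) {
    n <- nrow(m)
    p <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j) p[i, j] <- brutePcc(m[i, ], m[j, ])
    }
    p
}

# Directed rank of B in A's partner list by counting, average ties.
bruteRank <- function(pcc, i, j) {
    others <- setdiff(seq_len(nrow(pcc)), i)
    higher <- sum(pcc[i, others] > pcc[i, j])
    tied <- sum(pcc[i, others] == pcc[i, j])
    higher + (tied + 1) / 2
}

# All-pairs edge list by direct threshold application.
bruteEdges <- function(m, pccMin, mrMax, literal = FALSE) {
    p <- brutePccMatrix(m)
    n <- nrow(p)
    out <- character()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        mr <- sqrt(bruteRank(p, i, j) * bruteRank(p, j, i))
        ok <- p[i, j] >= pccMin && (if (literal) mr >= 10 else mr <= mrMax)
        if (ok) out <- c(out, paste(sort(c(rownames(p)[i], rownames(p)[j])),
                                    collapse = " "))
    }
    sort(out)
}

edgeKeys <- function(net) {
    e <- networkEdges(net)
    if (!nrow(e)) return(character())
    sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
}

# Trait value by direct summation over allele-effect products.
bruteTraitValue <- function(alleles, model, parameter) {
    pars <- model$parameters
    row <- which(pars$parameter == parameter)
    orient <- if (pars$direction[row] == "higher_better") 1 else -1
    eff <- function(latentEffect) pars$scale[row] * orient * latentEffect
    v <- pars$baseline[row] + eff(model$coreEffect) * alleles[["core"]]
    for (i in seq_along(model$peripheralEffects))
        v <- v + eff(model$peripheralEffects[i]) * alleles[[i + 1]]
    ct <- model$couplingTerms
    for (r in seq_len(nrow(ct)))
        v <- v + eff(ct$effect[r]) * alleles[[ct$locusA[r] + 1]] *
            alleles[[ct$locusB[r] + 1]]
    v
}

# Small expression matrix with a planted perfectly-correlated pair.
plantedPairMatrix <- function(nNoise = 8, seed = 42) {
    set.seed(seed)
    m <- rbind(sig1 = c(1, 3, 4, 7, 9),
               sig2 = 2 * c(1, 3, 4, 7, 9) + 1,
               matrix(rnorm(nNoise * 5), nNoise,
                      dimnames = list(paste0("n", seq_len(nNoise)), NULL)))
    m
}

# GrowthSeries built directly from mean curves (sd 0), for hand-checkable
# fork cases.
growthFromMeans <- function(control, stress, days = seq_along(control),
                            nPlants = 0L) {
    z <- cbind(mean = control, sd = rep(0, length(control)))
    s <- cbind(mean = stress, sd = rep(0, length(stress)))
    h <- cbind(mean = rep(1, length(control)), sd = rep(0, length(control)))
    new("GrowthSeries", genotype = "hand", days = as.integer(days),
        controlArea = z, stressArea = s, controlHeight = h,
        stressHeight = h, nPlants = as.integer(nPlants), metadata = list())
}

# Jaccard index of two sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
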