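#' Default effect model for the coupling-uncoupling simulator
#'
#' Encodes the omnigenic-style genetic architecture the analysis assumes:
#' one large-effect core locus (a Saltol-like Na+-exclusion QTL), many
#' small-effect peripheral loci of which a third are physiological "drags"
#' (negative sign), and epistatic coupling terms -- synergies between the
#' core locus and the strongest beneficial peripheral loci, and drag-drag
#' penalties. Effects are expressed on a latent tolerance scale and mapped
#' onto each physio-morphometric parameter through its baseline, scale and
#' orientation, so one genome produces a full trait matrix.
#'
#' The core effect is fixed at 10x the median peripheral magnitude.
#' Peripheral magnitudes run linearly from 0.1 to 0.3 latent units; every
#' third locus is a drag. Parameter baselines and scales are chosen to give
#' realistic raw ranges (e.g. ELI near 100-250 percent, Na+/K+ near 0.7-1.4).
#'
#' @param nPeripheral number of peripheral loci (default 50).
#' @param noiseSd measurement noise on the latent scale (default 0.15); the
#'   per-parameter noise sd is \code{noiseSd * scale_p}.
#' @param sesNoiseSd rating noise of the visual SES score (default 0.2).
#' @return list of class \code{"EffectModel"} with \code{parameters}
#'   (data.frame: parameter, direction, baseline, scale), \code{coreEffect},
#'   \code{peripheralEffects} (signed), \code{couplingTerms} (data.frame:
#'   locusA, locusB, effect; locus 0 is the core), \code{noiseSd},
#'   \code{sesNoiseSd}.
#' @export
defaultEffectModel <- function(nPeripheral = 50, noiseSd = 0.15,
                               sesNoiseSd = 0.2) {
    pars <- data.frame(
        parameter = c("eli_72", "eli_144", "na_k_144", "na_144", "change_lp",
                      "biomass_ratio", "conductance_ratio", "k_144",
                      "change_pox", "ion_slope"),
        direction = c(rep("lower_better", 5), rep("higher_better", 5)),
        baseline = c(150, 200, 1.2, 3.0, 1.6, 0.8, 0.6, 0.8, 1.3, 0.5),
        scale = c(5, 8, 0.05, 0.12, 0.06, 0.03, 0.03, 0.03, 0.05, 0.02),
        stringsAsFactors = FALSE)
    mag <- seq(0.1, 0.3, length.out = nPeripheral)
    sign <- ifelse(seq_len(nPeripheral) %% 3 == 0, -1, 1)
    pe <- mag * sign
    coreEffect <- 10 * median(mag)
    beneficial <- order(ifelse(pe > 0, pe, -Inf), decreasing = TRUE)
    drags <- which(pe < 0)
    coupling <- data.frame(locusA = integer(), locusB = integer(),
                           effect = numeric())
    nSyn <- min(3, sum(pe > 0))
    if (nSyn > 0)
        coupling <- rbind(coupling,
            data.frame(locusA = 0L, locusB = beneficial[seq_len(nSyn)],
                       effect = 0.2))
    if (length(drags) >= 4)
        coupling <- rbind(coupling,
            data.frame(locusA = drags[c(1, 3)], locusB = drags[c(2, 4)],
                       effect = -0.2))
    model <- list(parameters = pars, coreEffect = coreEffect,
                  peripheralEffects = pe, couplingTerms = coupling,
                  noiseSd = noiseSd, sesNoiseSd = sesNoiseSd)
    class(model) <- "EffectModel"
    .validateEffectModel(model)
    model
}

.validateEffectModel <- function(model) {
    stopifnot(is.data.frame(model$parameters),
              all(c("parameter", "direction", "baseline", "scale") %in%
                  colnames(model$parameters)))
    if (!all(model$parameters$direction %in% .DIRECTIONS))
        stop("unknown parameter direction")
    if (model$noiseSd < 0) stop("noiseSd must be >= 0")
    pe <- model$peripheralEffects
    if (any(abs(pe) > 0 & abs(pe) >= abs(model$coreEffect)))
        stop("peripheral effects must be smaller in magnitude than the core effect")
    invisible(model)
}

#' Simulate homozygous RIL genomes
#'
#' Each locus (core plus peripheral) of each RIL is drawn independently
#' Bernoulli(0.5) for parental origin -- the near-complete shuffling expected
#' of an F8 recombinant inbred population; all loci are homozygous-coded
#' (single 0/1 per locus). The two parents are appended: \code{P1} carries
#' the all-0 genome (sensitive parent) and \code{P2} the all-1 genome
#' (tolerant parent).
#'
#' @param nRil number of RILs (>= 1).
#' @param nPeripheral number of peripheral loci (>= 1).
#' @param seed integer seed (bit-reproducible).
#' @return (nRil + 2) x (1 + nPeripheral) binary matrix; rows are genotype
#'   ids (RIL001... plus P1, P2), column 1 is \code{core}, the rest
#'   \code{pl001}...
#' @export
simulateRilGenomes <- function(nRil, nPeripheral, seed) {
    if (nRil < 1 || nPeripheral < 1)
        stop("nRil and nPeripheral must be positive")
    alleles <- .withSeed(seed,
        matrix(rbinom(nRil * (nPeripheral + 1), 1, 0.5), nrow = nRil))
    alleles <- rbind(alleles,
                     rep(0, nPeripheral + 1),
                     rep(1, nPeripheral + 1))
    rownames(alleles) <- c(sprintf("RIL%03d", seq_len(nRil)), "P1", "P2")
    colnames(alleles) <- c("core", sprintf("pl%03d", seq_len(nPeripheral)))
    alleles
}

#' Simulate a trait matrix from genomes under an effect model
#'
#' For each genotype a latent tolerance value is accumulated over
#' allele-effect products -- core effect, signed peripheral effects, and
#' epistatic coupling terms for co-occurring allele pairs -- and then mapped
#' onto every parameter p as
#' \code{baseline_p + scale_p * orient_p * latent + Normal(0, noiseSd *
#' scale_p)}, with \code{orient_p} +1 for higher-is-better parameters and -1
#' otherwise. SES ratings (1-9, 1 = most tolerant, rounded to the half
#' point) are derived from the noiseless latent values plus rating noise.
#'
#' @param genomes allele matrix as from [simulateRilGenomes()].
#' @param model an \code{"EffectModel"} (see [defaultEffectModel()]).
#' @param seed integer seed.
#' @return A \linkS4class{TraitMatrix} with SES.
#' @export
simulateTraits <- function(genomes, model, seed) {
    .validateEffectModel(model)
    nP <- length(model$peripheralEffects)
    if (ncol(genomes) != nP + 1)
        stop("allele matrix has ", ncol(genomes) - 1,
             " peripheral loci but the model expects ", nP)
    latent <- .latentTolerance(genomes, model)
    pars <- model$parameters
    values <- .withSeed(seed, {
        vapply(seq_len(nrow(pars)), function(j) {
            orient <- if (pars$direction[j] == "higher_better") 1 else -1
            pars$baseline[j] + pars$scale[j] * orient * latent +
                rnorm(length(latent), 0, model$noiseSd * pars$scale[j])
        }, numeric(length(latent)))
    })
    dimnames(values) <- list(rownames(genomes), pars$parameter)
    ses <- .withSeed(seed + 1L, .sesFromLatent(latent, model$sesNoiseSd))
    names(ses) <- rownames(genomes)
    TraitMatrix(values, setNames(pars$direction, pars$parameter), ses = ses)
}

.latentTolerance <- function(genomes, model) {
    latent <- model$coreEffect * genomes[, 1] +
        as.vector(genomes[, -1, drop = FALSE] %*% model$peripheralEffects)
    ct <- model$couplingTerms
    if (!is.null(ct) && nrow(ct)) {
        for (r in seq_len(nrow(ct))) {
            xa <- genomes[, ct$locusA[r] + 1]
            xb <- genomes[, ct$locusB[r] + 1]
            latent <- latent + ct$effect[r] * xa * xb
        }
    }
    unname(latent)
}

.sesFromLatent <- function(latent, sesNoiseSd) {
    rng <- range(latent)
    if (diff(rng) == 0) return(rep(5, length(latent)))
    raw <- 1 + (rng[2] - latent) / diff(rng) * 8 +
        rnorm(length(latent), 0, sesNoiseSd)
    pmin(9, pmax(1, round(raw * 2) / 2))
}

#' Simulate a full RIL population with designated transgressive outliers
#'
#' Draws random RIL genomes, then adds two designed genomes realizing the
#' coupling-uncoupling extremes: the super-tolerant outlier (\code{RIL_ST})
#' carries the core allele and every beneficial peripheral allele while
#' shedding all drags, and the super-sensitive outlier (\code{RIL_SS})
#' stacks every drag while losing the core and all beneficial alleles. By
#' construction the super-tolerant genome scores strictly beyond both
#' parents on every parameter (in expectation; exactly when
#' \code{noiseSd = 0}).
#'
#' @param nRil number of random RILs (default 64, the size of the
#'   representative evaluation group).
#' @param nPeripheral number of peripheral loci (default 50).
#' @param model an \code{"EffectModel"}; defaults to
#'   \code{defaultEffectModel(nPeripheral)}.
#' @param seed integer seed.
#' @return A \linkS4class{SyntheticPopulation}.
#' @export
simulatePopulation <- function(nRil = 64, nPeripheral = 50,
                               model = defaultEffectModel(nPeripheral),
                               seed = 1) {
    alleles <- simulateRilGenomes(nRil, nPeripheral, seed)
    pe <- model$peripheralEffects
    st <- c(1, as.numeric(pe > 0))
    ss <- c(0, as.numeric(pe < 0))
    parents <- alleles[c("P1", "P2"), , drop = FALSE]
    rils <- alleles[setdiff(rownames(alleles), c("P1", "P2")), ,
                    drop = FALSE]
    alleles <- rbind(rils, RIL_ST = st, RIL_SS = ss, parents)
    traits <- simulateTraits(alleles, model, seed = seed + 2L)
    new("SyntheticPopulation", alleles = alleles, traits = traits,
        parents = c("P1", "P2"),
        outliers = c(super_tolerant = "RIL_ST", super_sensitive = "RIL_SS"),
        model = unclass(model), seed = as.integer(seed))
}

#' Growth-simulation settings
#'
#' @param nDays observation window in days (>= 3; default 18, the imaging
#'   period).
#' @param slopeArea,interceptArea linear control growth of projected shoot
#'   area (cm^2/day, cm^2).
#' @param slopeHeight,interceptHeight control growth of plant height
#'   (cm/day, cm).
#' @param forkDay day at which the stress curve starts losing slope
#'   (default 7, when growth retardation first becomes detectable).
#' @param retentionMin post-fork slope retention of a fully sensitive
#'   genotype; retention rises linearly to 1 at tolerance 1.
#' @param noiseSd,noiseSdHeight per-plant measurement noise sd (cm^2, cm).
#' @param nPlants plants per arm (default 5).
#' @return list of class \code{"GrowthConfig"}.
#' @export
growthConfig <- function(nDays = 18, slopeArea = 2, interceptArea = 5,
                         slopeHeight = 0.8, interceptHeight = 10,
                         forkDay = 7, retentionMin = 0.3, noiseSd = 0.15,
                         noiseSdHeight = 0.1, nPlants = 5) {
    if (nDays < 3) stop("nDays must be at least 3")
    structure(list(nDays = nDays, slopeArea = slopeArea,
                   interceptArea = interceptArea, slopeHeight = slopeHeight,
                   interceptHeight = interceptHeight, forkDay = forkDay,
                   retentionMin = retentionMin, noiseSd = noiseSd,
                   noiseSdHeight = noiseSdHeight, nPlants = nPlants),
              class = "GrowthConfig")
}

#' Simulate paired control/stress growth curves
#'
#' Control growth is linear; the stress curve is identical up to the planted
#' fork day, after which its slope is multiplied by a retention fraction
#' that increases linearly with the genotype's tolerance
#' (\code{retention = retentionMin + (1 - retentionMin) * tolerance}), so a
#' fully tolerant genotype (\code{tolerance = 1}) shows no fork at all. The
#' planted fork day is recorded in the metadata as ground truth.
#'
#' @param tolerance genotype tolerance in [0, 1].
#' @param config a \code{"GrowthConfig"} (see [growthConfig()]).
#' @param seed integer seed.
#' @param genotype genotype id stored in the object.
#' @return A \linkS4class{GrowthSeries}.
#' @export
simulateGrowth <- function(tolerance, config = growthConfig(), seed = 1,
                           genotype = "synthetic") {
    stopifnot(inherits(config, "GrowthConfig"))
    if (tolerance < 0 || tolerance > 1)
        stop("tolerance must lie in [0, 1]")
    if (config$forkDay < 1 || config$forkDay > config$nDays)
        stop("fork day outside the observation window")
    retention <- config$retentionMin +
        (1 - config$retentionMin) * tolerance
    days <- seq_len(config$nDays)
    arm <- function(slope, intercept, retained, noise) {
        mu <- ifelse(days <= config$forkDay,
                     intercept + slope * days,
                     intercept + slope * config$forkDay +
                         retained * slope * (days - config$forkDay))
        plants <- matrix(rnorm(length(days) * config$nPlants, 0, noise),
                         nrow = length(days)) + mu
        cbind(mean = rowMeans(plants), sd = apply(plants, 1, sd))
    }
    mats <- .withSeed(seed, list(
        ca = arm(config$slopeArea, config$interceptArea, 1, config$noiseSd),
        sa = arm(config$slopeArea, config$interceptArea, retention,
                 config$noiseSd),
        ch = arm(config$slopeHeight, config$interceptHeight, 1,
                 config$noiseSdHeight),
        sh = arm(config$slopeHeight, config$interceptHeight, retention,
                 config$noiseSdHeight)))
    new("GrowthSeries", genotype = genotype, days = as.integer(days),
        controlArea = mats$ca, stressArea = mats$sa,
        controlHeight = mats$ch, stressHeight = mats$sh,
        nPlants = as.integer(config$nPlants),
        metadata = list(forkDay = config$forkDay, retention = retention,
                        tolerance = tolerance))
}

.BAIT_TEMPLATES <- c("sustained_up", "transient_up", "down", "flat")

.baitProfile <- function(template, t) {
    tmax <- max(t)
    switch(template,
        sustained_up = 3 + 5 * t / tmax,
        transient_up = 3 + 5 * exp(-((t - 36) / 40)^2),
        down = 8 - 5 * t / tmax,
        flat = rep(5, length(t)),
        stop("unknown temporal template: ", template))
}

#' Simulate a bait-cohort expression time course
#'
#' Each bait gene follows one of four named temporal templates
#' (sustained-up, transient-up, down, flat); its cohort genes are
#' \code{loading * bait + Normal(0, sigma)} at every timepoint/replicate,
#' and background genes are independent noise. Cohort membership is planted
#' per genotype (and may differ between genotypes, i.e. rewiring); the
#' planted membership is recorded in the object's metadata as ground truth.
#'
#' @param genotype genotype id.
#' @param cohorts named list: bait gene id -> character vector of cohort
#'   gene ids (each bait needs >= 1 cohort gene).
#' @param nBackground number of independent background genes (ignored when
#'   \code{backgroundGenes} is given).
#' @param backgroundGenes optional explicit background gene ids, so several
#'   genotypes can share one gene universe.
#' @param timepoints sampling times in hours (default 0, 24, 48, 72, 144).
#' @param nReps biological replicates per timepoint (default 3).
#' @param sigma cohort-gene noise sd (default 0.05).
#' @param loading cohort-gene loading on the bait (default 1).
#' @param templates optional named character vector (bait -> template name);
#'   defaults to cycling through sustained-up, transient-up, down.
#' @param seed integer seed.
#' @return An \linkS4class{ExpressionTimeCourse} whose metadata ground truth
#'   holds the planted cohorts and templates.
#' @export
simulateExpression <- function(genotype, cohorts, nBackground = 25,
                               backgroundGenes = NULL,
                               timepoints = c(0, 24, 48, 72, 144),
                               nReps = 3, sigma = 0.05, loading = 1,
                               templates = NULL, seed = 1) {
    if (!length(cohorts) || is.null(names(cohorts)))
        stop("cohorts must be a named list (bait -> cohort genes)")
    if (any(lengths(cohorts) < 1))
        stop("each bait needs at least one cohort gene")
    baits <- names(cohorts)
    if (is.null(backgroundGenes))
        backgroundGenes <- if (nBackground > 0)
            sprintf("BG%04d", seq_len(nBackground)) else character()
    genes <- c(baits, unlist(cohorts, use.names = FALSE), backgroundGenes)
    if (anyDuplicated(genes))
        stop("duplicate gene identifiers")
    if (is.null(templates))
        templates <- setNames(
            rep(c("sustained_up", "transient_up", "down"),
                length.out = length(baits)), baits)
    cols <- expand.grid(rep = seq_len(nReps), time = timepoints)
    nc <- nrow(cols)
    values <- .withSeed(seed, {
        m <- matrix(NA_real_, length(genes), nc,
                    dimnames = list(genes, NULL))
        for (b in baits) {
            mu <- .baitProfile(templates[[b]], cols$time)
            baitVals <- mu + rnorm(nc, 0, sigma)
            m[b, ] <- baitVals
            for (g in cohorts[[b]])
                m[g, ] <- loading * baitVals + rnorm(nc, 0, sigma)
        }
        for (g in backgroundGenes)
            m[g, ] <- rnorm(nc, 5, 1)
        m
    })
    colnames(values) <- paste0("t", cols$time, "_r", cols$rep)
    ExpressionTimeCourse(values, timeH = cols$time, genotype = genotype,
                         replicate = cols$rep,
                         groundTruth = list(cohorts = cohorts,
                                            templates = templates))
}

#' Simulate a hyperspectral pixel-intensity stack
#'
#' Pixel intensities are Normal with a smooth band/day mean surface; under
#' stress the per-band standard deviation is multiplied by
#' \code{stressEffect}, so the stress/control variance ratio equals
#' \code{stressEffect^2}. Band wavelengths are evenly spaced over
#' \code{waveRange} (243 bands over 550-1700 nm by default, a spacing of
#' 1150/242 = 4.75 nm).
#'
#' @param nBands number of wavelength bands (>= 1; default 243).
#' @param nDays number of imaging days (default 18).
#' @param pixelsPerImage pixels per band-day image (>= 2).
#' @param stressEffect multiplicative sd reduction under stress (default
#'   0.7; 1 = no effect).
#' @param waveRange wavelength range in nm (default c(550, 1700)).
#' @param seed integer seed.
#' @return list of class \code{"HyperspectralStack"}: \code{control} and
#'   \code{stress} arrays [band, day, pixel], \code{wavelengths},
#'   \code{stressEffect}.
#' @export
simulateHyperspectral <- function(nBands = 243, nDays = 18,
                                  pixelsPerImage = 200, stressEffect = 0.7,
                                  waveRange = c(550, 1700), seed = 1) {
    if (nBands < 1) stop("nBands must be at least 1")
    if (pixelsPerImage < 2)
        stop("pixelsPerImage must be at least 2 (variance undefined)")
    wl <- if (nBands == 1) waveRange[1]
          else seq(waveRange[1], waveRange[2], length.out = nBands)
    mu <- outer(0.4 + 0.3 * sin(pi * (wl - waveRange[1]) /
                                diff(range(waveRange))),
                0.005 * seq_len(nDays), "+")
    sigma0 <- 0.1
    draw <- function(sd) {
        a <- array(rnorm(nBands * nDays * pixelsPerImage, 0, sd),
                   dim = c(nBands, nDays, pixelsPerImage))
        a <- sweep(a, c(1, 2), mu, "+")
        dimnames(a) <- list(band = format(round(wl, 2)),
                            day = seq_len(nDays), NULL)
        a
    }
    stack <- .withSeed(seed, list(control = draw(sigma0),
                                  stress = draw(sigma0 * stressEffect)))
    structure(list(control = stack$control, stress = stack$stress,
                   wavelengths = wl, stressEffect = stressEffect),
              class = "HyperspectralStack")
}
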