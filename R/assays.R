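#' Electrolyte leakage of a single sample
#'
#' Converts a pair of conductivity readings (before and after boiling the
#' tissue) into a leakage percentage. The universal convention expresses the
#' electrolytes leached into solution as a fraction of the total tissue
#' electrolyte released by boiling, \code{ec_unboiled / ec_boiled * 100},
#' which is bounded by 100 whenever the unboiled reading does not exceed the
#' boiled one. The \code{"literal"} convention returns
#' \code{ec_boiled / ec_unboiled * 100} instead, for workflows that defined
#' EL that way; both conventions agree (= 100) when the two readings are
#' equal.
#'
#' @param ecUnboiled conductivity after leaching, before boiling (> 0; any
#'   consistent unit, e.g. uS/cm).
#' @param ecBoiled conductivity after boiling, i.e. total tissue electrolyte
#'   (> 0, same unit).
#' @param convention \code{"leaked_over_total"} (default) or \code{"literal"}.
#' @return Electrolyte leakage in percent.
#' @export
electrolyteLeakage <- function(ecUnboiled, ecBoiled,
                               convention = c("leaked_over_total", "literal")) {
    convention <- match.arg(convention)
    if (any(ecUnboiled <= 0) || any(ecBoiled <= 0))
        stop("conductivities must be strictly positive")
    if (convention == "leaked_over_total")
        ecUnboiled / ecBoiled * 100
    else
        ecBoiled / ecUnboiled * 100
}

#' Electrolyte Leakage Index
#'
#' ELI relates the leakage at the time of maximum injury (144 h of stress) to
#' the pre-stress leakage: \code{ELI = EL_stress / EL_control * 100}. A value
#' of 100 means no change in membrane integrity; larger values indicate
#' injury.
#'
#' @param elStress electrolyte leakage (percent) under stress.
#' @param elControl electrolyte leakage (percent) at 0 h (> 0).
#' @return The index (percent).
#' @export
eli <- function(elStress, elControl) {
    if (any(elControl <= 0))
        stop("control electrolyte leakage must be strictly positive")
    elStress / elControl * 100
}

#' Malondialdehyde content from TBARS absorbances
#'
#' Applies the Beer-Lambert law \code{C = A / (epsilon * l)} to the
#' background-corrected thiobarbituric-acid absorbance
#' \code{A = A532 - A600}, with the MDA extinction coefficient
#' 155 mM^-1 cm^-1 by default. A negative corrected absorbance (background
#' exceeding signal) is returned as-is with a warning so the raw signal stays
#' available for QC; set \code{clampNegative = TRUE} to truncate at zero.
#'
#' @param a532 absorbance at the TBARS peak (>= 0).
#' @param a600 background absorbance (>= 0).
#' @param pathCm light path length in cm (> 0).
#' @param epsilon extinction coefficient in mM^-1 cm^-1 (> 0; default 155).
#' @param clampNegative truncate negative corrected absorbance at zero.
#' @return MDA content in mM.
#' @export
mdaContent <- function(a532, a600, pathCm = 1, epsilon = 155,
                       clampNegative = FALSE) {
    if (epsilon <= 0 || pathCm <= 0)
        stop("epsilon and pathCm must be strictly positive")
    a <- a532 - a600
    if (any(a < 0)) {
        if (clampNegative) a <- pmax(a, 0)
        else warning("background absorbance exceeds signal (negative A)")
    }
    a / (epsilon * pathCm)
}

#' Ion content from flame photometry
#'
#' Implements the flame-photometry working formula verbatim:
#' \code{reading/100 * standard/100 * digestionVolume * dilutionFactor /
#' dryWeight * 100}. Unit bookkeeping (reading and standard in instrument
#' percent-scale units, digestion volume in mL, dry weight in g) is the
#' caller's responsibility; the result is conventionally reported as percent
#' ion per g dry weight.
#'
#' @param reading instrument reading for the sample.
#' @param standard reading of the calibration standard (> 0).
#' @param digestionVolume volume of digestion solution (mL).
#' @param dilutionFactor dilution applied to the digest.
#' @param dryWeight dry tissue weight in g (> 0).
#' @return Ion content (percent per g dry weight).
#' @export
ionContent <- function(reading, standard, digestionVolume, dilutionFactor,
                       dryWeight) {
    if (any(standard <= 0)) stop("standard must be strictly positive")
    if (any(dryWeight <= 0)) stop("dryWeight must be strictly positive")
    reading / 100 * standard / 100 * digestionVolume * dilutionFactor /
        dryWeight * 100
}

#' Na+/K+ and stress/control ratio indices
#'
#' @param na shoot Na+ content (>= 0).
#' @param k shoot K+ content (> 0).
#' @param stressVal,controlVal paired measurement under stress and control
#'   (controlVal > 0), e.g. shoot biomass.
#' @return list with \code{naK} (Na+/K+), \code{stressControl}
#'   (stress/control) and the interpretive flag \code{growthPenalty}
#'   (\code{TRUE} when stress/control < 1).
#' @export
ratioIndices <- function(na, k, stressVal, controlVal) {
    if (any(k <= 0) || any(controlVal <= 0))
        stop("denominators must be strictly positive")
    sc <- stressVal / controlVal
    list(naK = na / k, stressControl = sc, growthPenalty = sc < 1)
}

#' Fit a linear standard curve
#'
#' Least-squares fit of absorbance on concentration over a set of standards,
#' recording the calibrated concentration range so inverse predictions
#' outside it can be flagged as extrapolations.
#'
#' @param concentration known standard concentrations (>= 2 distinct values).
#' @param absorbance measured absorbances, same length.
#' @return list of class \code{"StandardCurve"} with \code{slope},
#'   \code{intercept} and \code{range}.
#' @export
fitStandardCurve <- function(concentration, absorbance) {
    if (length(concentration) != length(absorbance))
        stop("concentration and absorbance must have equal length")
    if (length(unique(concentration)) < 2)
        stop("need at least 2 distinct standard concentrations")
    fit <- lm(absorbance ~ concentration)
    structure(list(slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]),
                   range = range(concentration)),
              class = "StandardCurve")
}

#' Inverse-predict concentration from a standard curve
#'
#' @param absorbance measured absorbance(s).
#' @param curve a \code{"StandardCurve"} from [fitStandardCurve()].
#' @return Concentration(s) in the units of the standards, with a logical
#'   attribute \code{"extrapolated"} marking values inverse-predicted outside
#'   the calibrated range (also raised as a warning).
#' @export
quantifyFromCurve <- function(absorbance, curve) {
    stopifnot(inherits(curve, "StandardCurve"))
    if (abs(curve$slope) < 1e-12)
        stop("degenerate standard curve (zero slope)")
    conc <- (absorbance - curve$intercept) / curve$slope
    extra <- conc < curve$range[1] | conc > curve$range[2]
    if (any(extra))
        warning("inverse prediction outside the calibrated range (extrapolation)")
    attr(conc, "extrapolated") <- extra
    conc
}

#' Invert SES ratings onto the 1-10 performance scale
#'
#' The Standard Evaluation Score rates visual salinity injury on a 1-9 scale
#' with 1 = most tolerant. To make SES directly proportional to the other
#' phenotypic scores it is mapped onto 1-10 with orientation reversed over
#' the observed cohort range, so the worst genotype (highest SES) scores 1
#' and the best (lowest SES) scores 10 -- the same min-max normalization used
#' for every other APS component.
#'
#' @param ses numeric vector of SES ratings in [1, 9] for the whole cohort.
#' @return numeric vector of inverted scores in [1, 10]; a cohort with a
#'   single distinct rating maps to mid-scale 5.5 with a warning.
#' @export
invertSes <- function(ses) {
    if (any(ses < 1 | ses > 9, na.rm = TRUE))
        stop("SES ratings must lie in [1, 9]")
    minmaxScore(-ses)
}
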