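#' Convert pixel counts to projected area
#'
#' @param pixelCount number of plant pixels (>= 0).
#' @param pixelsPerCm2 calibration scale in pixels per cm^2 (> 0).
#' @return area in cm^2.
#' @export
pixelsToArea <- function(pixelCount, pixelsPerCm2) {
    if (any(pixelsPerCm2 <= 0)) stop("scale must be strictly positive")
    if (any(pixelCount < 0)) stop("pixel counts must be non-negative")
    pixelCount / pixelsPerCm2
}

#' Detect the control-stress fork day
#'
#' Operationalizes the visual "forking" of control and stress growth curves:
#' the fork day is the earliest day on which the control-stress mean
#' difference exceeds \code{kSd} times that day's pooled uncertainty, and
#' (with \code{persist = TRUE}, the default) keeps exceeding it on every
#' later day. The pooled uncertainty is the standard error of the mean
#' difference, \code{sqrt(sd_c^2/n + sd_s^2/n)} with \code{n} plants per
#' arm (raw sds are used when \code{n} is unknown). With noiseless input
#' (all sds zero) any strictly positive divergence forks.
#'
#' @param x a \linkS4class{GrowthSeries} covering >= 4 days.
#' @param kSd threshold multiplier (default 2).
#' @param persist require the divergence to hold on all later days.
#' @param trait \code{"area"} (default) or \code{"height"}.
#' @return list of class \code{"ForkResult"}: \code{forkDay} (NA when the
#'   arms never diverge), \code{forkAngleDeg} (NA without a fork; see
#'   [forkAngle()] for the surrogate definition and its unit dependence),
#'   \code{slopeControl}, \code{slopeStress} (post-fork, units/day),
#'   \code{psaRatio} (per-day stress/control area ratio), \code{trait},
#'   \code{units}, \code{kSd}, \code{persist}.
#' @rdname detectFork
#' @export
setMethod("detectFork", "GrowthSeries",
    function(x, kSd = 2, persist = TRUE, trait = c("area", "height")) {
    trait <- match.arg(trait)
    days <- growthDays(x)
    if (length(days) < 4) stop("need at least 4 days")
    cm <- armSeries(x, "control", trait, "mean")
    sm <- armSeries(x, "stress", trait, "mean")
    sdc <- armSeries(x, "control", trait, "sd")
    sds <- armSeries(x, "stress", trait, "sd")
    n <- x@nPlants
    pooled <- if (n >= 2) sqrt(sdc^2 / n + sds^2 / n)
              else sqrt((sdc^2 + sds^2) / 2)
    diffs <- cm - sm
    exceeds <- diffs > kSd * pooled
    forkDay <- NA_integer_
    if (persist) {
        ok <- rev(cumprod(rev(exceeds))) == 1
        if (any(ok)) forkDay <- days[which(ok)[1]]
    } else if (any(exceeds)) {
        forkDay <- days[which(exceeds)[1]]
    }
    angle <- NA_real_; sc <- NA_real_; ss <- NA_real_
    if (!is.na(forkDay) && sum(days >= forkDay) >= 2) {
        fa <- forkAngle(x, forkDay = forkDay, trait = trait)
        angle <- fa$angleDeg; sc <- fa$slopeControl; ss <- fa$slopeStress
    }
    structure(list(forkDay = forkDay, forkAngleDeg = angle,
                   slopeControl = sc, slopeStress = ss,
                   psaRatio = psaRatio(x), trait = trait,
                   units = if (trait == "area") "cm2/day" else "cm/day",
                   kSd = kSd, persist = persist),
              class = "ForkResult")
})

#' Fork angle between post-fork growth slopes
#'
#' Least-squares slopes are fitted to each arm over the days at and after
#' the fork, and the angle is \code{|atan(slope_control) -
#' atan(slope_stress)|} in degrees. This is a reproducible surrogate for the
#' visually assessed fork angle; because an arctangent of a slope depends on
#' the measurement units, the units are always reported alongside.
#'
#' @param x a \linkS4class{GrowthSeries}.
#' @param forkDay day from which slopes are fitted (>= 2 observed days at or
#'   after it).
#' @param trait \code{"area"} or \code{"height"}.
#' @return list with \code{angleDeg}, \code{slopeControl},
#'   \code{slopeStress}, \code{units}.
#' @rdname forkAngle
#' @export
setMethod("forkAngle", "GrowthSeries",
    function(x, forkDay, trait = c("area", "height")) {
    trait <- match.arg(trait)
    days <- growthDays(x)
    post <- days >= forkDay
    if (sum(post) < 2) stop("need at least 2 post-fork days")
    d <- days[post]
    sc <- unname(coef(lm(armSeries(x, "control", trait, "mean")[post] ~ d))[2])
    ss <- unname(coef(lm(armSeries(x, "stress", trait, "mean")[post] ~ d))[2])
    list(angleDeg = abs(atan(sc) - atan(ss)) * 180 / pi,
         slopeControl = sc, slopeStress = ss,
         units = if (trait == "area") "cm2/day" else "cm/day")
})

#' Per-day projected shoot area ratio (stress/control)
#'
#' @param x a \linkS4class{GrowthSeries} with strictly positive control
#'   means.
#' @return named numeric vector, one ratio per day.
#' @rdname psaRatio
#' @export
setMethod("psaRatio", "GrowthSeries", function(x) {
    cm <- armSeries(x, "control", "area", "mean")
    sm <- armSeries(x, "stress", "area", "mean")
    if (any(cm <= 0)) stop("control means must be strictly positive")
    setNames(sm / cm, paste0("day", growthDays(x)))
})

#' Per-band, per-day variance of hyperspectral pixel intensities
#'
#' The unbiased sample variance of pixel intensities is computed for each
#' wavelength band and day; its spread tracks physical changes such as
#' wilting, drying, yellowing or necrosis.
#'
#' @param x either a 3-d array indexed [band, day, pixel] (>= 2 pixels), or
#'   a \code{"HyperspectralStack"} from [simulateHyperspectral()], in which
#'   case both arms are processed.
#' @return For an array: a band x day variance matrix (rownames = band
#'   wavelengths when available). For a stack: list with \code{control},
#'   \code{stress} matrices and \code{wavelengths}.
#' @export
hyperspectralVariance <- function(x) {
    if (inherits(x, "HyperspectralStack")) {
        return(list(control = hyperspectralVariance(x$control),
                    stress = hyperspectralVariance(x$stress),
                    wavelengths = x$wavelengths))
    }
    if (!is.array(x) || length(dim(x)) != 3)
        stop("expected a [band, day, pixel] array")
    if (dim(x)[3] < 2) stop("need at least 2 pixels per band-day")
    v <- apply(x, c(1, 2), var)
    dimnames(v) <- dimnames(x)[1:2]
    v
}
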