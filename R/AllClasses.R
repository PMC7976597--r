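#' @import methods
#' @importFrom stats dnorm dpois kmeans lm pchisq ppois qnorm quantile
#'   rlnorm rnorm rpois runif sd coef median pbinom dist
NULL

.scalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
.scalarInt <- function(x) .scalarNum(x) && x == round(x)
.scalarLgl <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' SceneParams: configuration of a synthetic compartment scene
#'
#' Holds everything needed to generate a ground-truthed field of circular
#' compartments (droplets or Gelbeads) and to render it as a two-channel
#' fluorescence micrograph: image geometry, the lognormal diameter
#' distribution (mean and CV), the Poisson occupancy rate, the two-level
#' intensity model of the signal channel, and the acquisition noise.
#'
#' @slot imageWidth,imageHeight image size in pixels.
#' @slot pixelSize pixel size in micrometres per pixel (> 0).
#' @slot nCompartments number of compartments to place (>= 0).
#' @slot diameterMean mean compartment diameter, micrometres.
#' @slot diameterCV coefficient of variation of diameter, as a fraction
#'   (0.05 means 5 \%).
#' @slot occupancyLambda mean number of entities (cells or template
#'   copies) per compartment; occupancies are Poisson.
#' @slot refIntensityMean in-compartment intensity of the reference
#'   channel, ADU.
#' @slot sigIntensityNegative,sigIntensityPositive signal-channel
#'   intensities of negative and positive compartments, ADU.
#' @slot background image background level, ADU.
#' @slot noiseSD standard deviation of additive Gaussian noise, ADU.
#' @slot cellSpotSigma Gaussian sigma of a rendered cell spot,
#'   micrometres (used by the spot rendering mode).
#' @slot seed integer seed; all draws are deterministic given it.
#'
#' @seealso [SceneParams()] for the user constructor.
#' @exportClass SceneParams
setClass("SceneParams", representation(
    imageWidth = "integer", imageHeight = "integer",
    pixelSize = "numeric", nCompartments = "integer",
    diameterMean = "numeric", diameterCV = "numeric",
    occupancyLambda = "numeric",
    refIntensityMean = "numeric",
    sigIntensityNegative = "numeric", sigIntensityPositive = "numeric",
    background = "numeric", noiseSD = "numeric",
    cellSpotSigma = "numeric", seed = "integer"))

setValidity("SceneParams", function(object) {
    msg <- character()
    if (!.scalarNum(object@pixelSize) || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single finite value > 0")
    if (object@imageWidth < 1L || object@imageHeight < 1L)
        msg <- c(msg, "image dimensions must be >= 1 px")
    if (object@nCompartments < 0L)
        msg <- c(msg, "nCompartments must be >= 0")
    if (!.scalarNum(object@diameterMean) || object@diameterMean <= 0)
        msg <- c(msg, "diameterMean must be > 0")
    if (!.scalarNum(object@diameterCV) || object@diameterCV < 0)
        msg <- c(msg, "diameterCV must be >= 0")
    if (!.scalarNum(object@occupancyLambda) || object@occupancyLambda < 0)
        msg <- c(msg, "occupancyLambda must be >= 0")
    ints <- c(object@refIntensityMean, object@sigIntensityNegative,
              object@sigIntensityPositive, object@background)
    if (!all(vapply(ints, .scalarNum, logical(1))) || any(ints < 0))
        msg <- c(msg, "all intensities must be finite and >= 0")
    if (object@sigIntensityPositive <= object@sigIntensityNegative)
        msg <- c(msg, "sigIntensityPositive must exceed sigIntensityNegative")
    if (!.scalarNum(object@noiseSD) || object@noiseSD < 0)
        msg <- c(msg, "noiseSD must be >= 0")
    if (length(msg)) msg else TRUE
})

#' GroundTruth: per-compartment truth of a synthetic scene
#'
#' One row per compartment: id, centre (0-based pixel-centre coordinates),
#' diameter in micrometres, the number of encapsulated entities, and the
#' positive/negative class. Under the default intensity model a compartment
#' is positive iff it contains at least one entity.
#'
#' @slot compartments data.frame with columns `id`, `center_x`, `center_y`
#'   (px), `diameter_um`, `n_entities`, `is_positive`.
#' @slot pixelSize micrometres per pixel, carried so diameters can be
#'   related to pixel geometry.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    compartments = "data.frame", pixelSize = "numeric"))

setValidity("GroundTruth", function(object) {
    need <- c("id", "center_x", "center_y", "diameter_um",
              "n_entities", "is_positive")
    df <- object@compartments
    if (!all(need %in% names(df)))
        return(paste("compartments must have columns:",
                     paste(need, collapse = ", ")))
    msg <- character()
    if (nrow(df)) {
        if (any(df$diameter_um <= 0)) msg <- c(msg, "diameters must be > 0")
        if (any(df$n_entities < 0) ||
            any(df$n_entities != round(df$n_entities)))
            msg <- c(msg, "n_entities must be non-negative integers")
        if (!identical(as.logical(df$is_positive), df$n_entities > 0))
            msg <- c(msg, "is_positive must equal (n_entities > 0)")
        if (anyDuplicated(df$id)) msg <- c(msg, "ids must be unique")
    }
    if (!.scalarNum(object@pixelSize) || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be > 0")
    if (length(msg)) msg else TRUE
})

#' SizeStats: size-distribution summary of a compartment population
#'
#' @slot n number of diameters summarised.
#' @slot meanDiameter,sdDiameter mean and sample (n-1) standard deviation,
#'   micrometres. `sdDiameter` is `NA` when n < 2.
#' @slot cv coefficient of variation in percent (100 * sd / mean).
#' @slot p10,p25,p75,p90 percentiles by linear interpolation, micrometres.
#' @slot outliers diameters strictly outside the [p10, p90] whiskers.
#' @exportClass SizeStats
setClass("SizeStats", representation(
    n = "integer", meanDiameter = "numeric", sdDiameter = "numeric",
    cv = "numeric", p10 = "numeric", p25 = "numeric", p75 = "numeric",
    p90 = "numeric", outliers = "numeric"))

setValidity("SizeStats", function(object) {
    msg <- character()
    if (!is.na(object@cv) && object@cv < 0) msg <- c(msg, "cv must be >= 0")
    qs <- c(object@p10, object@p25, object@p75, object@p90)
    if (!any(is.na(qs)) && is.unsorted(qs))
        msg <- c(msg, "percentiles must be ordered p10 <= p25 <= p75 <= p90")
    if (length(object@outliers) &&
        !all(object@outliers < object@p10 | object@outliers > object@p90))
        msg <- c(msg, "outliers must lie strictly outside [p10, p90]")
    if (length(msg)) msg else TRUE
})

#' ThresholdFit: fitted two-component Gaussian mixture and its threshold
#'
#' Result of [fitBimodalThreshold()]: the negative and positive component
#' parameters, the mixing weight of the negative component, the bright/dark
#' decision threshold (density intersection between the two means), and a
#' separation index |muPos - muNeg| / sqrt(sdNeg * sdPos).
#'
#' @slot muNeg,muPos component means (muNeg < muPos).
#' @slot sdNeg,sdPos component standard deviations.
#' @slot weightNeg mixing weight of the negative component, in (0, 1).
#' @slot threshold decision threshold in the units of the fitted values.
#' @slot separation dimensionless separation index.
#' @slot converged FALSE when EM hit its iteration cap or the components
#'   overlap heavily (separation < 2); the fit is still reported.
#' @exportClass ThresholdFit
setClass("ThresholdFit", representation(
    muNeg = "numeric", muPos = "numeric", sdNeg = "numeric",
    sdPos = "numeric", weightNeg = "numeric", threshold = "numeric",
    separation = "numeric", converged = "logical"))

setValidity("ThresholdFit", function(object) {
    msg <- character()
    if (object@weightNeg <= 0 || object@weightNeg >= 1)
        msg <- c(msg, "weightNeg must be in (0, 1)")
    if (object@converged &&
        !(object@muNeg < object@threshold && object@threshold < object@muPos))
        msg <- c(msg, "threshold must lie between the means when converged")
    if (length(msg)) msg else TRUE
})

#' CallSummary: positive/negative call counts with a Wilson interval
#'
#' @slot nTotal,nPositive total and positive compartment counts.
#' @slot fractionPositive nPositive / nTotal (NA when nTotal = 0).
#' @slot ci95 95 \% Wilson score interval for the positive fraction.
#' @exportClass CallSummary
setClass("CallSummary", representation(
    nTotal = "integer", nPositive = "integer",
    fractionPositive = "numeric", ci95 = "numeric"))

setValidity("CallSummary", function(object) {
    msg <- character()
    if (object@nPositive < 0L || object@nPositive > object@nTotal)
        msg <- c(msg, "need 0 <= nPositive <= nTotal")
    if (length(object@ci95) != 2L)
        msg <- c(msg, "ci95 must have length 2")
    if (object@nTotal > 0L &&
        !(object@ci95[1] <= object@fractionPositive &&
          object@fractionPositive <= object@ci95[2]))
        msg <- c(msg, "fractionPositive must lie inside ci95")
    if (length(msg)) msg else TRUE
})

#' DigitalResult: Poisson digital quantification of one sample
#'
#' Encodes the standard digital assay estimate: lambda = -ln(negative
#' fraction) copies per partition, converted to copies per microlitre via
#' the partition volume, with a 95 \% confidence interval.
#'
#' @slot nTotal,nNegative partition counts.
#' @slot lambdaHat estimated mean copies per partition.
#' @slot partitionVolume partition volume in nanolitres.
#' @slot concentration estimated concentration, copies per microlitre.
#' @slot ci95 95 \% confidence interval for the concentration.
#' @exportClass DigitalResult
setClass("DigitalResult", representation(
    nTotal = "integer", nNegative = "integer", lambdaHat = "numeric",
    partitionVolume = "numeric", concentration = "numeric",
    ci95 = "numeric"))

setValidity("DigitalResult", function(object) {
    msg <- character()
    if (object@nNegative < 0L || object@nNegative > object@nTotal)
        msg <- c(msg, "need 0 <= nNegative <= nTotal")
    if (object@partitionVolume <= 0)
        msg <- c(msg, "partitionVolume must be > 0")
    lam <- -log(object@nNegative / object@nTotal)
    if (abs(lam - object@lambdaHat) > 1e-8 * max(1, lam))
        msg <- c(msg, "lambdaHat must equal -ln(nNegative/nTotal)")
    if (!(object@ci95[1] <= object@concentration + 1e-12 &&
          object@concentration <= object@ci95[2] + 1e-12))
        msg <- c(msg, "concentration must lie inside ci95")
    if (length(msg)) msg else TRUE
})

#' OccupancyPmf: Poisson occupancy probabilities at a given rate
#'
#' @slot lam mean entities per compartment.
#' @slot p0,p1 probabilities of exactly 0 and exactly 1 entity.
#' @slot pGe1,pGe2 probabilities of at least 1 and at least 2 entities.
#' @exportClass OccupancyPmf
setClass("OccupancyPmf", representation(
    lam = "numeric", p0 = "numeric", p1 = "numeric",
    pGe1 = "numeric", pGe2 = "numeric"))

setValidity("OccupancyPmf", function(object) {
    msg <- character()
    if (abs(object@p0 + object@p1 + object@pGe2 - 1) > 1e-12)
        msg <- c(msg, "p0 + p1 + pGe2 must equal 1")
    if (abs(object@pGe1 - (1 - object@p0)) > 1e-12)
        msg <- c(msg, "pGe1 must equal 1 - p0")
    if (length(msg)) msg else TRUE
})

#' DynamicRange: theoretical quantifiable range of a digital assay design
#'
#' @slot nPartitions number of partitions read.
#' @slot partitionVolume partition volume, nanolitres.
#' @slot lod limit of detection, copies per microlitre.
#' @slot lowerQuant,upperQuant lower and upper quantification bounds,
#'   copies per microlitre.
#' @slot criteria named list recording the rules used (minimum positive
#'   partitions, detection confidence, relative CI width limit, minimum
#'   expected negatives).
#' @exportClass DynamicRange
setClass("DynamicRange", representation(
    nPartitions = "integer", partitionVolume = "numeric",
    lod = "numeric", lowerQuant = "numeric", upperQuant = "numeric",
    criteria = "list"))

setValidity("DynamicRange", function(object) {
    if (!(object@lod <= object@lowerQuant &&
          object@lowerQuant < object@upperQuant))
        "need lod <= lowerQuant < upperQuant" else TRUE
})

#' RegressionResult: efficiency regression of estimated vs reference
#' concentration
#'
#' @slot slopeK OLS slope (the amplification-efficiency coefficient k).
#' @slot slopeSE standard error of the slope.
#' @slot intercept intercept, copies per microlitre.
#' @slot rSquared coefficient of determination.
#' @slot nPoints number of (reference, estimated) pairs.
#' @exportClass RegressionResult
setClass("RegressionResult", representation(
    slopeK = "numeric", slopeSE = "numeric", intercept = "numeric",
    rSquared = "numeric", nPoints = "integer"))

setValidity("RegressionResult", function(object) {
    msg <- character()
    if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (object@nPoints < 3L)
        msg <- c(msg, "a reported fit needs nPoints >= 3")
    if (length(msg)) msg else TRUE
})

#' StabilityReport: size-distribution change across a heating protocol
#'
#' @slot cvBefore,cvAfter diameter CVs in percent.
#' @slot deltaCV cvAfter - cvBefore, percentage points.
#' @slot meanBefore,meanAfter mean diameters, micrometres.
#' @slot outlierFractionBefore,outlierFractionAfter fraction of diameters
#'   outside the [p10, p90] whiskers.
#' @exportClass StabilityReport
setClass("StabilityReport", representation(
    cvBefore = "numeric", cvAfter = "numeric", deltaCV = "numeric",
    meanBefore = "numeric", meanAfter = "numeric",
    outlierFractionBefore = "numeric", outlierFractionAfter = "numeric"))

setValidity("StabilityReport", function(object) {
    if (abs(object@deltaCV - (object@cvAfter - object@cvBefore)) > 1e-9)
        "deltaCV must equal cvAfter - cvBefore" else TRUE
})
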