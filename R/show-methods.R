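#' @describeIn SceneParams-class compact display
#' @param object object to display
setMethod("show", "SceneParams", function(object) {
    cat(sprintf(paste0(
        "SceneParams: %d x %d px at %.3g um/px\n",
        "  %d compartments, diameter %.4g um (CV %.3g%%), lambda = %.3g\n",
        "  ref %.4g / sig %.4g|%.4g over bg %.4g ADU, noise sd %.3g, seed %d\n"),
        object@imageWidth, object@imageHeight, object@pixelSize,
        object@nCompartments, object@diameterMean, 100 * object@diameterCV,
        object@occupancyLambda, object@refIntensityMean,
        object@sigIntensityNegative, object@sigIntensityPositive,
        object@background, object@noiseSD, object@seed))
})

#' @describeIn GroundTruth-class compact display
#' @param object object to display
setMethod("show", "GroundTruth", function(object) {
    df <- object@compartments
    cat(sprintf("GroundTruth: %d compartments (%d positive) at %.3g um/px\n",
                nrow(df), sum(df$is_positive), object@pixelSize))
    if (nrow(df))
        cat(sprintf("  diameters %.4g-%.4g um, %d entities in total\n",
                    min(df$diameter_um), max(df$diameter_um),
                    sum(df$n_entities)))
})

#' @describeIn SizeStats-class compact display
#' @param object object to display
setMethod("show", "SizeStats", function(object) {
    cat(sprintf(paste0(
        "SizeStats: n = %d, mean %.4g um, CV %.3g%%\n",
        "  p10/p25/p75/p90 = %.4g/%.4g/%.4g/%.4g um, %d outliers\n"),
        object@n, object@meanDiameter, object@cv, object@p10, object@p25,
        object@p75, object@p90, length(object@outliers)))
})

#' @describeIn ThresholdFit-class compact display
#' @param object object to display
setMethod("show", "ThresholdFit", function(object) {
    cat(sprintf(paste0(
        "ThresholdFit: threshold %.5g (separation %.3g, %s)\n",
        "  neg N(%.4g, %.3g^2) w = %.3g | pos N(%.4g, %.3g^2)\n"),
        object@threshold, object@separation,
        if (object@converged) "converged" else "NOT converged",
        object@muNeg, object@sdNeg, object@weightNeg,
        object@muPos, object@sdPos))
})

#' @describeIn CallSummary-class compact display
#' @param object object to display
setMethod("show", "CallSummary", function(object) {
    cat(sprintf(
        "CallSummary: %d / %d positive (%.1f%%), 95%% CI [%.1f, %.1f]%%\n",
        object@nPositive, object@nTotal, 100 * object@fractionPositive,
        100 * object@ci95[1L], 100 * object@ci95[2L]))
})

#' @describeIn DigitalResult-class compact display
#' @param object object to display
setMethod("show", "DigitalResult", function(object) {
    cat(sprintf(paste0(
        "DigitalResult: %d negatives of %d partitions (%.3g nL)\n",
        "  lambda = %.4g copies/partition; %.4g copies/uL ",
        "[%.4g, %.4g]\n"),
        object@nNegative, object@nTotal, object@partitionVolume,
        object@lambdaHat, object@concentration,
        object@ci95[1L], object@ci95[2L]))
})

#' @describeIn OccupancyPmf-class compact display
#' @param object object to display
setMethod("show", "OccupancyPmf", function(object) {
    cat(sprintf(paste0(
        "OccupancyPmf at lambda = %.4g:\n",
        "  P(0) = %.4f, P(1) = %.4f, P(>=1) = %.4f, P(>=2) = %.4f\n"),
        object@lam, object@p0, object@p1, object@pGe1, object@pGe2))
})

#' @describeIn DynamicRange-class compact display
#' @param object object to display
setMethod("show", "DynamicRange", function(object) {
    cat(sprintf(paste0(
        "DynamicRange: %d partitions of %.3g nL\n",
        "  LOD %.3g, quantifiable %.3g-%.4g copies/uL\n"),
        object@nPartitions, object@partitionVolume, object@lod,
        object@lowerQuant, object@upperQuant))
})

#' @describeIn RegressionResult-class compact display
#' @param object object to display
setMethod("show", "RegressionResult", function(object) {
    cat(sprintf(
        "RegressionResult: k = %.3f +/- %.3f, intercept %.3g, R2 = %.4f (n = %d)\n",
        object@slopeK, object@slopeSE, object@intercept, object@rSquared,
        object@nPoints))
})

#' @describeIn StabilityReport-class compact display
#' @param object object to display
setMethod("show", "StabilityReport", function(object) {
    cat(sprintf(paste0(
        "StabilityReport: CV %.3g%% -> %.3g%% (delta %+.3g points)\n",
        "  mean diameter %.4g -> %.4g um, ",
        "outlier fraction %.3g -> %.3g\n"),
        object@cvBefore, object@cvAfter, object@deltaCV,
        object@meanBefore, object@meanAfter,
        object@outlierFractionBefore, object@outlierFractionAfter))
})
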