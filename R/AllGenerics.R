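#' Accessors for gelbead result objects
#'
#' Small accessor family so slots never need to be touched directly:
#' `compartments()` returns the per-compartment table of a
#' [GroundTruth-class] object, `nTotal()` / `nPositive()` / `nNegative()`
#' the counts of a call or quantification result, `fractionPositive()` and
#' `ci95()` the positive fraction and its interval, `lambdaHat()` and
#' `concentration()` the Poisson estimates, `threshold()` and
#' `separation()` the fitted decision threshold, `cvPercent()` the size CV
#' in percent, `deltaCV()` the heating-induced CV change, and `slopeK()` /
#' `rSquared()` the efficiency regression summary.
#'
#' @param object a gelbead S4 object.
#' @return the slot value named by the accessor.
#' @name accessors
#' @aliases compartments nTotal nPositive nNegative fractionPositive ci95
#'   lambdaHat concentration threshold separation cvPercent deltaCV slopeK
#'   rSquared
NULL

#' @rdname accessors
#' @export
setGeneric("compartments", function(object) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("nTotal", function(object) standardGeneric("nTotal"))
#' @rdname accessors
#' @export
setGeneric("nPositive", function(object) standardGeneric("nPositive"))
#' @rdname accessors
#' @export
setGeneric("nNegative", function(object) standardGeneric("nNegative"))
#' @rdname accessors
#' @export
setGeneric("fractionPositive",
           function(object) standardGeneric("fractionPositive"))
#' @rdname accessors
#' @export
setGeneric("ci95", function(object) standardGeneric("ci95"))
#' @rdname accessors
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))
#' @rdname accessors
#' @export
setGeneric("concentration", function(object) standardGeneric("concentration"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("separation", function(object) standardGeneric("separation"))
#' @rdname accessors
#' @export
setGeneric("cvPercent", function(object) standardGeneric("cvPercent"))
#' @rdname accessors
#' @export
setGeneric("deltaCV", function(object) standardGeneric("deltaCV"))
#' @rdname accessors
#' @export
setGeneric("slopeK", function(object) standardGeneric("slopeK"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname accessors
setMethod("compartments", "GroundTruth", function(object) object@compartments)
#' @rdname accessors
setMethod("nTotal", "CallSummary", function(object) object@nTotal)
#' @rdname accessors
setMethod("nTotal", "DigitalResult", function(object) object@nTotal)
#' @rdname accessors
setMethod("nPositive", "CallSummary", function(object) object@nPositive)
#' @rdname accessors
setMethod("nNegative", "DigitalResult", function(object) object@nNegative)
#' @rdname accessors
setMethod("fractionPositive", "CallSummary",
          function(object) object@fractionPositive)
#' @rdname accessors
setMethod("ci95", "CallSummary", function(object) object@ci95)
#' @rdname accessors
setMethod("ci95", "DigitalResult", function(object) object@ci95)
#' @rdname accessors
setMethod("lambdaHat", "DigitalResult", function(object) object@lambdaHat)
#' @rdname accessors
setMethod("concentration", "DigitalResult",
          function(object) object@concentration)
#' @rdname accessors
setMethod("threshold", "ThresholdFit", function(object) object@threshold)
#' @rdname accessors
setMethod("separation", "ThresholdFit", function(object) object@separation)
#' @rdname accessors
setMethod("cvPercent", "SizeStats", function(object) object@cv)
#' @rdname accessors
setMethod("deltaCV", "StabilityReport", function(object) object@deltaCV)
#' @rdname accessors
setMethod("slopeK", "RegressionResult", function(object) object@slopeK)
#' @rdname accessors
setMethod("rSquared", "RegressionResult", function(object) object@rSquared)
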