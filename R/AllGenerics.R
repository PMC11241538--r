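#' Accessor generics
#'
#' Small accessor family for the package's S4 classes; always prefer these
#' over direct slot access.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(x) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("curveTimes", function(x) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("baselineLevel", function(x) standardGeneric("baselineLevel"))
#' @rdname accessors
#' @export
setGeneric("cciaValue", function(x) standardGeneric("cciaValue"))
#' @rdname accessors
#' @export
setGeneric("aucProximal", function(x) standardGeneric("aucProximal"))
#' @rdname accessors
#' @export
setGeneric("aucStenotic", function(x) standardGeneric("aucStenotic"))
#' @rdname accessors
#' @export
setGeneric("ffrValue", function(x) standardGeneric("ffrValue"))
#' @rdname accessors
#' @export
setGeneric("peakTimes", function(x) standardGeneric("peakTimes"))
#' @rdname accessors
#' @export
setGeneric("rrCv", function(x) standardGeneric("rrCv"))
#' @rdname accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @rdname accessors
#' @export
setGeneric("matchScores", function(x) standardGeneric("matchScores"))
#' @rdname accessors
#' @export
setGeneric("validityMask", function(x) standardGeneric("validityMask"))

#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameTimes", "FrameStack", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
#' @export
setMethod("mmPerPx", "FrameStack", function(x) x@mmPerPx)
#' @rdname accessors
#' @export
setMethod("mmPerPx", "RoiSpec", function(x) x@mmPerPx)
#' @rdname accessors
#' @export
setMethod("curveValues", "TimeIntensityCurve", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("curveTimes", "TimeIntensityCurve", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("baselineLevel", "TimeIntensityCurve", function(x) x@baselineLevel)
#' @rdname accessors
#' @export
setMethod("cciaValue", "CciaResult", function(x) x@ccia)
#' @rdname accessors
#' @export
setMethod("aucProximal", "CciaResult", function(x) x@aucProximal)
#' @rdname accessors
#' @export
setMethod("aucStenotic", "CciaResult", function(x) x@aucStenotic)
#' @rdname accessors
#' @export
setMethod("ffrValue", "FfrResult", function(x) x@ffr)
#' @rdname accessors
#' @export
setMethod("peakTimes", "RPeakSet", function(x) x@peakTimes)
#' @rdname accessors
#' @export
setMethod("rrCv", "RPeakSet", function(x) x@rrCv)
#' @rdname accessors
#' @export
setMethod("displacements", "MotionTrack", function(x) x@displacements)
#' @rdname accessors
#' @export
setMethod("matchScores", "MotionTrack", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("validityMask", "StabilizedStack", function(x) x@validityMask)

setMethod("show", "FrameStack", function(object) {
    d <- dim(object@frames)
    cat(sprintf("%s: %d frame(s) of %d x %d px, %.4g mm/px, %.4g fps, t = [%.3g, %.3g] s\n",
                class(object), d[3L], d[1L], d[2L], object@mmPerPx,
                object@frameRate, object@times[1L], object@times[d[3L]]))
})

setMethod("show", "TimeIntensityCurve", function(object) {
    cat(sprintf("TimeIntensityCurve: %d samples over [%.3g, %.3g] s, peak %.4g, baseline %.4g, %d ROI px\n",
                length(object@times), object@times[1L],
                object@times[length(object@times)], max(object@values),
                object@baselineLevel, object@roiPixelCount))
})

setMethod("show", "CciaResult", function(object) {
    cat(sprintf("CciaResult: CCIA = %.4f (AUC stenotic %.6g / AUC proximal %.6g)\n",
                object@ccia, object@aucStenotic, object@aucProximal))
    if (length(object@window) == 2L && all(is.finite(object@window)))
        cat(sprintf("  integration window [%.3g, %.3g] s\n",
                    object@window[1L], object@window[2L]))
})

setMethod("show", "FfrResult", function(object) {
    cat(sprintf("FfrResult: FFR = %.4f (mean Pd %.2f / mean Pa %.2f mmHg, Pv %.1f, %d cycles)\n",
                object@ffr, object@meanPd, object@meanPa, object@pv,
                object@nCycles))
})

setMethod("show", "RPeakSet", function(object) {
    cat(sprintf("RPeakSet: %d peaks, mean R-R %.3f s, R-R CV %.4f\n",
                length(object@peakTimes), object@meanRr, object@rrCv))
})

setMethod("show", "MotionTrack", function(object) {
    a <- sqrt(rowSums(object@displacements^2))
    cat(sprintf("MotionTrack: %d frames, reference %d, |d| up to %.2f px, median NCC %.3f\n",
                nrow(object@displacements), object@referenceFrame, max(a),
                stats::median(object@scores)))
})

setMethod("show", "StenosisGeometry", function(object) {
    cat(sprintf("StenosisGeometry: %.0f%% DS (h/r = %.2g), Li %.3g + Xs %.3g + Lo %.3g = %.3g mm, normal %.3g mm\n",
                object@percentDs, object@hOverR, object@li, object@xs,
                object@lo, object@totalLength, object@normalDiameter))
})

setMethod("show", "CorrelationReport", function(object) {
    cat(sprintf("CorrelationReport: r = %.4f, p = %.4g, n = %d; y = %.4g x + %.4g\n",
                object@r, object@pValue, object@n, object@slope,
                object@intercept))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %.0f%% DS x %.3g mm lesion, %s flow %.3g cm/s @ %.0f bpm, %g frames @ %g fps, dx %.3g mm, D %.3g mm^2/s, noise SD %.3g, seed %d\n",
                object@geometry@percentDs, object@geometry@totalLength,
                if (object@flow@baseFraction >= 1) "constant" else "pulsatile",
                object@flow@meanVelocity, object@flow@heartRate,
                object@duration * object@frameRate, object@frameRate,
                object@gridDx, object@dispersionCoeff, object@noiseSd,
                object@seed))
})
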