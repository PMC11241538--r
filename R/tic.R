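#' Extract the contrast time-intensity curve within an ROI
#'
#' The ROI statistic is the per-pixel mean intensity. Contrast agent
#' attenuates the X-ray image, so the signal is polarity-inverted:
#' \code{value(t) = max(0, baseline - mean(frame_t within mask))}, where the
#' baseline is the mean over the first \code{baselineFrames} (pre-injection)
#' frames.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param mask logical matrix matching the frame dimensions, non-empty.
#' @param baselineFrames number of leading pre-injection frames used for the
#'   baseline (>= 1, < number of frames).
#' @return A \linkS4class{TimeIntensityCurve}.
#' @export
extractSignal <- function(stack, mask, baselineFrames = 1L) {
    stopifnot(is(stack, "FrameStack"))
    d <- dim(stack@frames)
    if (!is.logical(mask)) stop("'mask' must be logical")
    if (!identical(dim(mask), d[1:2]))
        stop("mask dimensions (", paste(dim(mask), collapse = " x "),
             ") do not match the frames (", d[1L], " x ", d[2L], ")")
    idx <- which(mask)
    if (length(idx) == 0L) stop("'mask' is empty")
    if (baselineFrames < 1L || baselineFrames >= d[3L])
        stop("'baselineFrames' must be in [1, nFrames - 1]")
    perFrame <- prod(d[1:2])
    means <- vapply(seq_len(d[3L]), function(k)
        mean(stack@frames[idx + (k - 1L) * perFrame]), numeric(1))
    baseline <- mean(means[seq_len(baselineFrames)])
    TimeIntensityCurve(stack@times, pmax(0, baseline - means),
                       roiPixelCount = length(idx),
                       baselineLevel = baseline)
}

#' Trapezoidal area under a time-intensity curve
#'
#' Integrates the curve over \code{[tStart, tEnd]} by the trapezoid rule,
#' linearly interpolating the curve at the window edges; exact for
#' piecewise-linear curves sampled at their breakpoints.
#'
#' @param curve a \linkS4class{TimeIntensityCurve}.
#' @param tStart,tEnd integration window (s), inside the curve support;
#'   defaults to the full support.
#' @return Area in signal-seconds.
#' @examples
#' cv <- TimeIntensityCurve(0:10, rep(2, 11))
#' curveAuc(cv)           # rectangle: 2 * 10
#' @export
curveAuc <- function(curve, tStart = NULL, tEnd = NULL) {
    t <- curve@times; v <- curve@values
    if (length(t) < 2L) stop("need at least 2 samples to integrate")
    if (is.null(tStart)) tStart <- t[1L]
    if (is.null(tEnd)) tEnd <- t[length(t)]
    if (tStart >= tEnd) stop("'tStart' must be < 'tEnd'")
    if (tStart < t[1L] - 1e-12 || tEnd > t[length(t)] + 1e-12)
        stop("integration window [", tStart, ", ", tEnd,
             "] lies outside the curve support")
    vs <- stats::approx(t, v, xout = c(tStart, tEnd))$y
    keep <- t > tStart & t < tEnd
    tt <- c(tStart, t[keep], tEnd)
    vv <- c(vs[1L], v[keep], vs[2L])
    sum(diff(tt) * (vv[-length(vv)] + vv[-1L]) / 2)
}

#' The contrast-intensity stenosis index
#'
#' CCIA is the ratio of the contrast time-intensity AUC in the stenotic
#' region to that in the equal-sized proximal region. Under the
#' Stewart-Hamilton relation each AUC is inversely proportional to local
#' flow, so the ratio indexes the hemodynamic impact of the lesion: values
#' near 1 indicate free contrast passage, low values a severe stenosis.
#' Values above 1 are legal and occur in real data; no clamping is applied
#' and the value is never rounded internally.
#'
#' @param aucProximal AUC in the proximal region (> 0).
#' @param aucStenotic AUC in the stenotic region (> 0).
#' @param window optional integration window recorded for provenance.
#' @param curves optional list of the two curves.
#' @return A \linkS4class{CciaResult}.
#' @examples
#' cciaValue(cciaIndex(1706, 1041))  # 0.61 at 2 dp
#' @export
cciaIndex <- function(aucProximal, aucStenotic, window = c(NA_real_, NA_real_),
                      curves = list()) {
    if (!is.finite(aucProximal) || aucProximal <= 0)
        stop("'aucProximal' must be finite and > 0 (absent contrast or bad baseline?)")
    if (!is.finite(aucStenotic) || aucStenotic <= 0)
        stop("'aucStenotic' must be finite and > 0 (absent contrast or bad baseline?)")
    new("CciaResult", aucProximal = as.numeric(aucProximal),
        aucStenotic = as.numeric(aucStenotic),
        ccia = as.numeric(aucStenotic) / as.numeric(aucProximal),
        window = as.numeric(window), curves = curves)
}

#' Stewart-Hamilton indicator-dilution flow estimate
#'
#' Flow = injected indicator amount / time-integral of downstream
#' concentration. The image-domain AUC is mapped to a concentration AUC by
#' the calibration gain (signal units per concentration unit).
#'
#' @param injection an \linkS4class{Injection} (amount I in mL).
#' @param curveAuc time-intensity AUC (signal * s), > 0.
#' @param calibrationGain signal units per concentration unit (> 0);
#'   1 when \code{curveAuc} is already a concentration AUC.
#' @return Flow estimate in mL/s.
#' @export
stewartHamiltonFlow <- function(injection, curveAuc, calibrationGain = 1) {
    stopifnot(is(injection, "Injection"))
    if (!is.finite(curveAuc) || curveAuc <= 0)
        stop("'curveAuc' must be finite and > 0")
    if (calibrationGain <= 0) stop("'calibrationGain' must be > 0")
    injection@amount / (curveAuc / calibrationGain)
}

.arcLength <- function(cl) c(0, cumsum(sqrt(rowSums(diff(cl)^2))))

# interpolate the centerline point at arc length s (px)
.pointAt <- function(cl, arc, s) {
    c(stats::approx(arc, cl[, 1L], xout = s, rule = 2)$y,
      stats::approx(arc, cl[, 2L], xout = s, rule = 2)$y)
}

#' Place the equal-sized proximal region upstream of the lesion
#'
#' Translates the stenotic mask upstream along the directed centerline so
#' that its downstream boundary sits \code{gapMm} (default 10 mm) of
#' centerline arc length upstream of the stenotic region's upstream
#' boundary. The translation is by a single displacement vector with
#' nearest-pixel rounding, so the proximal region has exactly the same
#' pixel count as the stenotic region.
#'
#' @param roi a \linkS4class{RoiSpec}.
#' @param gapMm gap between the two regions, mm of arc length.
#' @param imageDim optional c(nrow, ncol) bounds check target; defaults to
#'   the mask dimensions.
#' @return Logical matrix: the proximal mask.
#' @export
defineProximalRoi <- function(roi, gapMm = 10, imageDim = dim(roi@stenoticMask)) {
    stopifnot(is(roi, "RoiSpec"))
    cl <- roi@centerline
    arc <- .arcLength(cl)
    ri <- pmin(pmax(round(cl[, 1L]), 1L), nrow(roi@stenoticMask))
    ci <- pmin(pmax(round(cl[, 2L]), 1L), ncol(roi@stenoticMask))
    inside <- roi@stenoticMask[cbind(ri, ci)]
    if (!any(inside)) stop("centerline does not cross the stenotic mask")
    sMin <- min(arc[inside])          # upstream (proximal) lesion boundary
    sMax <- max(arc[inside])          # downstream lesion boundary
    extent <- sMax - sMin
    gapPx <- gapMm / roi@mmPerPx
    sTargetEnd <- sMin - gapPx        # where the shifted mask must end
    if (sTargetEnd - extent < arc[1L] - 1e-9)
        stop("centerline too short: need ", round(extent + gapPx), " px of ",
             "upstream arc length before the lesion, have ", round(sMin))
    shift <- .pointAt(cl, arc, sTargetEnd) - .pointAt(cl, arc, sMax)
    dyx <- round(shift)
    w <- which(roi@stenoticMask, arr.ind = TRUE)
    nw <- cbind(w[, 1L] + dyx[1L], w[, 2L] + dyx[2L])
    if (any(nw[, 1L] < 1L) || any(nw[, 1L] > imageDim[1L]) ||
        any(nw[, 2L] < 1L) || any(nw[, 2L] > imageDim[2L]))
        stop("translated proximal mask exits the image bounds")
    out <- matrix(FALSE, imageDim[1L], imageDim[2L])
    out[nw] <- TRUE
    out
}

#' Compute CCIA from a frame stack and ROI specification
#'
#' Composes \code{\link{defineProximalRoi}}, \code{\link{extractSignal}} on
#' both regions, \code{\link{curveAuc}} on both curves, and
#' \code{\link{cciaIndex}}. Both curves are recorded in the result for
#' inspection.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param roi a \linkS4class{RoiSpec} (calibration should match the stack).
#' @param baselineFrames pre-injection frames used for the baseline.
#' @param window integration window c(tStart, tEnd); defaults to the full
#'   acquisition.
#' @param gapMm proximal-region offset, mm.
#' @return A \linkS4class{CciaResult}.
#' @export
computeCcia <- function(stack, roi, baselineFrames = 1L, window = NULL,
                        gapMm = 10) {
    prox <- defineProximalRoi(roi, gapMm = gapMm, imageDim = dim(stack@frames)[1:2])
    cs <- extractSignal(stack, .fitMask(roi@stenoticMask, dim(stack@frames)[1:2]),
                        baselineFrames)
    cp <- extractSignal(stack, prox, baselineFrames)
    if (is.null(window)) window <- range(stack@times)
    cciaIndex(curveAuc(cp, window[1L], window[2L]),
              curveAuc(cs, window[1L], window[2L]),
              window = window,
              curves = list(proximal = cp, stenotic = cs))
}

# pad/validate a mask against the stack's frame dimensions
.fitMask <- function(mask, dims) {
    if (identical(dim(mask), as.integer(dims))) return(mask)
    stop("ROI mask dimensions do not match the stack frames")
}
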