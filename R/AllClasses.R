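#' @import methods
NULL

.strictlyIncreasing <- function(x) length(x) < 2L || all(diff(x) > 0)

#' FrameStack: an angiographic image sequence
#'
#' Ordered grayscale frames with per-frame acquisition times and a
#' millimetre-per-pixel spatial calibration. Frames are stored as a numeric
#' array of dimension \code{nrow x ncol x nFrames}; pixel (1, 1) is the
#' top-left corner and coordinates are (row, column), 1-based, throughout
#' the package.
#'
#' @slot frames numeric array, \code{nrow x ncol x nFrames}, finite and >= 0.
#' @slot times numeric, acquisition time of each frame in seconds, strictly
#'   increasing.
#' @slot mmPerPx numeric(1), spatial calibration in mm per pixel (> 0).
#' @slot frameRate numeric(1), nominal frames per second.
#' @export
setClass("FrameStack",
    representation(frames = "array", times = "numeric",
                   mmPerPx = "numeric", frameRate = "numeric"))

setValidity("FrameStack", function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L)
        return("'frames' must be a 3-D array (rows x cols x frames)")
    if (d[3L] < 1L)
        return("stack must contain at least one frame")
    if (length(object@times) != d[3L])
        return("length(times) must equal the number of frames")
    if (!all(is.finite(object@times)) || !.strictlyIncreasing(object@times))
        return("'times' must be finite and strictly increasing")
    if (!all(is.finite(object@frames)))
        return("all intensities must be finite")
    if (any(object@frames < 0))
        return("all intensities must be >= 0")
    if (length(object@mmPerPx) != 1L || !is.finite(object@mmPerPx) ||
        object@mmPerPx <= 0)
        return("'mmPerPx' must be a single positive number")
    if (length(object@frameRate) != 1L || object@frameRate <= 0)
        return("'frameRate' must be a single positive number")
    TRUE
})

#' Construct a FrameStack
#'
#' @param frames numeric array \code{nrow x ncol x nFrames} of non-negative
#'   intensities.
#' @param times per-frame times in seconds; defaults to
#'   \code{(0:(n-1)) / frameRate}.
#' @param mmPerPx spatial calibration, mm per pixel.
#' @param frameRate nominal frame rate in frames per second.
#' @return A \linkS4class{FrameStack}.
#' @examples
#' fs <- FrameStack(array(0, c(4, 4, 3)), mmPerPx = 0.2, frameRate = 30)
#' nFrames(fs)
#' @export
FrameStack <- function(frames, times = NULL, mmPerPx, frameRate = 30) {
    if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
    if (!is.array(frames) || length(dim(frames)) != 3L)
        stop("'frames' must be a 3-D array")
    if (is.null(times)) times <- (seq_len(dim(frames)[3L]) - 1) / frameRate
    new("FrameStack", frames = frames, times = as.numeric(times),
        mmPerPx = as.numeric(mmPerPx), frameRate = as.numeric(frameRate))
}

#' StabilizedStack: a motion-corrected FrameStack
#'
#' A \linkS4class{FrameStack} produced by \code{\link{stabilize}}, carrying a
#' per-pixel validity mask that is FALSE wherever the inverse translation
#' sampled outside the original field of view (those pixels hold replicated
#' edge values).
#'
#' @slot validityMask logical array of the same dimension as \code{frames}.
#' @export
setClass("StabilizedStack", contains = "FrameStack",
    representation(validityMask = "array"))

setValidity("StabilizedStack", function(object) {
    if (!identical(dim(object@validityMask), dim(object@frames)))
        return("'validityMask' must match the frame array dimensions")
    if (!is.logical(object@validityMask))
        return("'validityMask' must be logical")
    TRUE
})

#' EcgTrace: a uniformly sampled ECG record
#'
#' @slot times sample times in seconds, strictly increasing, uniformly spaced
#'   (tolerance 1e-6 s).
#' @slot voltage ECG voltage in arbitrary units.
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("EcgTrace",
    representation(times = "numeric", voltage = "numeric",
                   samplingRate = "numeric"))

setValidity("EcgTrace", function(object) {
    n <- length(object@times)
    if (n < 2L) return("an ECG trace needs at least 2 samples")
    if (length(object@voltage) != n)
        return("'times' and 'voltage' must have equal length")
    dt <- diff(object@times)
    if (any(dt <= 0)) return("'times' must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
        return("'times' must be uniformly spaced (1e-6 s tolerance)")
    if (object@samplingRate <= 0) return("'samplingRate' must be > 0")
    TRUE
})

#' Construct an EcgTrace
#'
#' @param times sample times (s), uniform spacing.
#' @param voltage voltages (arbitrary units).
#' @param samplingRate Hz; inferred from \code{times} when missing.
#' @return An \linkS4class{EcgTrace}.
#' @export
EcgTrace <- function(times, voltage, samplingRate = NULL) {
    if (is.null(samplingRate))
        samplingRate <- 1 / stats::median(diff(times))
    new("EcgTrace", times = as.numeric(times), voltage = as.numeric(voltage),
        samplingRate = as.numeric(samplingRate))
}

#' PressureTraces: paired aortic and distal pressure recordings
#'
#' @slot times sample times in seconds, strictly increasing.
#' @slot pa aortic pressure, mmHg, > 0 everywhere.
#' @slot pd distal coronary pressure, mmHg.
#' @slot pv venous pressure (constant), mmHg; defaults to 0.
#' @export
setClass("PressureTraces",
    representation(times = "numeric", pa = "numeric", pd = "numeric",
                   pv = "numeric"))

setValidity("PressureTraces", function(object) {
    n <- length(object@times)
    if (length(object@pa) != n || length(object@pd) != n)
        return("'times', 'pa' and 'pd' must have equal length")
    if (!.strictlyIncreasing(object@times))
        return("'times' must be strictly increasing")
    if (any(!is.finite(object@pa)) || any(object@pa <= 0))
        return("'pa' must be finite and > 0 everywhere")
    if (length(object@pv) != 1L) return("'pv' must be a single number")
    TRUE
})

#' Construct PressureTraces
#'
#' @param times sample times (s).
#' @param pa aortic pressure (mmHg).
#' @param pd distal pressure (mmHg).
#' @param pv venous pressure (mmHg), default 0.
#' @return A \linkS4class{PressureTraces}.
#' @export
PressureTraces <- function(times, pa, pd, pv = 0) {
    new("PressureTraces", times = as.numeric(times), pa = as.numeric(pa),
        pd = as.numeric(pd), pv = as.numeric(pv))
}

#' RoiSpec: stenotic region of interest with a directed centerline
#'
#' The stenotic mask marks the region where the vessel narrows; the
#' centerline is an ordered (row, column) path directed from inflow
#' (proximal) to outflow (distal) used to place the equal-sized proximal
#' region upstream (see \code{\link{defineProximalRoi}}).
#'
#' @slot stenoticMask logical matrix, non-empty.
#' @slot centerline numeric matrix, n x 2, columns (row, col), 1-based,
#'   >= 2 points, intersecting the mask.
#' @slot mmPerPx mm-per-pixel calibration (> 0).
#' @export
setClass("RoiSpec",
    representation(stenoticMask = "matrix", centerline = "matrix",
                   mmPerPx = "numeric"))

setValidity("RoiSpec", function(object) {
    m <- object@stenoticMask
    if (!is.logical(m) || !any(m)) return("'stenoticMask' must be a non-empty logical matrix")
    cl <- object@centerline
    if (ncol(cl) != 2L || nrow(cl) < 2L)
        return("'centerline' must be an n x 2 matrix with >= 2 points")
    ri <- pmin(pmax(round(cl[, 1L]), 1L), nrow(m))
    ci <- pmin(pmax(round(cl[, 2L]), 1L), ncol(m))
    if (!any(m[cbind(ri, ci)]))
        return("'centerline' must intersect the stenotic mask")
    if (length(object@mmPerPx) != 1L || object@mmPerPx <= 0)
        return("'mmPerPx' must be a single positive number")
    TRUE
})

#' Construct a RoiSpec
#'
#' @param stenoticMask logical matrix marking the stenotic region.
#' @param centerline n x 2 matrix of (row, col) points, proximal to distal.
#' @param mmPerPx mm-per-pixel calibration.
#' @return A \linkS4class{RoiSpec}.
#' @export
RoiSpec <- function(stenoticMask, centerline, mmPerPx) {
    storage.mode(centerline) <- "double"
    new("RoiSpec", stenoticMask = stenoticMask, centerline = centerline,
        mmPerPx = as.numeric(mmPerPx))
}

#' TimeIntensityCurve: contrast signal over time within one ROI
#'
#' The baseline-subtracted, polarity-inverted attenuation signal C(t):
#' contrast agent darkens the angiogram, so the signal is
#' \code{max(0, baseline - frame mean)} within the ROI.
#'
#' @slot times frame times, seconds, strictly increasing.
#' @slot values contrast signal, >= 0.
#' @slot roiPixelCount number of pixels in the ROI.
#' @slot baselineLevel pre-injection mean intensity within the ROI.
#' @export
setClass("TimeIntensityCurve",
    representation(times = "numeric", values = "numeric",
                   roiPixelCount = "integer", baselineLevel = "numeric"))

setValidity("TimeIntensityCurve", function(object) {
    if (length(object@times) != length(object@values))
        return("'times' and 'values' must have equal length")
    if (!.strictlyIncreasing(object@times))
        return("'times' must be strictly increasing")
    if (any(!is.finite(object@values)) || any(object@values < 0))
        return("'values' must be finite and >= 0")
    TRUE
})

#' Construct a TimeIntensityCurve
#'
#' @param times frame times (s).
#' @param values contrast signal values (>= 0).
#' @param roiPixelCount pixels in the ROI.
#' @param baselineLevel baseline intensity level.
#' @return A \linkS4class{TimeIntensityCurve}.
#' @export
TimeIntensityCurve <- function(times, values, roiPixelCount = NA_integer_,
                               baselineLevel = NA_real_) {
    new("TimeIntensityCurve", times = as.numeric(times),
        values = as.numeric(values),
        roiPixelCount = as.integer(roiPixelCount),
        baselineLevel = as.numeric(baselineLevel))
}

#' Injection: contrast injection protocol
#'
#' @slot amount injected contrast volume I, mL (> 0); default 4 mL.
#' @slot rate injection rate, mL/s (> 0); default 16 mL/s.
#' @slot startTime injection start, seconds from acquisition start.
#' @export
setClass("Injection",
    representation(amount = "numeric", rate = "numeric",
                   startTime = "numeric"))

setValidity("Injection", function(object) {
    if (object@amount <= 0) return("'amount' must be > 0")
    if (object@rate <= 0) return("'rate' must be > 0")
    TRUE
})

#' Construct an Injection
#'
#' Defaults follow the standard automated protocol: 4 mL at 16 mL/s.
#'
#' @param amount contrast volume (mL).
#' @param rate injection rate (mL/s).
#' @param startTime injection start (s).
#' @return An \linkS4class{Injection}.
#' @export
Injection <- function(amount = 4, rate = 16, startTime = 0.5) {
    new("Injection", amount = as.numeric(amount), rate = as.numeric(rate),
        startTime = as.numeric(startTime))
}

#' CciaResult: the contrast-intensity index and its ingredient AUCs
#'
#' @slot aucProximal time-intensity AUC in the proximal region (signal * s).
#' @slot aucStenotic time-intensity AUC in the stenotic region (signal * s).
#' @slot ccia the index, \code{aucStenotic / aucProximal}; values below 1
#'   indicate reduced contrast passage through the lesion.
#' @slot window integration window c(tStart, tEnd), seconds (may be NA).
#' @slot curves list of the two \linkS4class{TimeIntensityCurve}s
#'   (\code{proximal}, \code{stenotic}) when computed from a stack.
#' @export
setClass("CciaResult",
    representation(aucProximal = "numeric", aucStenotic = "numeric",
                   ccia = "numeric", window = "numeric", curves = "list"))

setValidity("CciaResult", function(object) {
    v <- c(object@aucProximal, object@aucStenotic, object@ccia)
    if (any(!is.finite(v)) || any(v <= 0))
        return("AUCs and ccia must be finite and > 0")
    if (abs(object@ccia - object@aucStenotic / object@aucProximal) >
        1e-12 * max(1, object@ccia))
        return("'ccia' must equal aucStenotic / aucProximal")
    TRUE
})

#' FfrResult: cycle-averaged fractional flow reserve
#'
#' @slot meanPa cycle-averaged aortic pressure, mmHg.
#' @slot meanPd cycle-averaged distal pressure, mmHg.
#' @slot ffr (meanPd - pv) / (meanPa - pv).
#' @slot pv venous pressure used, mmHg.
#' @slot nCycles number of cardiac cycles averaged.
#' @export
setClass("FfrResult",
    representation(meanPa = "numeric", meanPd = "numeric", ffr = "numeric",
                   pv = "numeric", nCycles = "integer"))

setValidity("FfrResult", function(object) {
    expect <- (object@meanPd - object@pv) / (object@meanPa - object@pv)
    if (!is.finite(object@ffr) || abs(object@ffr - expect) > 1e-12)
        return("'ffr' must equal (meanPd - pv) / (meanPa - pv)")
    TRUE
})

#' RPeakSet: detected ECG R peaks and R-R statistics
#'
#' @slot peakTimes R-peak times, seconds, strictly increasing (>= 2 peaks).
#' @slot meanRr mean R-R interval, seconds.
#' @slot rrCv coefficient of variation of the R-R intervals.
#' @export
setClass("RPeakSet",
    representation(peakTimes = "numeric", meanRr = "numeric",
                   rrCv = "numeric"))

setValidity("RPeakSet", function(object) {
    if (length(object@peakTimes) < 2L) return("need at least 2 peaks")
    if (!.strictlyIncreasing(object@peakTimes))
        return("'peakTimes' must be strictly increasing")
    if (object@meanRr <= 0) return("'meanRr' must be > 0")
    TRUE
})

#' MotionTrack: per-frame rigid displacements relative to a reference frame
#'
#' @slot displacements n x 2 matrix of (dy, dx) in pixels; the displacement
#'   of the reference frame is (0, 0).
#' @slot scores per-frame normalized cross-correlation peak, in [-1, 1].
#' @slot referenceFrame index of the reference frame.
#' @slot phases per-frame cardiac phase in [0, 1), NA when unphased.
#' @export
setClass("MotionTrack",
    representation(displacements = "matrix", scores = "numeric",
                   referenceFrame = "integer", phases = "numeric"))

setValidity("MotionTrack", function(object) {
    n <- nrow(object@displacements)
    if (ncol(object@displacements) != 2L)
        return("'displacements' must be an n x 2 matrix")
    if (length(object@scores) != n)
        return("one score per frame required")
    if (any(abs(object@scores) > 1 + 1e-9, na.rm = TRUE))
        return("scores must lie in [-1, 1]")
    rf <- object@referenceFrame
    if (rf < 1L || rf > n) return("'referenceFrame' out of range")
    if (any(abs(object@displacements[rf, ]) > 1e-9))
        return("reference-frame displacement must be (0, 0)")
    if (length(object@phases) > 0L && length(object@phases) != n)
        return("'phases', when present, must have one entry per frame")
    TRUE
})

#' Construct a MotionTrack
#'
#' @param displacements n x 2 matrix (dy, dx) in pixels.
#' @param scores per-frame match scores in [-1, 1]; default 1.
#' @param referenceFrame reference frame index.
#' @param phases optional per-frame cardiac phases.
#' @return A \linkS4class{MotionTrack}.
#' @export
MotionTrack <- function(displacements, scores = rep(1, nrow(displacements)),
                        referenceFrame = 1L, phases = numeric(0)) {
    storage.mode(displacements) <- "double"
    new("MotionTrack", displacements = displacements,
        scores = as.numeric(scores),
        referenceFrame = as.integer(referenceFrame),
        phases = as.numeric(phases))
}

#' StenosisGeometry: axisymmetric stenosis phantom parameterization
#'
#' An idealized straight vessel of normal diameter r carrying a lesion with
#' a linear inlet taper (length li), a constant-diameter throat of diameter
#' h = hOverR * r and length xs, and a linear outlet taper (length lo).
#' Percent diameter stenosis is 100 * (1 - h/r) by definition.
#'
#' @slot hOverR stenotic-to-normal diameter ratio, in (0, 1].
#' @slot percentDs percent diameter stenosis, = 100 * (1 - hOverR).
#' @slot li inlet taper length, mm.
#' @slot xs constant-stenosis length, mm.
#' @slot lo outlet taper length, mm.
#' @slot normalDiameter normal vessel diameter, mm (default 3).
#' @slot totalLength li + xs + lo, mm.
#' @export
setClass("StenosisGeometry",
    representation(hOverR = "numeric", percentDs = "numeric", li = "numeric",
                   xs = "numeric", lo = "numeric", normalDiameter = "numeric",
                   totalLength = "numeric"))

setValidity("StenosisGeometry", function(object) {
    if (object@hOverR <= 0 || object@hOverR > 1)
        return("'hOverR' must lie in (0, 1]")
    if (abs(object@percentDs - 100 * (1 - object@hOverR)) > 1e-6)
        return("'percentDs' must equal 100 * (1 - hOverR)")
    if (object@li < 0 || object@lo < 0 || object@xs < 0)
        return("taper and throat lengths must be >= 0")
    if (abs(object@totalLength - (object@li + object@xs + object@lo)) > 1e-9)
        return("'totalLength' must equal li + xs + lo")
    if (object@normalDiameter <= 0) return("'normalDiameter' must be > 0")
    TRUE
})

#' Construct a StenosisGeometry
#'
#' @param hOverR stenotic-to-normal diameter ratio in (0, 1].
#' @param li,xs,lo inlet taper, constant-throat and outlet taper lengths (mm).
#' @param normalDiameter normal vessel diameter (mm).
#' @return A \linkS4class{StenosisGeometry}.
#' @examples
#' stenosisGeometry(0.5, xs = 12)  # 50% diameter stenosis, 18 mm lesion
#' @export
stenosisGeometry <- function(hOverR, li = 3, xs = 0, lo = 3,
                             normalDiameter = 3) {
    new("StenosisGeometry", hOverR = as.numeric(hOverR),
        percentDs = round(100 * (1 - as.numeric(hOverR)), 9),
        li = as.numeric(li), xs = as.numeric(xs), lo = as.numeric(lo),
        normalDiameter = as.numeric(normalDiameter),
        totalLength = as.numeric(li + xs + lo))
}

#' FlowWaveform: pulsatile coronary flow waveform
#'
#' Velocity in the normal segment: a constant diastolic base plus a half-sine
#' systolic bump occupying \code{systolicFraction} of each cycle, scaled so
#' the period-mean equals \code{meanVelocity} exactly. \code{baseFraction}
#' sets the diastolic base as a fraction of the mean; \code{baseFraction = 1}
#' gives constant (non-pulsatile) flow.
#'
#' @slot meanVelocity period-mean velocity in the normal segment, cm/s.
#' @slot heartRate beats per minute.
#' @slot systolicFraction fraction of the cycle occupied by the systolic
#'   bump (the pump output-phase ratio), in (0, 1].
#' @slot baseFraction diastolic base velocity / mean velocity, in [0, 1].
#' @export
setClass("FlowWaveform",
    representation(meanVelocity = "numeric", heartRate = "numeric",
                   systolicFraction = "numeric", baseFraction = "numeric"))

setValidity("FlowWaveform", function(object) {
    if (object@meanVelocity <= 0) return("'meanVelocity' must be > 0")
    if (object@heartRate <= 0) return("'heartRate' must be > 0")
    if (object@systolicFraction <= 0 || object@systolicFraction > 1)
        return("'systolicFraction' must lie in (0, 1]")
    if (object@baseFraction < 0 || object@baseFraction > 1)
        return("'baseFraction' must lie in [0, 1]")
    TRUE
})

#' Construct a FlowWaveform
#'
#' Defaults reproduce the bench circulation settings: 25 cm/s mean velocity,
#' 60 bpm, 60\% output phase ratio.
#'
#' @param meanVelocity mean velocity, cm/s.
#' @param heartRate heart rate, bpm.
#' @param systolicFraction systolic fraction of the cycle.
#' @param baseFraction diastolic base as a fraction of the mean (1 = constant
#'   flow).
#' @return A \linkS4class{FlowWaveform}.
#' @export
flowWaveform <- function(meanVelocity = 25, heartRate = 60,
                         systolicFraction = 0.6, baseFraction = 0.6) {
    new("FlowWaveform", meanVelocity = as.numeric(meanVelocity),
        heartRate = as.numeric(heartRate),
        systolicFraction = as.numeric(systolicFraction),
        baseFraction = as.numeric(baseFraction))
}

#' Constant (non-pulsatile) flow waveform
#'
#' @param meanVelocity velocity, cm/s.
#' @param heartRate nominal heart rate retained for cycle bookkeeping, bpm.
#' @return A \linkS4class{FlowWaveform} with zero pulsation.
#' @export
constantFlow <- function(meanVelocity = 25, heartRate = 60)
    flowWaveform(meanVelocity, heartRate, baseFraction = 1)

#' SimConfig: full configuration of the in-silico phantom
#'
#' @slot geometry a \linkS4class{StenosisGeometry}.
#' @slot flow a \linkS4class{FlowWaveform}.
#' @slot injection an \linkS4class{Injection}.
#' @slot gridDx axial grid spacing, mm.
#' @slot dispersionCoeff axial dispersion coefficient, mm^2/s.
#' @slot frameRate rendered frame rate, fps.
#' @slot duration acquisition duration, s (frameRate * duration frames).
#' @slot mmPerPx rendered pixel calibration, mm per pixel.
#' @slot noiseSd additive Gaussian detector noise SD, intensity units.
#' @slot seed RNG seed for rendering noise.
#' @slot domainLength modeled vessel length, mm; the lesion center sits at
#'   0.65 * domainLength so the proximal region and its 10 mm offset fit
#'   upstream for every lesion length.
#' @slot delayLength upstream tubing between injector and modeled inlet, mm
#'   (pure transport delay plus pre-dispersion).
#' @slot injectionSpreadSd temporal smoothing SD of the injected bolus after
#'   upstream transit, s; the 0.5 s default approximates laminar shear
#'   stretching over the injector tubing (full width ~ tubing length /
#'   (2 x mean velocity) = 1 s).
#' @slot background rendered background intensity level.
#' @slot gain rendered attenuation per unit concentration per mm of lumen
#'   chord.
#' @export
setClass("SimConfig",
    representation(geometry = "StenosisGeometry", flow = "FlowWaveform",
                   injection = "Injection", gridDx = "numeric",
                   dispersionCoeff = "numeric", frameRate = "numeric",
                   duration = "numeric", mmPerPx = "numeric",
                   noiseSd = "numeric", seed = "integer",
                   domainLength = "numeric", delayLength = "numeric",
                   injectionSpreadSd = "numeric", background = "numeric",
                   gain = "numeric"))

setValidity("SimConfig", function(object) {
    if (object@gridDx <= 0) return("'gridDx' must be > 0")
    if (object@dispersionCoeff < 0) return("'dispersionCoeff' must be >= 0")
    nf <- object@duration * object@frameRate
    if (abs(nf - round(nf)) > 1e-9)
        return("duration * frameRate must be a whole number of frames")
    if (object@mmPerPx <= 0) return("'mmPerPx' must be > 0")
    if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
    if (object@domainLength < object@geometry@totalLength)
        return("'domainLength' must exceed the lesion length")
    if (object@background <= 0 || object@gain <= 0)
        return("'background' and 'gain' must be > 0")
    TRUE
})

#' Construct a SimConfig
#'
#' Defaults reproduce the bench acquisition: 300 frames at 30 fps over 10 s,
#' 4 mL of contrast injected at 16 mL/s through 500 mm of upstream tubing,
#' pulsatile flow at 25 cm/s mean and 60 bpm.
#'
#' @param geometry a \linkS4class{StenosisGeometry}.
#' @param flow a \linkS4class{FlowWaveform}.
#' @param injection an \linkS4class{Injection}.
#' @param gridDx grid spacing (mm).
#' @param dispersionCoeff dispersion coefficient (mm^2/s).
#' @param frameRate frames per second.
#' @param duration acquisition length (s).
#' @param mmPerPx render calibration (mm/px).
#' @param noiseSd detector noise SD (intensity units).
#' @param seed RNG seed.
#' @param domainLength modeled vessel length (mm).
#' @param delayLength upstream tubing length (mm).
#' @param injectionSpreadSd bolus temporal smoothing SD (s).
#' @param background rendered background level.
#' @param gain rendered attenuation gain.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(geometry = stenosisGeometry(0.5, xs = 12),
                      flow = flowWaveform(), injection = Injection(),
                      gridDx = 0.5, dispersionCoeff = 1, frameRate = 30,
                      duration = 10, mmPerPx = 0.2, noiseSd = 10,
                      seed = 1L, domainLength = 100, delayLength = 500,
                      injectionSpreadSd = 0.5, background = 3000,
                      gain = 150) {
    new("SimConfig", geometry = geometry, flow = flow, injection = injection,
        gridDx = as.numeric(gridDx),
        dispersionCoeff = as.numeric(dispersionCoeff),
        frameRate = as.numeric(frameRate), duration = as.numeric(duration),
        mmPerPx = as.numeric(mmPerPx), noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed), domainLength = as.numeric(domainLength),
        delayLength = as.numeric(delayLength),
        injectionSpreadSd = as.numeric(injectionSpreadSd),
        background = as.numeric(background), gain = as.numeric(gain))
}

#' ConcentrationField: solved bolus concentration on the axial grid
#'
#' Output of \code{\link{advectBolus}}: cross-section-averaged contrast
#' concentration C(x, t) (mL contrast per mL fluid) at cell centers and
#' frame times, with mass bookkeeping for conservation checks.
#'
#' @slot concentration nCells x nTimes matrix of concentrations.
#' @slot x axial cell-center positions, mm.
#' @slot times frame times, s.
#' @slot area lumen cross-section area at cell centers, mm^2.
#' @slot massIn cumulative injected tracer at each frame time, mL.
#' @slot massOut cumulative tracer leaving the outlet at each frame time, mL.
#' @slot flowAt function of t returning volumetric flow, mL/s.
#' @export
setClass("ConcentrationField",
    representation(concentration = "matrix", x = "numeric",
                   times = "numeric", area = "numeric", massIn = "numeric",
                   massOut = "numeric", flowAt = "function"))

#' CorrelationReport: Pearson correlation with the least-squares line
#'
#' @slot r Pearson product-moment coefficient.
#' @slot pValue two-sided p-value (t transform, n - 2 df).
#' @slot n sample size.
#' @slot slope,intercept ordinary least-squares fit of y on x.
#' @export
setClass("CorrelationReport",
    representation(r = "numeric", pValue = "numeric", n = "integer",
                   slope = "numeric", intercept = "numeric"))

setValidity("CorrelationReport", function(object) {
    if (abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
    if (object@n < 3L) return("'n' must be >= 3")
    TRUE
})

#' ReplicateSummary: mean and sample SD of replicate measurements
#'
#' @slot mean mean of the replicates.
#' @slot sd sample standard deviation (n - 1 denominator); NA when n < 2.
#' @slot n number of replicates.
#' @export
setClass("ReplicateSummary",
    representation(mean = "numeric", sd = "numeric", n = "integer"))
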