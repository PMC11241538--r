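#' The nine bench stenosis geometries
#'
#' Diameter ratios h/r of 0.3, 0.5 and 0.7 (70/50/30 percent diameter
#' stenosis) crossed with total lesion lengths of 6, 18 and 30 mm (constant
#' throat of 0, 12, 24 mm between 3 mm tapers).
#'
#' @return A list of nine \linkS4class{StenosisGeometry} objects.
#' @export
benchGeometries <- function() {
    out <- list()
    for (h in c(0.3, 0.5, 0.7))
        for (xs in c(0, 12, 24))
            out[[length(out) + 1L]] <- stenosisGeometry(h, li = 3, xs = xs,
                                                        lo = 3)
    out
}

.lesionStart <- function(geometry, domainLength)
    0.65 * domainLength - geometry@totalLength / 2

#' Lumen diameter along the phantom axis
#'
#' Normal diameter outside the lesion; linear inlet taper down to
#' h = hOverR * normal diameter over \code{li}; constant throat over
#' \code{xs}; linear outlet taper back over \code{lo}. The lesion center
#' sits at 0.65 x \code{domainLength}, leaving room upstream for the
#' proximal measurement region.
#'
#' @param geometry a \linkS4class{StenosisGeometry}.
#' @param x axial position(s), mm, in [0, domainLength].
#' @param domainLength modeled vessel length, mm.
#' @return Lumen diameter(s), mm.
#' @examples
#' diameterProfile(stenosisGeometry(0.3), 65)  # mid-throat: 0.9 mm
#' @export
diameterProfile <- function(geometry, x, domainLength = 100) {
    stopifnot(is(geometry, "StenosisGeometry"))
    if (any(x < -1e-9) || any(x > domainLength + 1e-9))
        stop("'x' outside the [0, ", domainLength, "] mm domain")
    r <- geometry@normalDiameter
    h <- geometry@hOverR * r
    s0 <- .lesionStart(geometry, domainLength)
    a1 <- s0 + geometry@li                 # throat start
    a2 <- a1 + geometry@xs                 # throat end
    a3 <- a2 + geometry@lo                 # lesion end
    d <- rep(r, length(x))
    if (geometry@li > 0) {
        sel <- x >= s0 & x < a1
        d[sel] <- r + (h - r) * (x[sel] - s0) / geometry@li
    }
    sel <- x >= a1 & x <= a2
    d[sel] <- h
    if (geometry@lo > 0) {
        sel <- x > a2 & x <= a3
        d[sel] <- h + (r - h) * (x[sel] - a2) / geometry@lo
    }
    d
}

#' Pulsatile flow velocity and volumetric flow
#'
#' The velocity waveform is a constant diastolic base plus a half-sine
#' systolic bump over the systolic fraction of each cycle, scaled so its
#' period mean equals the configured mean velocity exactly.
#'
#' @param flow a \linkS4class{FlowWaveform}.
#' @param t time(s), s (>= 0).
#' @return \code{flowVelocity}: velocity in the normal segment, cm/s.
#' @export
flowVelocity <- function(flow, t) {
    stopifnot(is(flow, "FlowWaveform"))
    period <- 60 / flow@heartRate
    phase <- (t %% period) / period
    vd <- flow@baseFraction * flow@meanVelocity
    a <- (flow@meanVelocity - vd) * pi / (2 * flow@systolicFraction)
    v <- rep(vd, length(t))
    sel <- phase < flow@systolicFraction
    v[sel] <- vd + a * sin(pi * phase[sel] / flow@systolicFraction)
    v
}

#' @rdname flowVelocity
#' @param diameterMm vessel diameter used to convert velocity to flow, mm.
#' @return \code{pulsatileFlow}: volumetric flow, mL/s.
#' @export
pulsatileFlow <- function(flow, t, diameterMm = 3) {
    area <- pi * (diameterMm / 20)^2      # cm^2
    flowVelocity(flow, t) * area          # cm/s * cm^2 = mL/s
}

# smoothed injection rate (mL tracer / s) after upstream tubing transit:
# a boxcar of length amount/rate convolved with a Gaussian of SD sigma
.sourceRate <- function(injection, arrival, sigma, t) {
    tInj <- injection@amount / injection@rate
    injection@rate * (stats::pnorm(t, arrival, sigma) -
                      stats::pnorm(t, arrival + tInj, sigma))
}

#' Simulate contrast bolus transport through the phantom
#'
#' Mass-conserving finite-volume solution of the cross-section-averaged
#' advection-dispersion equation with upwind advection, an open outflow
#' boundary and the injection entering the inlet as a smoothed source (the
#' upstream injector tubing is modeled as a pure transport delay at the
#' mean velocity plus Gaussian temporal spreading). Internal sub-stepping
#' is chosen automatically for CFL stability; an unstable configuration
#' raises an error rather than being silently clipped.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{ConcentrationField} sampled at the frame times.
#' @export
advectBolus <- function(config) {
    stopifnot(is(config, "SimConfig"))
    g <- config@geometry
    dx <- config@gridDx
    n <- round(config@domainLength / dx)
    x <- (seq_len(n) - 0.5) * dx
    A <- pi * (diameterProfile(g, x, config@domainLength) / 2)^2   # mm^2
    vol <- A * dx / 1000                                           # mL
    aFace <- (A[-n] + A[-1L]) / 2

    nf <- round(config@duration * config@frameRate)
    frameDt <- 1 / config@frameRate
    qPeak <- max(pulsatileFlow(config@flow,
                               seq(0, 60 / config@flow@heartRate,
                                   length.out = 512),
                               g@normalDiameter))
    uMax <- qPeak * 1000 / min(A)                                  # mm/s
    dtMax <- 0.45 * dx / uMax
    if (config@dispersionCoeff > 0)
        dtMax <- min(dtMax, 0.25 * dx^2 / config@dispersionCoeff)
    nsub <- max(1L, ceiling(frameDt / dtMax))
    dt <- frameDt / nsub

    tSub <- (seq_len((nf - 1L) * nsub) - 0.5) * dt
    q <- pulsatileFlow(config@flow, tSub, g@normalDiameter)
    arrival <- config@injection@startTime +
        config@delayLength / (config@flow@meanVelocity * 10)
    src <- .sourceRate(config@injection, arrival, config@injectionSpreadSd,
                       tSub)
    # when the smeared bolus completes within the record, rescale so the
    # full injected amount enters (the Gaussian smearing must not leak
    # tracer outside the simulated window)
    tEnd <- arrival + config@injection@amount / config@injection@rate +
        4 * config@injectionSpreadSd
    if (tEnd <= config@duration && sum(src) > 0)
        src <- src * config@injection@amount / (sum(src) * dt)
    res <- .advectCore(vol, aFace, dx, config@dispersionCoeff, q, src, dt,
                       nsub, nf - 1L)
    if (isTRUE(res$unstable))
        stop("unstable transport configuration: refine 'gridDx' or check ",
             "the flow settings")
    flow <- config@flow
    dn <- g@normalDiameter
    new("ConcentrationField",
        concentration = cbind(0, res$conc),
        x = x, times = (seq_len(nf) - 1L) * frameDt, area = A,
        massIn = c(0, res$massIn), massOut = c(0, res$massOut),
        flowAt = function(t) pulsatileFlow(flow, t, dn))
}

#' Concentration time-course and AUC at an axial station
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @param xMm axial station, mm.
#' @return \code{stationCurve}: a \linkS4class{TimeIntensityCurve} of the
#'   concentration at the nearest grid cell; \code{stationAuc}: its full
#'   trapezoidal AUC (concentration * s).
#' @export
stationCurve <- function(field, xMm) {
    stopifnot(is(field, "ConcentrationField"))
    i <- which.min(abs(field@x - xMm))
    TimeIntensityCurve(field@times, pmax(0, field@concentration[i, ]))
}

#' @rdname stationCurve
#' @export
stationAuc <- function(field, xMm) curveAuc(stationCurve(field, xMm))

#' Tracer mass balance of a simulated field
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @return data.frame with, per frame time: cumulative injected mass,
#'   cumulative outflow mass, mass in the domain and the relative
#'   conservation error (inDomain + out - in) / max(in).
#' @export
massBalance <- function(field) {
    stopifnot(is(field, "ConcentrationField"))
    vol <- field@area * diff(field@x[1:2]) / 1000
    inDomain <- colSums(field@concentration * vol)
    err <- (inDomain + field@massOut - field@massIn) /
        max(field@massIn, .Machine$double.eps)
    data.frame(time = field@times, massIn = field@massIn,
               massOut = field@massOut, inDomain = inDomain,
               relError = err)
}

# smooth seeded random field for background anatomy texture
.smoothField <- function(ny, nx, sdPx = 3, amplitude = 300) {
    pad <- 3L * sdPx
    f <- matrix(stats::rnorm((ny + 2 * pad) * (nx + 2 * pad)),
                ny + 2 * pad, nx + 2 * pad)
    k <- stats::dnorm(seq(-pad, pad), sd = sdPx)
    k <- k / sum(k)
    f <- apply(f, 2L, function(col) stats::filter(col, k, sides = 2))
    f <- t(apply(f, 1L, function(row) stats::filter(row, k, sides = 2)))
    f <- f[pad + seq_len(ny), pad + seq_len(nx)]
    f[is.na(f)] <- 0
    amplitude * f / stats::sd(f)
}

#' Render a concentration field as an angiographic frame stack
#'
#' Straight-vessel projection model: each pixel's attenuation is the local
#' concentration times the chord length of the circular lumen along the
#' projection ray, scaled by the gain; frames are background minus
#' attenuation plus additive Gaussian detector noise, clipped at 0 and
#' quantized to integer intensity counts.
#'
#' @param field a \linkS4class{ConcentrationField}.
#' @param config the \linkS4class{SimConfig} used to generate the field.
#' @param backgroundField optional matrix added to the flat background
#'   (static anatomy texture); must match the rendered frame size.
#' @param motion optional nFrames x 2 matrix of (dy, dx) scene translations
#'   per frame, px (applied before noise).
#' @param setSeed set the RNG from \code{config@@seed} (default TRUE);
#'   internal callers that manage the seed themselves pass FALSE.
#' @return A \linkS4class{FrameStack}.
#' @export
renderFrames <- function(field, config, backgroundField = NULL,
                         motion = NULL, setSeed = TRUE) {
    stopifnot(is(field, "ConcentrationField"), is(config, "SimConfig"))
    if (setSeed) set.seed(config@seed)
    g <- config@geometry
    nx <- round(config@domainLength / config@mmPerPx)
    ny <- round(3 * g@normalDiameter / config@mmPerPx)
    xCol <- (seq_len(nx) - 0.5) * config@mmPerPx
    yOff <- (seq_len(ny) - (ny + 1) / 2) * config@mmPerPx
    d <- diameterProfile(g, xCol, config@domainLength)
    chord <- outer(yOff, d, function(y, dd) {
        h2 <- (dd / 2)^2 - y^2
        2 * sqrt(pmax(0, h2))
    })
    bg <- matrix(config@background, ny, nx)
    if (!is.null(backgroundField)) {
        if (!identical(dim(backgroundField), dim(bg)))
            stop("'backgroundField' must be ", ny, " x ", nx)
        bg <- bg + backgroundField
    }
    nf <- length(field@times)
    frames <- array(0, c(ny, nx, nf))
    for (k in seq_len(nf)) {
        cc <- stats::approx(field@x, field@concentration[, k], xout = xCol,
                            rule = 2)$y
        scene <- bg - config@gain * chord *
            matrix(cc, ny, nx, byrow = TRUE)
        if (!is.null(motion) && any(motion[k, ] != 0))
            # move scene content BY (dy, dx): sample the source at p - d
            scene <- .translateFrame(scene, -motion[k, 1L],
                                     -motion[k, 2L])$frame
        if (config@noiseSd > 0)
            scene <- scene + stats::rnorm(length(scene), sd = config@noiseSd)
        frames[, , k] <- round(pmax(0, scene))
    }
    FrameStack(frames, times = field@times, mmPerPx = config@mmPerPx,
               frameRate = config@frameRate)
}

#' Simulate a complete static angiographic acquisition
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{FrameStack}.
#' @export
simulateStack <- function(config) renderFrames(advectBolus(config), config)

#' Ground-truth ROI specification for a rendered phantom
#'
#' The stenotic mask covers the nominal lesion axial extent across the full
#' normal lumen width; the centerline runs along the vessel axis from
#' inflow (left) to outflow (right).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{RoiSpec} matching \code{\link{renderFrames}}
#'   output.
#' @export
phantomRoi <- function(config) {
    g <- config@geometry
    nx <- round(config@domainLength / config@mmPerPx)
    ny <- round(3 * g@normalDiameter / config@mmPerPx)
    xCol <- (seq_len(nx) - 0.5) * config@mmPerPx
    yOff <- (seq_len(ny) - (ny + 1) / 2) * config@mmPerPx
    s0 <- .lesionStart(g, config@domainLength)
    cols <- xCol >= s0 & xCol <= s0 + g@totalLength
    rows <- abs(yOff) <= g@normalDiameter / 2
    mask <- outer(rows, cols, "&")
    yc <- (ny + 1) / 2
    RoiSpec(mask, cbind(rep(yc, nx), seq_len(nx)), config@mmPerPx)
}

#' Synthetic pressure traces for a phantom configuration
#'
#' The distal bed is modeled as a fixed microvascular resistance anchored
#' so the distal pressure is 100 mmHg at the nominal mean flow; the
#' stenosis adds a Poiseuille (viscous) pressure drop integrated over the
#' diameter profile in excess of a same-length normal vessel (the shared
#' tubing gradient cancels between the two measurement sites just across
#' the lesion) plus a Borda-Carnot sudden-expansion loss at the outlet,
#' both evaluated at the instantaneous flow. Hence
#' Pd(t) = Rd * Q(t) and Pa(t) = Pd(t) + dP(Q(t)), which keeps
#' 0 < Pd <= Pa pointwise and makes the pressure drop strictly increasing
#' in stenosis severity and length.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param duration trace length, s (default 12: two settling cycles plus
#'   the 10 averaged ones at 60 bpm).
#' @param samplingRate Hz.
#' @param viscosity perfusate dynamic viscosity, Pa s (default 4.5 cP).
#' @param density perfusate density, kg/m^3.
#' @param pdNominal distal pressure at nominal mean flow, mmHg.
#' @return A \linkS4class{PressureTraces}.
#' @export
simulatePressures <- function(config, duration = 12, samplingRate = 500,
                              viscosity = 4.5e-3, density = 1050,
                              pdNominal = 100) {
    stopifnot(is(config, "SimConfig"))
    g <- config@geometry
    t <- seq(0, duration, by = 1 / samplingRate)
    qMl <- pulsatileFlow(config@flow, t, g@normalDiameter)    # mL/s
    qSi <- qMl * 1e-6                                         # m^3/s

    # lesion-specific viscous resistance: the Poiseuille integral over the
    # diameter profile in excess of the same-length normal vessel (the
    # pressure sensors sit just across the lesion, so the shared tubing
    # drop cancels between the two measurement sites)
    dxf <- config@gridDx / 4
    xf <- seq(dxf / 2, config@domainLength - dxf / 2, by = dxf)
    dM <- diameterProfile(g, xf, config@domainLength) * 1e-3  # m
    dN <- g@normalDiameter * 1e-3
    rVisc <- sum(128 * viscosity / pi * (1 / dM^4 - 1 / dN^4) *
                 dxf * 1e-3)                                  # Pa s / m^3

    aN <- pi * (g@normalDiameter * 1e-3 / 2)^2
    aT <- pi * (g@hOverR * g@normalDiameter * 1e-3 / 2)^2
    dP <- rVisc * qSi
    if (g@hOverR < 1)
        dP <- dP + 0.5 * density * (qSi / aT - qSi / aN)^2    # expansion loss

    qNom <- config@flow@meanVelocity * (aN * 1e4) * 1e-6      # m^3/s
    rd <- pdNominal * 133.322 / qNom                          # Pa s / m^3
    pd <- rd * qSi / 133.322                                  # mmHg
    pa <- pd + dP / 133.322
    PressureTraces(t, pa, pd, pv = 0)
}

#' Simulate a moving (in vivo style) acquisition with ground truth
#'
#' Renders the phantom with a static anatomy texture, then applies a smooth
#' cardiac-phase-locked translation to every frame; emits a synthetic ECG
#' with R peaks exactly at the cycle starts and the exact per-frame
#' displacements (relative to the first frame, which carries zero motion)
#' as ground truth. A motion-free render of the same scene is included for
#' end-to-end comparisons.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param motionAmplitude peak-to-peak vertical excursion, px.
#' @param ecgNoiseSd additive ECG noise SD (R-spike amplitude is 1).
#' @param textureAmplitude SD of the background anatomy texture, intensity
#'   units.
#' @param ecgSamplingRate Hz.
#' @return A list with \code{stack} (moving), \code{staticStack},
#'   \code{ecg} (\linkS4class{EcgTrace}), \code{track} (ground-truth
#'   \linkS4class{MotionTrack}) and \code{rPeakTimes}.
#' @export
simulateInvivo <- function(config, motionAmplitude = 5, ecgNoiseSd = 0.02,
                           textureAmplitude = 300, ecgSamplingRate = 500) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    field <- advectBolus(config)
    g <- config@geometry
    nx <- round(config@domainLength / config@mmPerPx)
    ny <- round(3 * g@normalDiameter / config@mmPerPx)
    texture <- .smoothField(ny, nx, sdPx = 3, amplitude = textureAmplitude)

    period <- 60 / config@flow@heartRate
    ft <- field@times
    phi <- ft / period
    traj <- cbind(motionAmplitude * 0.5 * (1 - cos(2 * pi * phi)),
                  0.3 * motionAmplitude * sin(2 * pi * phi))

    staticStack <- renderFrames(field, config, backgroundField = texture,
                                setSeed = FALSE)
    moving <- renderFrames(field, config, backgroundField = texture,
                           motion = traj, setSeed = FALSE)

    te <- seq(0, config@duration, by = 1 / ecgSamplingRate)
    rPeaks <- seq(0, config@duration, by = period)
    volt <- rep(0, length(te))
    for (tk in rPeaks) volt <- volt + exp(-(te - tk)^2 / (2 * 0.012^2))
    volt <- volt + 0.15 * sin(2 * pi * te / period + 1) +
        stats::rnorm(length(te), sd = ecgNoiseSd)
    ecg <- EcgTrace(te, volt, ecgSamplingRate)

    track <- MotionTrack(sweep(traj, 2L, traj[1L, ]), referenceFrame = 1L)
    list(stack = moving, staticStack = staticStack, ecg = ecg,
         track = track, rPeakTimes = rPeaks)
}

#' Run the full phantom grid
#'
#' Simulates every supplied geometry (default: the nine bench models),
#' renders \code{replicates} noisy acquisitions each, computes CCIA from
#' the rendered stacks and FFR from the synthetic pressure traces, and
#' returns a tidy results table.
#'
#' @param geometries list of \linkS4class{StenosisGeometry} objects.
#' @param replicates acquisitions per geometry (default 3).
#' @param seed base RNG seed; replicate seeds are derived from it.
#' @param noiseSd rendering noise SD (0 for noise-free).
#' @param config template \linkS4class{SimConfig}; its geometry, seed and
#'   noise are overridden per run.
#' @return data.frame with columns \code{length}, \code{percent_ds},
#'   \code{replicate}, \code{ccia}, \code{ffr}.
#' @export
runGrid <- function(geometries = benchGeometries(), replicates = 3,
                    seed = 1L, noiseSd = 10, config = simConfig()) {
    rows <- list()
    for (gi in seq_along(geometries)) {
        g <- geometries[[gi]]
        cfg <- config
        cfg@geometry <- g
        cfg@noiseSd <- as.numeric(noiseSd)
        validObject(cfg)
        field <- advectBolus(cfg)
        roi <- phantomRoi(cfg)
        fr <- computeFfr(simulatePressures(cfg),
                         period = 60 / cfg@flow@heartRate, nCycles = 10)
        nBase <- max(1L, floor(cfg@injection@startTime * cfg@frameRate))
        for (rep in seq_len(replicates)) {
            cfg@seed <- as.integer((seed * 97L + gi * 13L + rep) %% 2147483647L)
            stack <- renderFrames(field, cfg)
            cc <- computeCcia(stack, roi, baselineFrames = nBase,
                              window = c(cfg@injection@startTime,
                                         max(frameTimes(stack))))
            rows[[length(rows) + 1L]] <- data.frame(
                length = g@totalLength, percent_ds = g@percentDs,
                replicate = rep, ccia = cciaValue(cc), ffr = ffrValue(fr))
        }
    }
    do.call(rbind, rows)
}
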