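#' Detect R peaks in an ECG trace
#'
#' A compact QRS detector: 5-15 Hz Butterworth bandpass (zero-phase),
#' squared derivative envelope, moving-average smoothing, then peak picking
#' with a 0.25 s refractory period; each detection is refined to the local
#' maximum of the raw voltage within +/- 0.1 s.
#'
#' @param ecg an \linkS4class{EcgTrace} with sampling rate >= 100 Hz and at
#'   least 2 s of signal.
#' @param threshold envelope threshold as a fraction of the envelope
#'   maximum.
#' @return An \linkS4class{RPeakSet}; the R-R coefficient of variation uses
#'   the sample (n - 1) standard deviation.
#' @export
detectRPeaks <- function(ecg, threshold = 0.3) {
    stopifnot(is(ecg, "EcgTrace"))
    fs <- ecg@samplingRate
    if (fs < 100) stop("sampling rate must be >= 100 Hz")
    if (diff(range(ecg@times)) < 2) stop("need at least 2 s of ECG signal")
    v <- ecg@voltage
    if (stats::sd(v) < 1e-12) stop("flat ECG trace: no peaks found")
    bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
    f <- signal::filtfilt(bp, v)
    env <- c(diff(f), 0)^2
    w <- max(1L, round(0.15 * fs))
    env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
    env[is.na(env)] <- 0
    thr <- threshold * max(env)
    if (max(env) < 1e-12) stop("flat ECG trace: no peaks found")
    cand <- which(env > thr &
                  env >= c(-Inf, env[-length(env)]) &
                  env >= c(env[-1L], -Inf))
    if (length(cand) == 0L) stop("no QRS complexes found")
    refr <- round(0.25 * fs)
    peaks <- integer(0)
    for (i in cand) {
        if (length(peaks) == 0L || i - peaks[length(peaks)] > refr) {
            peaks <- c(peaks, i)
        } else if (env[i] > env[peaks[length(peaks)]]) {
            peaks[length(peaks)] <- i
        }
    }
    half <- as.integer(round(0.1 * fs))
    refined <- vapply(peaks, function(i) {
        lo <- max(1L, i - half); hi <- min(length(v), i + half)
        lo + which.max(v[lo:hi]) - 1L
    }, numeric(1))
    refined <- sort(unique(refined))
    if (length(refined) < 2L) stop("fewer than 2 R peaks found")
    pt <- ecg@times[refined]
    rr <- diff(pt)
    new("RPeakSet", peakTimes = pt, meanRr = mean(rr),
        rrCv = stats::sd(rr) / mean(rr))
}

#' Check for a normal sinus rhythm
#'
#' Motion stabilization assumes a regular cardiac cycle; this gate passes
#' when the R-R coefficient of variation is at or below the threshold
#' (inclusive).
#'
#' @param peaks an \linkS4class{RPeakSet}.
#' @param cvThreshold maximum acceptable R-R CV (default 0.10).
#' @return A list with \code{pass} (logical) and \code{message}.
#' @export
checkSinusRhythm <- function(peaks, cvThreshold = 0.10) {
    stopifnot(is(peaks, "RPeakSet"))
    pass <- peaks@rrCv <= cvThreshold
    list(pass = pass,
         message = sprintf(
             "R-R CV = %.4f (threshold %.2f): %s", peaks@rrCv, cvThreshold,
             if (pass) "normal sinus rhythm" else
                 "irregular rhythm - stabilization refused (use force = TRUE to override)"))
}

#' Assign a cardiac phase to each frame time
#'
#' phase(t) = (t - t_k) / (t_(k+1) - t_k) for the enclosing R-R interval;
#' frames outside the span of the detected peaks are unphased (NA).
#'
#' @param frameTimes frame acquisition times, s.
#' @param peaks an \linkS4class{RPeakSet}.
#' @return Numeric vector of phases in [0, 1), NA where unphased.
#' @export
assignCardiacPhase <- function(frameTimes, peaks) {
    stopifnot(is(peaks, "RPeakSet"))
    pt <- peaks@peakTimes
    k <- findInterval(frameTimes, pt)
    phase <- rep(NA_real_, length(frameTimes))
    ok <- k >= 1L & k < length(pt)
    phase[ok] <- (frameTimes[ok] - pt[k[ok]]) / (pt[k[ok] + 1L] - pt[k[ok]])
    atLast <- frameTimes == pt[length(pt)]
    phase[atLast] <- 0
    phase
}

# NCC between template vector (pre-centered) and a candidate patch
.nccSurface <- function(frame, tpl, y0, x0, h, w, r) {
    tv <- as.vector(tpl) - mean(tpl)
    tn <- sqrt(sum(tv^2))
    out <- matrix(-Inf, 2L * r + 1L, 2L * r + 1L)
    for (dy in -r:r) for (dx in -r:r) {
        p <- frame[(y0 + dy):(y0 + dy + h - 1L), (x0 + dx):(x0 + dx + w - 1L)]
        pv <- as.vector(p) - mean(p)
        pn <- sqrt(sum(pv^2))
        out[dy + r + 1L, dx + r + 1L] <-
            if (tn < 1e-12 || pn < 1e-12) 0 else sum(tv * pv) / (tn * pn)
    }
    out
}

# 1-D parabolic sub-sample refinement around an interior maximum
.parabolic <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (abs(den) < 1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (cm1 - cp1) / den))
}

#' Track a template across all frames by normalized cross-correlation
#'
#' For every frame the template (cut from the reference frame) is matched
#' over a (2r+1)^2 search window; the displacement is the NCC argmax,
#' refined to sub-pixel precision by separable parabolic interpolation of
#' the correlation peak. NCC is used because it is invariant to the global
#' intensity shifts that contrast passage induces.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param templateBox c(y0, x0, h, w): top-left corner (1-based) and size of
#'   the template in the reference frame.
#' @param searchRadius maximum displacement searched, px; must be at least
#'   the expected motion amplitude.
#' @param referenceFrame reference frame index (default 1).
#' @param phases optional per-frame cardiac phases to attach.
#' @return A \linkS4class{MotionTrack}; displacements are (dy, dx) of the
#'   anatomy in each frame relative to the reference frame.
#' @export
trackTemplate <- function(stack, templateBox, searchRadius,
                          referenceFrame = 1L, phases = numeric(0)) {
    stopifnot(is(stack, "FrameStack"), length(templateBox) == 4L)
    d <- dim(stack@frames)
    y0 <- templateBox[1L]; x0 <- templateBox[2L]
    h <- templateBox[3L]; w <- templateBox[4L]
    r <- as.integer(searchRadius)
    if (h > d[1L] || w > d[2L]) stop("template larger than the frame")
    if (y0 < 1L || x0 < 1L || y0 + h - 1L > d[1L] || x0 + w - 1L > d[2L])
        stop("template box out of bounds")
    if (y0 - r < 1L || x0 - r < 1L || y0 + h - 1L + r > d[1L] ||
        x0 + w - 1L + r > d[2L])
        stop("search window exits the frame; reduce 'searchRadius' or move the template")
    tpl <- stack@frames[y0:(y0 + h - 1L), x0:(x0 + w - 1L), referenceFrame]
    n <- d[3L]
    disp <- matrix(0, n, 2L)
    scores <- numeric(n)
    for (k in seq_len(n)) {
        if (k == referenceFrame) { scores[k] <- 1; next }
        s <- .nccSurface(stack@frames[, , k], tpl, y0, x0, h, w, r)
        ij <- which(s == max(s), arr.ind = TRUE)[1L, ]
        dy <- ij[1L] - r - 1L; dx <- ij[2L] - r - 1L
        sy <- sx <- 0
        exactMatch <- max(s) > 1 - 1e-9   # integer-perfect: do not refine
        if (!exactMatch && ij[1L] > 1L && ij[1L] < nrow(s))
            sy <- .parabolic(s[ij[1L] - 1L, ij[2L]], s[ij[1L], ij[2L]],
                             s[ij[1L] + 1L, ij[2L]])
        if (!exactMatch && ij[2L] > 1L && ij[2L] < ncol(s))
            sx <- .parabolic(s[ij[1L], ij[2L] - 1L], s[ij[1L], ij[2L]],
                             s[ij[1L], ij[2L] + 1L])
        disp[k, ] <- c(dy + sy, dx + sx)
        scores[k] <- max(-1, min(1, max(s)))
    }
    MotionTrack(disp, scores, referenceFrame = as.integer(referenceFrame),
                phases = phases)
}

# translate one frame by (dy, dx) with bilinear interpolation, edge clamp;
# returns list(frame, valid)
.translateFrame <- function(fr, dy, dx) {
    ny <- nrow(fr); nx <- ncol(fr)
    ys <- seq_len(ny) + dy
    xs <- seq_len(nx) + dx
    vy <- ys >= 1 & ys <= ny
    vx <- xs >= 1 & xs <= nx
    y0 <- pmin(pmax(floor(ys), 1L), ny); y1 <- pmin(y0 + 1L, ny)
    x0 <- pmin(pmax(floor(xs), 1L), nx); x1 <- pmin(x0 + 1L, nx)
    wy <- pmin(pmax(ys - y0, 0), 1)
    wx <- pmin(pmax(xs - x0, 0), 1)
    f00 <- fr[y0, x0, drop = FALSE]; f10 <- fr[y1, x0, drop = FALSE]
    f01 <- fr[y0, x1, drop = FALSE]; f11 <- fr[y1, x1, drop = FALSE]
    a <- f00 * (1 - wy) + f10 * wy
    b <- f01 * (1 - wy) + f11 * wy
    out <- sweep(a, 2L, 1 - wx, "*") + sweep(b, 2L, wx, "*")
    list(frame = out, valid = outer(vy, vx, "&"))
}

#' Invert tracked motion to obtain a static-vessel stack
#'
#' Each frame is translated by minus its tracked displacement (bilinear
#' interpolation for sub-pixel shifts; pixels whose source lies outside the
#' field of view are filled with replicated edge values and flagged FALSE
#' in the validity mask). Timestamps are unchanged. Stabilization refuses
#' to run when a sinus-rhythm check attached via \code{rhythm} fails,
#' unless \code{force = TRUE}.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param track a \linkS4class{MotionTrack} with one displacement per frame.
#' @param rhythm optional result of \code{\link{checkSinusRhythm}}.
#' @param force run even when \code{rhythm$pass} is FALSE.
#' @return A \linkS4class{StabilizedStack}.
#' @export
stabilize <- function(stack, track, rhythm = NULL, force = FALSE) {
    stopifnot(is(stack, "FrameStack"), is(track, "MotionTrack"))
    n <- nFrames(stack)
    if (nrow(track@displacements) != n)
        stop("track has ", nrow(track@displacements),
             " displacements for ", n, " frames")
    if (!is.null(rhythm) && !isTRUE(rhythm$pass) && !force)
        stop(rhythm$message)
    out <- stack@frames
    valid <- array(TRUE, dim(stack@frames))
    for (k in seq_len(n)) {
        d <- track@displacements[k, ]
        if (all(d == 0)) next
        tr <- .translateFrame(stack@frames[, , k], d[1L], d[2L])
        out[, , k] <- tr$frame
        valid[, , k] <- tr$valid
    }
    new("StabilizedStack", frames = out, times = stack@times,
        mmPerPx = stack@mmPerPx, frameRate = stack@frameRate,
        validityMask = valid)
}
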