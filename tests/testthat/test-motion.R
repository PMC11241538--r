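test_that("R peaks are found within 10 ms on a clean synthetic ECG", {
    ecg <- syntheticEcg(c(0.5, 1.5, 2.5))
    pk <- detectRPeaks(ecg)
    expect_equal(length(peakTimes(pk)), 3L)
    expect_lt(max(abs(peakTimes(pk) - c(0.5, 1.5, 2.5))), 0.010)
    expect_lt(rrCv(pk), 0.01)
})

test_that("degenerate ECG traces are rejected", {
    t <- seq(0, 3, by = 0.002)
    expect_error(detectRPeaks(EcgTrace(t, rep(1, length(t)), 500)), "flat")
    expect_error(detectRPeaks(EcgTrace(seq(0, 1, 0.002),
                                       rnorm(501), 500)), "2 s")
    expect_error(detectRPeaks(EcgTrace(seq(0, 3, 0.02),
                                       rnorm(151), 50)), "100 Hz")
})

test_that("alternating R-R intervals give the closed-form CV and fail the gate", {
    peaks <- 0.3 + cumsum(c(0, rep(c(0.8, 1.2), 4)))
    ecg <- syntheticEcg(peaks, duration = max(peaks) + 0.3)
    pk <- detectRPeaks(ecg)
    rr <- rep(c(0.8, 1.2), 4)
    expect_equal(rrCv(pk), sd(rr) / mean(rr), tolerance = 0.02)
    expect_false(checkSinusRhythm(pk)$pass)
    expect_true(checkSinusRhythm(pk, cvThreshold = 0.5)$pass)
})

test_that("the sinus gate is inclusive at the threshold", {
    pk <- new("RPeakSet", peakTimes = c(0, 1), meanRr = 1, rrCv = 0.10)
    expect_true(checkSinusRhythm(pk, cvThreshold = 0.10)$pass)
    expect_true(checkSinusRhythm(new("RPeakSet", peakTimes = c(0, 1),
                                     meanRr = 1, rrCv = 0.01))$pass)
})

test_that("cardiac phase follows the enclosing R-R interval", {
    pk <- new("RPeakSet", peakTimes = c(0, 1, 2), meanRr = 1, rrCv = 0)
    ph <- assignCardiacPhase(c(0, 0.5, 1.25, 2, 2.5, -0.1), pk)
    expect_equal(ph[1:4], c(0, 0.5, 0.25, 0))
    expect_true(all(is.na(ph[5:6])))
})

shiftedStack <- function(shifts, M = smoothMatrix(100, 100), win = 60,
                         noiseSd = 0, seed = 5) {
    # frame k holds the master texture with its content moved by shifts[k, ]
    set.seed(seed)
    n <- nrow(shifts)
    fr <- array(0, c(win, win, n))
    for (k in seq_len(n)) {
        dy <- shifts[k, 1]; dx <- shifts[k, 2]
        i <- floor(dy); fy <- dy - i
        j <- floor(dx); fx <- dx - j
        block <- function(oy, ox)
            M[(21 - i - oy):(20 + win - i - oy),
              (21 - j - ox):(20 + win - j - ox)]
        fr[, , k] <- (1 - fy) * (1 - fx) * block(0, 0) +
            fy * (1 - fx) * block(1, 0) +
            (1 - fy) * fx * block(0, 1) + fy * fx * block(1, 1)
        if (noiseSd > 0)
            fr[, , k] <- fr[, , k] + rnorm(win * win, sd = noiseSd)
    }
    FrameStack(pmax(fr, 0), mmPerPx = 0.2, frameRate = 30)
}

test_that("identical frames track to zero displacement with perfect score", {
    st <- shiftedStack(matrix(0, 4, 2))
    tr <- trackTemplate(st, c(15, 15, 25, 25), searchRadius = 6)
    expect_equal(displacements(tr), matrix(0, 4, 2))
    expect_equal(matchScores(tr), rep(1, 4), tolerance = 1e-9)
})

test_that("integer shifts are recovered exactly and equivariantly", {
    sh <- rbind(c(0, 0), c(3, -2), c(-4, 5), c(2, 2))
    st <- shiftedStack(sh)
    tr <- trackTemplate(st, c(15, 15, 25, 25), searchRadius = 6)
    expect_equal(displacements(tr), sh, tolerance = 1e-9)

    # shifting every non-reference frame by an extra (1, -1) offsets the
    # tracked displacements by exactly that shift
    sh2 <- sweep(sh, 2, c(1, -1), "+"); sh2[1, ] <- 0
    st2 <- shiftedStack(sh2)
    tr2 <- trackTemplate(st2, c(15, 15, 25, 25), searchRadius = 6,
                         referenceFrame = 1L)
    expect_equal(displacements(tr2), sh2, tolerance = 1e-9)
})

test_that("sub-pixel shifts are recovered within a quarter pixel", {
    sh <- rbind(c(0, 0), c(0.4, 0), c(-0.3, 0.4), c(1.6, -2.4))
    st <- shiftedStack(sh, noiseSd = 0.5)
    tr <- trackTemplate(st, c(15, 15, 25, 25), searchRadius = 6)
    expect_lt(max(abs(displacements(tr) - sh)), 0.25)
})

test_that("tracking validates template and search geometry", {
    st <- shiftedStack(matrix(0, 2, 2))
    expect_error(trackTemplate(st, c(1, 1, 70, 70), 3), "larger than")
    expect_error(trackTemplate(st, c(1, 1, 20, 20), 5), "exits the frame")
})

test_that("stabilization inverts tracked motion", {
    sh <- rbind(c(0, 0), c(3, -2), c(-2.5, 1.5), c(4, 4))
    # a broad-correlation texture keeps the double-interpolation blur of
    # the render + stabilize round trip well under the 1% RMS budget
    st <- shiftedStack(sh, M = smoothMatrix(100, 100, sdPx = 6))
    tr <- trackTemplate(st, c(15, 15, 25, 25), searchRadius = 6)
    stab <- stabilize(st, tr)
    ref <- frames(st)[, , 1]
    interior <- 10:50
    rng <- diff(range(ref))
    for (k in 2:4) {
        err <- frames(stab)[interior, interior, k] -
            ref[interior, interior]
        expect_lt(sqrt(mean(err^2)), 0.01 * rng)
        expect_false(all(validityMask(stab)[, , k]))
    }
    expect_equal(frameTimes(stab), frameTimes(st))

    # zero track: bit-exact identity, full validity
    id <- stabilize(st, MotionTrack(matrix(0, 4, 2)))
    expect_identical(frames(id), frames(st))
    expect_true(all(validityMask(id)))
})

test_that("stabilize enforces track length and the rhythm gate", {
    st <- shiftedStack(matrix(0, 3, 2))
    expect_error(stabilize(st, MotionTrack(matrix(0, 2, 2))), "3 frames")
    bad <- list(pass = FALSE, message = "irregular rhythm")
    expect_error(stabilize(st, MotionTrack(matrix(0, 3, 2)), rhythm = bad),
                 "irregular")
    expect_s4_class(stabilize(st, MotionTrack(matrix(0, 3, 2)),
                              rhythm = bad, force = TRUE),
                    "StabilizedStack")
})
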