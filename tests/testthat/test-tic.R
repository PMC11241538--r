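makeStack <- function(attenuation, base = 100, ny = 10, nx = 20,
                      maskRows = 4:7, maskCols = 8:14) {
    # frames constant at `base` except the mask region darkened by
    # attenuation[k] in frame k
    n <- length(attenuation)
    fr <- array(base, c(ny, nx, n))
    for (k in seq_len(n)) fr[maskRows, maskCols, k] <-
        base - attenuation[k]
    mask <- matrix(FALSE, ny, nx)
    mask[maskRows, maskCols] <- TRUE
    list(stack = FrameStack(fr, mmPerPx = 0.2, frameRate = 30),
         mask = mask)
}

test_that("extractSignal inverts attenuation against the baseline", {
    att <- c(0, 0, 5, 12.5, 3, 0)
    fx <- makeStack(att)
    cv <- extractSignal(fx$stack, fx$mask, baselineFrames = 2)
    expect_equal(curveValues(cv), att)
    expect_equal(baselineLevel(cv), 100)
    expect_equal(cv@roiPixelCount, sum(fx$mask))

    # all-baseline stack: zero signal
    fx0 <- makeStack(rep(0, 5))
    expect_equal(curveValues(extractSignal(fx0$stack, fx0$mask, 1)),
                 rep(0, 5))

    # doubling the attenuation doubles the signal (linearity of the mean)
    fx2 <- makeStack(2 * att)
    expect_equal(curveValues(extractSignal(fx2$stack, fx2$mask, 2)), 2 * att)
})

test_that("extractSignal validates its inputs", {
    fx <- makeStack(c(0, 1, 2))
    expect_error(extractSignal(fx$stack, matrix(FALSE, 10, 20), 1), "empty")
    expect_error(extractSignal(fx$stack, fx$mask, 3), "baselineFrames")
    expect_error(extractSignal(fx$stack, matrix(TRUE, 3, 3), 1),
                 "do not match")
})

test_that("trapezoidal AUC matches closed forms", {
    # rectangle
    expect_equal(curveAuc(TimeIntensityCurve(0:10, rep(2, 11))), 20)
    # triangle: linear ramp 0 -> 1 over [0, 1]
    expect_equal(curveAuc(TimeIntensityCurve(c(0, 1), c(0, 1))), 0.5)
    # gamma-variate t^2 exp(-t) on a 1 ms grid: closed form Gamma(3) = 2
    t <- seq(0, 40, by = 0.001)
    g <- TimeIntensityCurve(t, t^2 * exp(-t))
    expect_equal(curveAuc(g), 2, tolerance = 1e-4 / 2)
    # window-edge interpolation is exact for piecewise-linear curves:
    # v = 2t on [0, 10]; integral over [0.25, 9.75] = 9.75^2 - 0.25^2
    ramp <- TimeIntensityCurve(0:10, 2 * (0:10))
    expect_equal(curveAuc(ramp, 0.25, 9.75), 9.75^2 - 0.25^2)
})

test_that("AUC rejects bad windows", {
    cv <- TimeIntensityCurve(0:5, rep(1, 6))
    expect_error(curveAuc(cv, 3, 2), "tStart")
    expect_error(curveAuc(cv, -1, 4), "outside")
    expect_error(curveAuc(TimeIntensityCurve(1, 1)), "2 samples")
})

test_that("the index reproduces the published per-patient ratios", {
    expect_equal(round(cciaValue(cciaIndex(1706, 1041)), 2), 0.61)
    expect_equal(round(cciaValue(cciaIndex(448, 491)), 2), 1.10)
    expect_equal(round(cciaValue(cciaIndex(477, 48)), 2), 0.10)
    expect_identical(cciaValue(cciaIndex(123.4, 123.4)), 1)
    expect_error(cciaIndex(0, 1), "aucProximal")
    expect_error(cciaIndex(1, -2), "aucStenotic")
})

test_that("Stewart-Hamilton flow is amount over concentration AUC", {
    expect_equal(stewartHamiltonFlow(Injection(amount = 1), 1), 1)
    expect_equal(stewartHamiltonFlow(Injection(amount = 4), 2), 2)
    # calibration gain maps image signal to concentration
    expect_equal(stewartHamiltonFlow(Injection(amount = 4), 200,
                                     calibrationGain = 100), 2)
    expect_error(stewartHamiltonFlow(Injection(), 0), "curveAuc")
})

test_that("the proximal region sits 10 mm upstream with equal size", {
    mask <- matrix(FALSE, 30, 200)
    mask[10:20, 100:130] <- TRUE
    roi <- RoiSpec(mask, cbind(rep(15, 200), 1:200), mmPerPx = 0.2)
    prox <- defineProximalRoi(roi)
    expect_equal(sum(prox), sum(mask))          # equal in size
    pc <- range(which(apply(prox, 2, any)))
    # gap between proximal downstream edge and lesion upstream edge:
    # 10 mm / 0.2 mm per px = 50 px
    expect_equal(100 - pc[2], 50)
    expect_equal(pc[2] - pc[1], 30)             # same extent

    # coarser calibration: 10 px gap
    roi1 <- RoiSpec(mask, cbind(rep(15, 200), 1:200), mmPerPx = 1)
    pc1 <- range(which(apply(defineProximalRoi(roi1), 2, any)))
    expect_equal(100 - pc1[2], 10)

    # centerline too short to fit the offset
    short <- RoiSpec(mask[, 1:135], cbind(rep(15, 60), 76:135),
                     mmPerPx = 0.2)
    expect_error(defineProximalRoi(short), "too short")
})

test_that("CCIA from a stack is invariant to global intensity rescaling", {
    att <- c(0, 0, 3, 8, 4, 1, 0, 0, 0, 0)
    ny <- 20; nx <- 120
    fr <- array(100, c(ny, nx, length(att)))
    for (k in seq_along(att)) {
        fr[8:12, 80:95, k] <- 100 - att[k]          # stenotic region
        fr[8:12, 15:30, k] <- 100 - 1.6 * att[k]    # proximal region
    }
    mask <- matrix(FALSE, ny, nx); mask[8:12, 80:95] <- TRUE
    roi <- RoiSpec(mask, cbind(rep(10, nx), 1:nx), mmPerPx = 0.2)
    st1 <- FrameStack(fr, mmPerPx = 0.2, frameRate = 30)
    st2 <- FrameStack(2 * fr, mmPerPx = 0.2, frameRate = 30)
    # proximal mask lands on cols 15:30 given the 50 px gap + lesion extent
    c1 <- computeCcia(st1, roi, baselineFrames = 2)
    c2 <- computeCcia(st2, roi, baselineFrames = 2)
    expect_equal(cciaValue(c1), cciaValue(c2), tolerance = 1e-9)
    expect_equal(cciaValue(c1), 1 / 1.6, tolerance = 1e-9)
    expect_named(c1@curves, c("proximal", "stenotic"))
})

test_that("no-lesion phantom yields unit CCIA under constant flow", {
    cfg <- fastConfig(geometry = stenosisGeometry(1), flow = constantFlow())
    cc <- cachedSim("ccia-nolesion", function() fastCcia(cfg))
    expect_gt(cc, 0.95)
    expect_lt(cc, 1.05)
})

test_that("CCIA decreases strictly with stenosis severity", {
    ccs <- cachedSim("ccia-severity", function() vapply(
        c(0.7, 0.5, 0.3), function(h)
            fastCcia(fastConfig(geometry = stenosisGeometry(h, xs = 12))),
        numeric(1)))
    expect_true(all(diff(ccs) < 0))
})

test_that("phantom flow is recovered by indicator dilution", {
    # the concentration AUC at any station under constant flow must invert
    # to the configured flow within 2%
    cfg <- fastConfig(geometry = stenosisGeometry(1), flow = constantFlow())
    est <- cachedSim("sh-image-flow", function() {
        field <- advectBolus(cfg)
        a <- stationAuc(field, 50)
        stewartHamiltonFlow(cfg@injection, a)
    })
    trueQ <- 25 * pi * 0.15^2
    expect_equal(est, trueQ, tolerance = 0.02)
})
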