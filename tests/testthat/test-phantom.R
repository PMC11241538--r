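test_that("the nine bench geometries are generated correctly", {
    gs <- benchGeometries()
    expect_length(gs, 9L)
    expect_setequal(vapply(gs, function(g) g@totalLength, numeric(1)),
                    c(6, 18, 30))
    for (g in gs) {
        expect_equal(g@percentDs, 100 * (1 - g@hOverR))
        expect_equal(g@totalLength, g@li + g@xs + g@lo)
    }
})

test_that("geometry validity enforces its identities", {
    expect_error(validObject(new("StenosisGeometry", hOverR = 0.5,
                                 percentDs = 40, li = 3, xs = 0, lo = 3,
                                 normalDiameter = 3, totalLength = 6)),
                 "percentDs")
    expect_error(stenosisGeometry(1.2), "hOverR")
    expect_error(stenosisGeometry(0.5, li = -1), ">= 0")
})

test_that("the diameter profile follows the taper/throat/taper shape", {
    g <- stenosisGeometry(0.3, li = 3, xs = 12, lo = 3)   # lesion 56-74 mm
    expect_equal(diameterProfile(g, c(5, 30, 95)), rep(3, 3))
    expect_equal(diameterProfile(g, 65), 0.9)             # h = 0.3 x 3
    expect_equal(diameterProfile(g, 56 + 1.5), (3 + 0.9) / 2)  # mid-taper
    gid <- stenosisGeometry(1)
    expect_equal(diameterProfile(gid, seq(0, 100, 5)), rep(3, 21))
    expect_error(diameterProfile(g, 101), "outside")
})

test_that("the pulsatile waveform has the configured mean and period", {
    fw <- flowWaveform()
    t <- seq(0, 1, length.out = 200001)[-200001]
    expect_equal(mean(flowVelocity(fw, t)), 25, tolerance = 1e-6)
    expect_true(all(flowVelocity(fw, t) >= 0))
    # 60 bpm: exact 1 s periodicity
    expect_equal(flowVelocity(fw, 0.3), flowVelocity(fw, 7.3))
    # mean volumetric flow: 25 cm/s through a 3 mm lumen
    expect_equal(mean(pulsatileFlow(fw, t)), 25 * pi * 0.15^2,
                 tolerance = 1e-5)
    # degenerate waveform: constant flow
    expect_equal(flowVelocity(constantFlow(), c(0, 0.2, 0.7)), rep(25, 3))
})

test_that("tracer mass is conserved and absent without injection", {
    cfg <- fastConfig()
    f <- cachedSim("field-default", function() advectBolus(cfg))
    mb <- massBalance(f)
    expect_lt(max(abs(mb$relError)), 1e-3)
    expect_equal(tail(mb$massIn, 1), 4, tolerance = 1e-6)

    # injection scheduled after the acquisition: zero field
    late <- fastConfig(injection = Injection(startTime = 100))
    f0 <- advectBolus(late)
    expect_equal(max(abs(f0@concentration)), 0)
})

test_that("a plug advances at Q/A under constant flow without dispersion", {
    # slow flow and a sharp injection so the whole pulse sits inside the
    # 100 mm domain while its centroid is measured
    cfg <- fastConfig(geometry = stenosisGeometry(1),
                      flow = constantFlow(10), dispersionCoeff = 0,
                      spreadSd = 0.02)
    f <- cachedSim("field-plug", function() advectBolus(cfg))
    centroid <- function(k) {
        w <- f@concentration[, k]
        sum(f@x * w) / sum(w)
    }
    k1 <- which.min(abs(f@times - 2.0)); k2 <- which.min(abs(f@times - 2.2))
    v <- (centroid(k2) - centroid(k1)) / (f@times[k2] - f@times[k1])
    expect_equal(v, 100, tolerance = 0.01)   # 10 cm/s in mm/s
})

test_that("station AUC is dispersion-invariant under constant flow", {
    aucs <- cachedSim("aucs-by-D", function() vapply(
        c(0, 1, 5), function(D) stationAuc(advectBolus(
            fastConfig(geometry = stenosisGeometry(1),
                       flow = constantFlow(), dispersionCoeff = D)), 50),
        numeric(1)))
    expect_lt(max(abs(aucs / aucs[1] - 1)), 0.02)
    expect_equal(aucs[1], 4 / (25 * pi * 0.15^2), tolerance = 0.02)
})

test_that("rendering matches the closed-form projection", {
    cfg <- fastConfig(noiseSd = 0)
    f <- cachedSim("field-default", function() advectBolus(cfg))
    st <- cachedSim("stack-clean", function() renderFrames(f, cfg))
    ny <- dim(frames(st))[1]; k <- 100
    # center row over a normal-segment column: chord = full 3 mm diameter
    j <- 150                                   # x = 29.9 mm
    cc <- approx(f@x, f@concentration[, k], xout = (j - 0.5) * 0.2)$y
    expected <- round(3000 - 150 * cc * 3)
    expect_equal(frames(st)[(ny + 1) / 2, j, k], expected)
    # far off-axis rows carry pure background
    expect_equal(frames(st)[1, j, k], 3000)
})

test_that("rendering is deterministic under a fixed seed", {
    cfg <- fastConfig(noiseSd = 8, seed = 99L)
    f <- cachedSim("field-default", function() advectBolus(fastConfig()))
    s1 <- renderFrames(f, cfg); s2 <- renderFrames(f, cfg)
    expect_identical(frames(s1), frames(s2))
    cfg2 <- cfg; cfg2@seed <- 100L
    expect_false(identical(frames(s1), frames(renderFrames(f, cfg2))))
})

test_that("the phantom ROI is well-formed", {
    cfg <- fastConfig()
    roi <- phantomRoi(cfg)
    expect_s4_class(roi, "RoiSpec")
    cols <- which(apply(roi@stenoticMask, 2, any))
    # 18 mm lesion at 0.2 mm/px: 90 columns
    expect_equal(length(cols), 90L)
    expect_equal(mmPerPx(roi), cfg@mmPerPx)
})

test_that("in vivo simulation ground truth is consistent", {
    cfg <- fastConfig(noiseSd = 0)
    sim <- cachedSim("invivo-quiet", function()
        simulateInvivo(cfg, motionAmplitude = 0, ecgNoiseSd = 0))
    expect_identical(frames(sim$stack), frames(sim$staticStack))
    expect_equal(sim$rPeakTimes, seq(0, 5, by = 1))

    sim5 <- cachedSim("invivo-moving", function()
        simulateInvivo(cfg, motionAmplitude = 5))
    d <- displacements(sim5$track)
    expect_equal(max(d[, 1]) - min(d[, 1]), 5, tolerance = 0.01)
    expect_equal(d[1, ], c(0, 0))
    pk <- detectRPeaks(sim5$ecg)
    expect_lt(max(vapply(peakTimes(pk), function(t)
        min(abs(sim5$rPeakTimes - t)), numeric(1))), 0.01)
})

test_that("the grid runner emits a tidy, seeded results table", {
    gs <- list(stenosisGeometry(0.7, xs = 0), stenosisGeometry(0.3, xs = 0))
    g0 <- runGrid(gs, replicates = 2, seed = 5L, noiseSd = 0,
                  config = fastConfig())
    expect_equal(nrow(g0), 4L)
    expect_named(g0, c("length", "percent_ds", "replicate", "ccia", "ffr"))
    # noise-free: replicates identical
    expect_equal(as.numeric(tapply(g0$ccia, g0$percent_ds, sd)), c(0, 0))
    # severe lesion scores lower on both indices
    expect_lt(mean(g0$ccia[g0$percent_ds == 70]),
              mean(g0$ccia[g0$percent_ds == 30]))
    expect_lt(g0$ffr[g0$percent_ds == 70][1], g0$ffr[g0$percent_ds == 30][1])

    gN <- runGrid(gs[1], replicates = 2, seed = 5L, noiseSd = 15,
                  config = fastConfig())
    expect_gt(sd(gN$ccia), 0)
})
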