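# Shared fixtures. Expensive simulations are built once per test run and
# memoized here; unit tests use a shortened acquisition (5 s, 150 frames,
# 100 mm injector tubing) so each transport solve stays around a second.

fastConfig <- function(geometry = stenosisGeometry(0.5, xs = 12),
                       flow = flowWaveform(), noiseSd = 0, seed = 1L,
                       spreadSd = 0.1, ...) {
    # the bolus smear models shear spreading over the injector tubing, so
    # it scales with the transit delay: a 100 mm line (0.4 s at 25 cm/s)
    # gets a quarter of the 500 mm default's 0.5 s spread
    simConfig(geometry = geometry, flow = flow, noiseSd = noiseSd,
              seed = seed, duration = 5, delayLength = 100,
              injectionSpreadSd = spreadSd, ...)
}

.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, maker) {
    if (is.null(.simCache[[key]])) .simCache[[key]] <- maker()
    .simCache[[key]]
}

# full analysis window of a fast-config stack (injection start to last frame)
fullWindow <- function(stack) c(0.5, max(frameTimes(stack)))

fastCcia <- function(cfg, stack = simulateStack(cfg)) {
    cciaValue(computeCcia(stack, phantomRoi(cfg),
                          baselineFrames = max(1L, floor(0.5 * cfg@frameRate)),
                          window = fullWindow(stack)))
}

# smooth seeded texture used as a trackable scene in motion tests
smoothMatrix <- function(ny, nx, seed = 7, sdPx = 3) {
    set.seed(seed)
    pad <- 3L * sdPx
    f <- matrix(rnorm((ny + 2 * pad) * (nx + 2 * pad)),
                ny + 2 * pad, nx + 2 * pad)
    k <- dnorm(seq(-pad, pad), sd = sdPx); k <- k / sum(k)
    f <- apply(f, 2L, function(col) stats::filter(col, k, sides = 2))
    f <- t(apply(f, 1L, function(row) stats::filter(row, k, sides = 2)))
    f <- f[pad + seq_len(ny), pad + seq_len(nx)]
    f[is.na(f)] <- 0
    100 + 50 * f / sd(f)
}

# synthetic ECG with Gaussian R spikes at the given times
syntheticEcg <- function(peakTimes, fs = 500, duration = NULL,
                         noiseSd = 0.01, seed = 11) {
    set.seed(seed)
    if (is.null(duration)) duration <- max(peakTimes) + 0.5
    t <- seq(0, duration, by = 1 / fs)
    v <- rep(0, length(t))
    for (tk in peakTimes) v <- v + exp(-(t - tk)^2 / (2 * 0.012^2))
    EcgTrace(t, v + rnorm(length(t), sd = noiseSd), fs)
}
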