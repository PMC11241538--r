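#' Trim pressure traces to the last n complete cardiac cycles
#'
#' Selects the final \code{nCycles} complete periods of the record (steady
#' state, avoiding start-up transients), aligned to period boundaries
#' counted from the first sample. The window is half-open:
#' \code{start <= t < end}, so with sampling commensurate with the period
#' each cycle contributes exactly one period of samples.
#'
#' @param traces a \linkS4class{PressureTraces}.
#' @param period cardiac period, s (1 s at 60 bpm).
#' @param nCycles number of cycles to keep (default 10).
#' @return A trimmed \linkS4class{PressureTraces}.
#' @export
cycleWindow <- function(traces, period, nCycles = 10) {
    stopifnot(is(traces, "PressureTraces"))
    t0 <- traces@times[1L]
    total <- traces@times[length(traces@times)] - t0
    if (total < nCycles * period - 1e-9)
        stop("record too short: ", signif(total, 4), " s < ", nCycles,
             " cycles x ", period, " s")
    k <- floor(total / period + 1e-9)
    end <- t0 + k * period
    start <- end - nCycles * period
    sel <- traces@times >= start - 1e-12 & traces@times < end - 1e-12
    PressureTraces(traces@times[sel], traces@pa[sel], traces@pd[sel],
                   pv = traces@pv)
}

#' Fractional flow reserve from pressure traces
#'
#' FFR is the ratio of distal to aortic coronary pressure under hyperemia;
#' with venous pressure Pv it reads (Pd - Pv) / (Pa - Pv), and with the
#' conventional Pv = 0 it reduces to Pd / Pa. Pressures are cycle-averaged
#' over the last \code{nCycles} complete periods (see
#' \code{\link{cycleWindow}}).
#'
#' @param traces a \linkS4class{PressureTraces}.
#' @param period cardiac period, s.
#' @param nCycles cycles to average (default 10).
#' @param pv venous pressure, mmHg (default 0, the conventional
#'   cancellation).
#' @return An \linkS4class{FfrResult}.
#' @examples
#' t <- seq(0, 10, by = 0.001)
#' tr <- PressureTraces(t, 100 + 20 * sin(2 * pi * t),
#'                      80 + 16 * sin(2 * pi * t))
#' ffrValue(computeFfr(tr, period = 1))  # 0.80
#' @export
computeFfr <- function(traces, period, nCycles = 10, pv = 0) {
    w <- cycleWindow(traces, period, nCycles)
    meanPa <- mean(w@pa)
    meanPd <- mean(w@pd)
    if (meanPa <= pv)
        stop("mean Pa (", signif(meanPa, 4), ") must exceed Pv (", pv, ")")
    new("FfrResult", meanPa = meanPa, meanPd = meanPd,
        ffr = (meanPd - pv) / (meanPa - pv), pv = as.numeric(pv),
        nCycles = as.integer(nCycles))
}
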