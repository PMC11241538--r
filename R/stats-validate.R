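#' Pearson correlation with the least-squares line
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom, plus the ordinary least-squares fit of y on
#' x (the "line of best fit" of the validation scatter plots). Degenerate
#' inputs raise errors rather than returning NaN.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance. NA pairs are not allowed; drop them first.
#' @return A \linkS4class{CorrelationReport}.
#' @export
pearsonReport <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
    if (anyNA(x) || anyNA(y)) stop("NA values: drop incomplete pairs first")
    if (length(x) < 3L) stop("need n >= 3")
    if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300)
        stop("zero variance in 'x' or 'y'")
    ct <- stats::cor.test(x, y, method = "pearson")
    fit <- stats::lm(y ~ x)
    new("CorrelationReport", r = unname(ct$estimate),
        pValue = ct$p.value, n = length(x),
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]))
}

#' Recompute the per-patient CCIA column
#'
#' For each record the index is recomputed as stenotic / proximal contrast
#' intensity and compared with the printed CCIA at two decimals
#' (round-half-to-even, R's default).
#'
#' @param table data.frame with columns \code{proximal}, \code{stenotic}
#'   and \code{ccia} (see \code{\link{readPatientTable}}).
#' @return The table with added columns \code{ccia_recomputed} and
#'   \code{ccia_match}.
#' @export
recomputePatientCcia <- function(table = readPatientTable()) {
    need <- c("proximal", "stenotic", "ccia")
    miss <- setdiff(need, names(table))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    if (any(table$proximal <= 0) || any(table$stenotic <= 0))
        stop("non-positive contrast intensity")
    table$ccia_recomputed <- table$stenotic / table$proximal
    table$ccia_match <- round(table$ccia_recomputed, 2) == table$ccia
    table
}

#' Summarize replicate measurements
#'
#' @param values numeric vector of replicate measurements (n >= 1).
#' @return A \linkS4class{ReplicateSummary}; the SD uses the n - 1
#'   denominator and is NA (undefined) for a single replicate.
#' @export
replicateSummary <- function(values) {
    if (length(values) == 0L) stop("empty input")
    new("ReplicateSummary", mean = mean(values),
        sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
        n = length(values))
}

#' Bench reference measurements for the nine stenosis models
#'
#' Physical bench measurements (not simulator output, not numeric targets):
#' per-model FFR and the mean +/- SD of the replicate CCIA measurements on
#' the in vitro circulation rig. Shipped for display-only comparison in
#' \code{\link{validateReport}}.
#'
#' @return data.frame with columns \code{length}, \code{percent_ds},
#'   \code{ffr}, \code{ccia_mean}, \code{ccia_sd}, \code{n}.
#' @export
invitroReference <- function() {
    data.frame(
        length = rep(c(6, 18, 30), each = 3),
        percent_ds = rep(c(30, 50, 70), 3),
        ffr = c(0.90, 0.86, 0.85, 0.84, 0.64, 0.61, 0.69, 0.37, 0.33),
        ccia_mean = c(0.82, 0.68, 0.61, 0.78, 0.69, 0.44, 0.80, 0.64, 0.40),
        ccia_sd = c(0.007, 0.007, 0.004, 0.052, 0.025, 0.016,
                    0.018, 0.006, 0.026),
        n = c(3, 3, 3, 3, 3, 3, 3, 3, 2))
}

.monotoneDecreasing <- function(x) all(diff(x) < 0)

# ordinal trend checks on a runGrid()-style results table
.ordinalChecks <- function(grid) {
    agg <- stats::aggregate(cbind(ccia, ffr) ~ length + percent_ds,
                            data = grid, FUN = mean)
    cciaByLength <- vapply(split(agg, agg$length), function(d)
        .monotoneDecreasing(d$ccia[order(d$percent_ds)]), logical(1))
    ffrByLength <- vapply(split(agg, agg$length), function(d)
        .monotoneDecreasing(d$ffr[order(d$percent_ds)]), logical(1))
    ffrByDs <- vapply(split(agg, agg$percent_ds), function(d)
        .monotoneDecreasing(d$ffr[order(d$length)]), logical(1))
    list(ccia_decreasing_in_ds = cciaByLength,
         ffr_decreasing_in_ds = ffrByLength,
         ffr_decreasing_in_length = ffrByDs,
         pass = all(cciaByLength, ffrByLength, ffrByDs))
}

#' Full statistical validation report
#'
#' Recomputes the per-patient CCIA column, the two in vivo Pearson
#' correlations (CCIA vs FFR over all patients; CCIA vs iFR over the
#' patients with an iFR measurement) with their best-fit lines, and the
#' display-only nine-model bench correlation between the published mean
#' CCIA and FFR values. When a simulator grid table is supplied the
#' ordinal trend checks (CCIA and FFR decreasing with stenosis severity,
#' FFR decreasing with length) are added. The expectations asserted are:
#' all per-patient CCIA values match at 2 dp, r(CCIA, FFR) = 0.5775 at
#' 4 dp with p < 0.05, and r(CCIA, iFR) = 0.7578 (within 0.0002) with
#' p < 0.01.
#'
#' @param patients the per-patient table (see \code{\link{readPatientTable}}).
#' @param grid optional \code{\link{runGrid}} results table (or CSV path).
#' @param out optional path: the report is written there as JSON.
#' @return A list of class \code{cciaValidationReport} with elements
#'   \code{patients}, \code{corFfr}, \code{corIfr}, \code{invitro},
#'   \code{ordinal} (or NULL), \code{checks} and \code{pass}.
#' @export
validateReport <- function(patients = readPatientTable(), grid = NULL, out = NULL) {
    t2 <- recomputePatientCcia(patients)
    corFfr <- pearsonReport(t2$ccia, t2$ffr)
    hasIfr <- !is.na(t2$ifr)
    corIfr <- pearsonReport(t2$ccia[hasIfr], t2$ifr[hasIfr])

    ref <- invitroReference()
    corBench <- pearsonReport(ref$ccia_mean, ref$ffr)

    ordinal <- NULL
    if (!is.null(grid)) {
        if (is.character(grid))
            grid <- readTable(grid, numericCols = c("length", "percent_ds",
                                                    "replicate", "ccia",
                                                    "ffr"))
        ordinal <- .ordinalChecks(grid)
    }

    checks <- list(
        patient_ccia_all_match = all(t2$ccia_match),
        ffr_r_matches = round(corFfr@r, 4) == 0.5775,
        ffr_p_below_0.05 = corFfr@pValue < 0.05,
        ifr_r_matches = abs(corIfr@r - 0.7578) <= 2e-4,
        ifr_p_below_0.01 = corIfr@pValue < 0.01)
    pass <- all(unlist(checks)) && (is.null(ordinal) || ordinal$pass)

    rep <- structure(list(patients = t2, corFfr = corFfr, corIfr = corIfr,
                          invitro = list(reference = ref,
                                         nineMeanR = corBench@r),
                          ordinal = ordinal, checks = checks, pass = pass),
                     class = "cciaValidationReport")
    if (!is.null(out)) {
        js <- list(
            patients = t2,
            cor_ccia_ffr = list(r = corFfr@r, p = corFfr@pValue,
                                n = corFfr@n, slope = corFfr@slope,
                                intercept = corFfr@intercept),
            cor_ccia_ifr = list(r = corIfr@r, p = corIfr@pValue,
                                n = corIfr@n, slope = corIfr@slope,
                                intercept = corIfr@intercept),
            invitro_nine_mean_r = corBench@r,
            ordinal = ordinal, checks = checks, pass = pass)
        jsonlite::write_json(js, out, digits = NA, auto_unbox = TRUE,
                             dataframe = "rows")
    }
    rep
}

#' @export
print.cciaValidationReport <- function(x, ...) {
    cat("Contrast-intensity validation report\n")
    cat(sprintf("  per-patient CCIA matches: %d / %d\n",
                sum(x$patients$ccia_match), nrow(x$patients)))
    cat(sprintf("  CCIA vs FFR: r = %.4f, p = %.4g, n = %d (fit y = %.3f x + %.3f)\n",
                x$corFfr@r, x$corFfr@pValue, x$corFfr@n, x$corFfr@slope,
                x$corFfr@intercept))
    cat(sprintf("  CCIA vs iFR: r = %.4f, p = %.4g, n = %d (fit y = %.3f x + %.3f)\n",
                x$corIfr@r, x$corIfr@pValue, x$corIfr@n, x$corIfr@slope,
                x$corIfr@intercept))
    cat(sprintf("  bench nine-model mean correlation (display only): r = %.4f\n",
                x$invitro$nineMeanR))
    if (!is.null(x$ordinal))
        cat(sprintf("  simulator ordinal trends: %s\n",
                    if (x$ordinal$pass) "all decreasing as expected"
                    else "VIOLATED"))
    cat(sprintf("  overall: %s\n", if (x$pass) "PASS" else "FAIL"))
    invisible(x)
}

#' Scatter plot of CCIA against a reference index
#'
#' @param x index values (CCIA).
#' @param y reference values (FFR or iFR).
#' @param report optional \linkS4class{CorrelationReport} to annotate.
#' @param xlab,ylab axis labels.
#' @param ... passed to \code{plot}.
#' @return Invisibly, the report used for annotation.
#' @export
plotCorrelation <- function(x, y, report = pearsonReport(x, y),
                            xlab = "CCIA", ylab = "Reference index", ...) {
    graphics::plot(x, y, pch = 19, xlab = xlab, ylab = ylab, ...)
    graphics::abline(report@intercept, report@slope)
    graphics::mtext(sprintf("r = %.4f, p = %.3g, n = %d", report@r,
                            report@pValue, report@n), side = 3, line = 0.2,
                    adj = 1, cex = 0.8)
    invisible(report)
}
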