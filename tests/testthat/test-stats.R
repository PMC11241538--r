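bruteForcePearson <- function(x, y) {
    # two-pass covariance oracle, independent of the implementation path
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    sxy <- sum((x - mx) * (y - my))
    sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
    r <- sxy / sqrt(sxx * syy)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(tt), n - 2),
         slope = sxy / sxx, intercept = my - sxy / sxx * mx)
}

test_that("pearsonReport agrees with the two-pass oracle", {
    set.seed(17)
    for (i in 1:20) {
        n <- sample(5:40, 1)
        x <- rnorm(n); y <- 0.6 * x + rnorm(n)
        got <- pearsonReport(x, y)
        ref <- bruteForcePearson(x, y)
        expect_equal(got@r, ref$r, tolerance = 1e-12)
        expect_equal(got@pValue, ref$p, tolerance = 1e-10)
        expect_equal(got@slope, ref$slope, tolerance = 1e-10)
        expect_equal(got@intercept, ref$intercept, tolerance = 1e-10)
    }
})

test_that("pearsonReport handles exact and degenerate cases", {
    x <- c(1, 2, 3, 5)
    expect_equal(pearsonReport(x, x)@r, 1)
    expect_equal(pearsonReport(x, -x)@r, -1)
    expect_error(pearsonReport(x, rep(2, 4)), "zero variance")
    expect_error(pearsonReport(1:2, 1:2), "n >= 3")
    expect_error(pearsonReport(1:4, 1:5), "equal length")
    expect_error(pearsonReport(c(1, NA, 3, 4), x), "NA")
})

test_that("the per-patient index recomputes from the printed intensities", {
    t2 <- recomputePatientCcia()
    expect_equal(round(t2$ccia_recomputed[t2$patient == 7], 2), 0.17)
    expect_equal(round(t2$ccia_recomputed[t2$patient == 13], 2), 0.43)
    expect_true(all(t2$ccia_match))

    hacked <- readPatientTable()
    hacked$stenotic[3] <- hacked$stenotic[3] * 1.2
    expect_false(all(recomputePatientCcia(hacked)$ccia_match))
    hacked$proximal[1] <- 0
    expect_error(recomputePatientCcia(hacked), "non-positive")
})

test_that("replicate summaries use the sample SD convention", {
    s <- replicateSummary(c(1, 1, 1))
    expect_equal(s@mean, 1); expect_equal(s@sd, 0)
    s2 <- replicateSummary(c(0, 1))
    expect_equal(s2@mean, 0.5)
    expect_equal(s2@sd, sqrt(0.5), tolerance = 1e-12)
    expect_true(is.na(replicateSummary(5)@sd))
    expect_error(replicateSummary(numeric(0)), "empty")
})

test_that("the validation report reproduces the published statistics", {
    out <- withr::local_tempfile(fileext = ".json")
    rep <- validateReport(out = out)
    expect_true(rep$pass)
    expect_equal(round(rep$corFfr@r, 4), 0.5775)
    expect_lt(rep$corFfr@pValue, 0.05)
    expect_equal(rep$corIfr@r, 0.7578, tolerance = 2e-4 / 0.7578)
    expect_lt(rep$corIfr@pValue, 0.01)
    expect_equal(rep$corIfr@n, 11L)
    js <- jsonlite::read_json(out, simplifyVector = TRUE)
    expect_true(js$pass)
    expect_equal(js$cor_ccia_ffr$n, 15)
    # the nine-model bench correlation is reported but never asserted
    expect_true(is.numeric(rep$invitro$nineMeanR))
    expect_output(print(rep), "PASS")
})

test_that("the validation report flags tampered fixtures", {
    hacked <- readPatientTable()
    hacked$stenotic[5] <- hacked$stenotic[5] + 40
    rep <- validateReport(hacked)
    expect_false(rep$pass)
    expect_false(rep$checks$patient_ccia_all_match)
})

test_that("ordinal trend checks accept clean grids and catch violations", {
    grid <- expand.grid(length = c(6, 18), percent_ds = c(30, 50, 70),
                        replicate = 1)
    grid$ccia <- 1 - grid$percent_ds / 100 + 0.001 * grid$length
    grid$ffr <- 1 - grid$percent_ds / 120 - 0.002 * grid$length
    rep <- validateReport(grid = grid)
    expect_true(rep$ordinal$pass)

    bad <- grid
    bad$ccia[bad$percent_ds == 70 & bad$length == 6] <- 0.9
    expect_false(validateReport(grid = bad)$ordinal$pass)
})
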