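test_that("one-rep-max estimation follows the repetition formula", {
    expect_identical(estimateOneRM(100, 1), 100)
    expect_equal(estimateOneRM(100, 10), 133.37, tolerance = 0.01)
    expect_true(is.finite(estimateOneRM(80, 36)))
    expect_error(estimateOneRM(80, 37), "below 37")
    expect_error(estimateOneRM(-5, 5), "positive")
    expect_error(estimateOneRM(100, 2.5), "whole number")
})

test_that("delta-to-atom-percent conversion matches closed-form evaluations", {
    ar <- 0.00015595
    expect_equal(deltaToAtomPercent(0), 100 * ar / (1 + ar), tolerance = 1e-10)
    expect_lt(abs(deltaToAtomPercent(0) - 0.0155926), 1e-6)
    expect_equal(deltaToAtomPercent(1000), 100 * 2 * ar / (1 + 2 * ar),
                 tolerance = 1e-12)
    deltas <- seq(-900, 2000, by = 10)
    expect_true(all(diff(deltaToAtomPercent(deltas)) > 0))   # monotone
    expect_error(deltaToAtomPercent(-1000), "-1000")
})

test_that("atom percent excess subtracts baseline and applies the dilution", {
    expect_true(all(apeExcess(0:5, rep(-60, 6))$ape == 0))
    ## a measured AP difference of 0.0143 becomes 0.5005 APE after x35
    d <- c(0, 500)
    ap <- deltaToAtomPercent(d)
    expect_equal(apeExcess(c(0, 1), d)$ape[2], (ap[2] - ap[1]) * 35)
    expect_equal(apeExcess(c(0, 1), d, dilution = 1)$ape[2], ap[2] - ap[1])
    expect_error(apeExcess(1:3, rep(0, 3)), "baseline")
})

test_that("the synthesis-rate equation and its linearity hold", {
    expect_equal(iMyoPS(0.037, 0.5, 2), 1.0, tolerance = 1e-12)
    expect_equal(iMyoPS(0, 0.5, 2), 0)
    expect_equal(iMyoPS(2 * 0.037, 0.5, 2), 2 * iMyoPS(0.037, 0.5, 2))
    expect_equal(iMyoPS(0.037, 0.5, 4), iMyoPS(0.037, 0.5, 2) / 2)
    expect_error(iMyoPS(0.1, 0, 2), "apeBW")
    expect_error(iMyoPS(0.1, 0.5, 0), "'t'")
})

test_that("all calculators match independently coded formulas on random input", {
    set.seed(51)
    n <- 1000
    load <- runif(n, 20, 300); reps <- sample(1:36, n, replace = TRUE)
    expect_lt(max(abs(estimateOneRM(load, reps) -
                      load / (1.0278 - 0.0278 * reps))), 1e-9)
    d <- runif(n, -500, 3000)
    ar <- 0.00015595
    ref <- 100 * (ar * (d * 0.001 + 1)) / (1 + ar * (d * 0.001 + 1))
    expect_lt(max(abs(deltaToAtomPercent(d) - ref)), 1e-9)
    dA <- runif(n, 0, 0.2); bw <- runif(n, 0.2, 0.8); tt <- runif(n, 0.5, 20)
    expect_lt(max(abs(iMyoPS(dA, bw, tt) - dA / (bw * 3.7 * tt) * 100)), 1e-9)
})

test_that("response CoV arithmetic matches hand calculation", {
    cov <- covTriplet(c(10, 20), c(-5, -10))
    expect_equal(unname(cov["hypat"]), 100 * sd(c(15, 30)) / 22.5,
                 tolerance = 1e-12)
    expect_equal(unname(cov["hypat"]), 47.1, tolerance = 0.1)
    expect_equal(unname(covTriplet(c(5, 5, 5), c(-2, -2, -2))),
                 c(0, 0, 0))
    expect_warning(cz <- covTriplet(c(-1, 1), c(1, 2)), "zero mean")
    expect_true(is.nan(cz[["rt"]]))
    expect_false(is.nan(cz[["hypat"]]))
    expect_error(covTriplet(1:3, 1:2), "equal length")
})

test_that("the designed synthesis rate is recovered from noise-free enrichment", {
    enr <- simulateEnrichment(list(trueRate = 1.37, noiseSd = 0), seed = 1)
    expect_equal(recoverSynthesisRate(enr), 1.37, tolerance = 0.02 * 1.37)
    enr2 <- simulateEnrichment(list(trueRate = 2.5, noiseSd = 0), seed = 2)
    expect_equal(recoverSynthesisRate(enr2, c(4, 18)), 2.5,
                 tolerance = 0.02 * 2.5)
})

test_that("the paired differential shrinks between-subject heterogeneity", {
    hits <- vapply(1:20, function(r) {
        resp <- simulateResponses(nSubjects = 34, seed = 600 + r)
        cov <- covTriplet(resp$rt, resp$ul)
        cov[["hypat"]] < min(cov[["rt"]], cov[["ul"]])
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})
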