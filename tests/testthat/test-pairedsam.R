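test_that("paired differences are antisymmetric and zero for identical pairs", {
    sp <- effectSpec(noiseSd = 0, subjectSd = 0,
                     classFractions = c(concordant_up = 0))
    sim <- simulateStudy(nGenes = 6, probesPerRegion = 2, nSubjects = 3,
                         spec = sp, seed = 21)
    rs <- preprocessProbes(sim$expr, sim$transcriptome)
    d1 <- pairedDifferences(rs)
    expect_true(all(d1 == 0))                      # no effects, no noise
    d2 <- pairedDifferences(rs, conditions = c("loaded", "unloaded"))
    expect_equal(d2, -d1)
    expect_error(pairedDifferences(rs[, -1]), "S01")
})

test_that("the d statistic matches an independently coded formula", {
    set.seed(22)
    delta <- matrix(rnorm(200 * 8), 200, 8)
    s0 <- 0.3
    d_pkg <- samStatistic(delta, s0)
    d_ref <- vapply(seq_len(200), function(i) {
        x <- delta[i, ]
        m <- sum(x) / 8
        se <- sqrt(sum((x - m)^2) / 7) / sqrt(8)
        m / (se + s0)
    }, numeric(1))
    expect_equal(d_pkg, d_ref, tolerance = 1e-12)
    expect_equal(samStatistic(matrix(c(-1, 1, -2, 2), 1), 0)[1], 0)
    expect_true(is.finite(samStatistic(matrix(1, 1, 4), 0)))  # zero variance
})

test_that("s0 selection is scale-equivariant and floors degenerate input", {
    set.seed(23)
    delta <- matrix(rnorm(500 * 10, sd = rep(c(0.2, 1), each = 250)), 500, 10)
    s0 <- chooseS0(delta)
    s0x2 <- chooseS0(2 * delta)
    expect_gt(s0, 0)
    expect_equal(s0x2 / s0, 2, tolerance = 0.25)
    expect_warning(s0c <- chooseS0(matrix(1, 10, 4)), "floor")
    expect_gt(s0c, 0)
})

test_that("chosen s0 flattens d dispersion across standard-error bins", {
    set.seed(24)
    delta <- matrix(rnorm(2000 * 12), 2000, 12)        # homoscedastic null
    s0 <- chooseS0(delta)
    d <- samStatistic(delta, s0)
    se <- apply(delta, 1, sd) / sqrt(12)
    bins <- cut(se, quantile(se, 0:10 / 10), include.lowest = TRUE)
    disp <- tapply(d, bins, mad)
    expect_lt(sd(disp) / mean(disp), 0.5)
})

test_that("small designs are fully enumerated and seed-independent", {
    set.seed(25)
    delta <- matrix(rnorm(50 * 3), 50, 3,
                    dimnames = list(paste0("ps", 1:50), NULL))
    q1 <- permutationFDR(delta, 0.1, nPerm = 100, seed = 1)
    q2 <- permutationFDR(delta, 0.1, nPerm = 100, seed = 999)
    expect_true(attr(q1, "enumerated"))
    expect_identical(as.numeric(q1), as.numeric(q2))   # all 8 sign patterns
    expect_true(all(q1 >= 0 & q1 <= 1))
})

test_that("q-values are monotone in |d| and invariant to probe-set order", {
    set.seed(26)
    delta <- matrix(rnorm(300 * 6), 300, 6)
    delta[1:20, ] <- delta[1:20, ] + 1.5
    q <- permutationFDR(delta, 0.05, nPerm = 200, seed = 3)
    d <- attr(q, "d")
    ord <- order(abs(d), decreasing = TRUE)
    expect_true(all(diff(q[ord]) >= 0))
    expect_equal(which.min(q), which.max(abs(d)))
    perm <- sample(nrow(delta))
    qp <- permutationFDR(delta[perm, ], 0.05, nPerm = 200, seed = 3)
    expect_equal(as.numeric(qp), as.numeric(q)[perm])
    expect_error(permutationFDR(delta, 0.05, nPerm = 50), "at least 100")
})

test_that("the FDR / fold-change gate follows both cutoffs", {
    ## q fine but fold too small; fold fine but q too large; down-call
    res <- callDE(c("a", "b", "c"),
                  meanDelta = log2(c(1.1, 2.0, 0.80)),
                  q = c(0.01, 0.10, 0.01),
                  d = c(1, 2, -2))
    tab <- deTable(res)
    expect_equal(tab$called, c(FALSE, FALSE, TRUE))
    expect_equal(tab$direction, c("none", "none", "down"))
    expect_true(tab$fc[3] < 1 / 1.2)
    expect_error(callDE("a", 0, 0.5, 0, fdr = 0.05, fc = 0.9), "fc")
})

test_that("planted effects are recovered with the designed fold change", {
    set.seed(27)
    G <- 400; n <- 12
    eff <- c(rep(log2(1.5), 40), rep(0, G - 40))
    delta <- eff + matrix(rnorm(G * n, 0, sqrt(2) * 0.25), G, n)
    res <- pairedSAM(delta, nPerm = 5000, seed = 4)
    tab <- deTable(res)
    expect_gt(mean(tab$called[1:40]), 0.8)
    expect_equal(mean(tab$fc[1:40]), 1.5, tolerance = 0.05)
    expect_lt(mean(tab$called[-(1:40)]), 0.02)
})
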