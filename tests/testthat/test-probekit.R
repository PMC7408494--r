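test_that("exact-match mapping counts forward and reverse-complement hits", {
    tx <- Biostrings::DNAStringSet(c(t1 = "AAAAACCCCCAAAAA",
                                     t2 = "AAAAACCCCCAAAAAAAAAACCCCCAAAAA"))
    ## once in t1 + twice in t2; absent; reverse-complement only (GGGTT)
    expect_identical(mapProbes(c("AACCC", "AGAGA", "GGGTT"), tx),
                     c(3L, 0L, 3L))
    expect_error(mapProbes("ACGTN", tx), "A, C, G, T")
    expect_error(mapProbes(strrep("A", 30), tx), "probe length")
})

test_that("the kept probe set equals the designed keep set exactly", {
    kept <- rowData(fx_flt)$probe_id
    designed <- fx_sim$truth$probe_id[fx_sim$truth$keep]
    expect_setequal(kept, designed)
})

test_that("rejection log gives one primary reason with the fixed priority", {
    log <- attr(fx_flt, "rejectionLog")
    truth <- fx_sim$truth
    expect_setequal(log$probe_id, truth$probe_id[!truth$keep])
    i <- match(log$probe_id, truth$probe_id)
    ## mapping dominates GC dominates background
    expect_true(all(log$reason[truth$multimap[i]] == "multimap"))
    expect_true(all(log$reason[!truth$multimap[i] & truth$gc_extreme[i]] == "gc"))
    expect_true(all(log$reason[!truth$multimap[i] & !truth$gc_extreme[i]] ==
                    "background"))
})

test_that("filtering is idempotent given the same background model", {
    counts_kept <- fx_counts[match(rowData(fx_flt)$probe_id,
                                   rowData(fx_sim$expr)$probe_id)]
    again <- filterProbes(fx_flt, counts_kept, fx_bg)
    expect_identical(rowData(again)$probe_id, rowData(fx_flt)$probe_id)
    expect_equal(nrow(attr(again, "rejectionLog")), 0)
})

test_that("unfitted or mismatched background models are rejected", {
    expect_error(filterProbes(fx_sim$expr, fx_counts, background = NULL),
                 "BackgroundModel")
    bg_wrong <- fitBackground(assay(fx_sim$expr)[, 1:3])
    expect_error(detectedAboveBackground(fx_sim$expr, bg_wrong),
                 "different number of samples")
})

test_that("GC correction shrinks the GC trend and preserves structure", {
    pre <- fx_flt
    post <- gcCorrect(pre)
    gc <- rowData(pre)$gc
    s_pre <- abs(stats::coef(stats::lm(assay(pre)[, 1] ~ gc))[2])
    s_post <- abs(stats::coef(stats::lm(assay(post)[, 1] ~ gc))[2])
    expect_lt(s_post, s_pre)
    ## identity cases: constant matrix, and all probes at the same GC
    const <- pre[1:20, ]
    assays(const)$log2intensity[] <- 5
    expect_equal(assay(gcCorrect(const)), assay(const))
    onegc <- pre[which(abs(gc - gc[1]) < 1e-12), ]
    expect_equal(assay(gcCorrect(onegc)), assay(onegc))
})

test_that("probe-set summarization is the member median", {
    sub <- fx_flt[1:3, ]
    assays(sub)$log2intensity[] <- matrix(c(1, 2, 9), 3,
                                          ncol(sub))
    cdf <- data.frame(probe_set_id = "TX:FL", transcript_id = "TX",
                      gene_id = "G", region = "FL",
                      probe_id = rowData(sub)$probe_id)
    rs <- summarizeProbeSets(sub, cdf)
    expect_true(all(assay(rs, "log2signal") == 2))
    ## single-probe set passes the probe through unchanged
    rs1 <- summarizeProbeSets(sub[1, ], cdf[1, ])
    expect_equal(unname(assay(rs1)[1, ]), unname(assay(sub)[1, ]))
})

test_that("summarization is probe-order invariant and monotone", {
    sub <- fx_flt[1:5, ]
    cdf <- data.frame(probe_set_id = "TX:FL", transcript_id = "TX",
                      gene_id = "G", region = "FL",
                      probe_id = rowData(sub)$probe_id)
    a <- assay(summarizeProbeSets(sub, cdf))
    b <- assay(summarizeProbeSets(sub, cdf[c(3, 1, 5, 2, 4), ]))
    expect_equal(a, b)
    bumped <- sub
    assays(bumped)$log2intensity[2, ] <-
        assays(bumped)$log2intensity[2, ] + 1
    expect_true(all(assay(summarizeProbeSets(bumped, cdf)) >= a))
})

test_that("the CDF assigns probes to regions without leakage", {
    cdf <- buildCDF(fx_flt)
    rd <- as.data.frame(rowData(fx_sim$expr))
    truth_region <- rd$region[match(cdf$probe_id, rd$probe_id)]
    expect_true(all(truth_region[cdf$region == "UTR3"] == "UTR3"))
    expect_true(all(truth_region[cdf$region == "UTR5"] == "UTR5"))
    ## FL unions all surviving probes of the transcript
    fl <- cdf[cdf$region == "FL", ]
    expect_setequal(fl$probe_id, rowData(fx_flt)$probe_id)
})

test_that("noise-free concordant genes shift all three region signals alike", {
    sp <- effectSpec(noiseSd = 0, subjectSd = 0, gcSlope = 0, deadFrac = 0,
                     multimapFrac = 0, gcExtremeFrac = 0,
                     classFractions = c(concordant_up = 0.5))
    sim <- simulateStudy(nGenes = 10, probesPerRegion = 2, nSubjects = 3,
                         spec = sp, seed = 11)
    rs <- preprocessProbes(sim$expr, sim$transcriptome)
    delta <- pairedDifferences(rs)
    up_tx <- rowData(rs)$gene_id %in% names(sim$classes)[
        sim$classes == "concordant_up"]
    expect_true(all(abs(delta[up_tx, ] - log2(1.5)) < 1e-9))
    expect_true(all(abs(delta[!up_tx, ]) < 1e-9))
})
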