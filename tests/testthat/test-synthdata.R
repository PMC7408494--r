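test_that("gene model generation is deterministic and counts add up", {
    a <- simulateGeneModels(100, 4, seed = 1)
    b <- simulateGeneModels(100, 4, seed = 1)
    expect_identical(as.character(a$transcriptome), as.character(b$transcriptome))
    expect_identical(as.data.frame(a$probeWindows), as.data.frame(b$probeWindows))
    expect_equal(nrow(a$probeWindows), 100 * 3 * 4)
    expect_false(identical(as.character(a$transcriptome),
                           as.character(simulateGeneModels(100, 4, seed = 2)$transcriptome)))
})

test_that("a minimal instance has one transcript with three disjoint regions", {
    gm <- simulateGeneModels(1, 1, seed = 7)
    m <- as.data.frame(gm$models)
    expect_equal(nrow(m), 3)
    expect_setequal(m$region, c("CDS", "UTR3", "UTR5"))
    m <- m[order(m$start), ]
    expect_true(all(m$start[-1] >= m$end[-3]))      # disjoint, half-open
    expect_equal(sum(m$end - m$start), sum(Biostrings::width(gm$transcriptome)))
})

test_that("invalid generator arguments are rejected", {
    expect_error(simulateGeneModels(0, 4, seed = 1), "nGenes")
    expect_error(simulateGeneModels(10, 0, seed = 1), "probesPerRegion")
    expect_error(simulateProbes(list(probeWindows = NULL)), "no probe windows")
    expect_error(studyDesign(1), "nSubjects")
    expect_error(simulateEnrichment(list(), seed = 1), "empty")
    expect_error(simulateCohorts("g1", studySizes = c(5, 1)), "at least 2")
})

test_that("probe GC fractions are computed from the sequence", {
    probes <- fx_sim$expr
    gc_manual <- vapply(strsplit(rowData(probes)$sequence, ""),
                        function(ch) mean(ch %in% c("G", "C")), numeric(1))
    expect_equal(rowData(probes)$gc, gc_manual)
    ## designed GC-extreme windows really are outside [0.2, 0.8]
    expect_true(all(rowData(probes)$gc[fx_sim$truth$gc_extreme] < 0.2 |
                    rowData(probes)$gc[fx_sim$truth$gc_extreme] > 0.8))
})

test_that("designed multi-mapping probes are discovered by the mapper", {
    expect_identical(fx_counts >= 2, as.logical(fx_sim$truth$multimap))
    expect_true(all(fx_counts[!fx_sim$truth$multimap] == 1L))
})

test_that("noise-free expression realizes the designed effects exactly", {
    sp <- effectSpec(noiseSd = 0, subjectSd = 0, gcSlope = 0,
                     classFractions = c(concordant_up = 0.5))
    gm <- simulateGeneModels(10, 2, seed = 3, gcExtremeFrac = 0)
    ps <- simulateProbes(gm, effectSpec(deadFrac = 0, multimapFrac = 0), seed = 3)
    cls <- assignEffectClasses(unique(ps$probes$gene_id), sp, seed = 3)
    des <- studyDesign(4)
    pe <- simulateExpression(ps, des, sp, cls, seed = 3)
    m <- assay(pe, "log2intensity")
    un <- des$sample_id[des$condition == "unloaded"]
    lo <- des$sample_id[des$condition == "loaded"]
    delta <- m[, lo] - m[, un]
    up <- rowData(pe)$gene_id %in% names(cls)[cls == "concordant_up"]
    expect_true(all(abs(delta[up, ] - log2(1.5)) < 1e-12))
    expect_true(all(delta[!up, ] == 0))
})

test_that("switching off the GC bias removes the intensity-GC trend", {
    sp0 <- effectSpec(gcSlope = 0, classFractions = c(concordant_up = 0))
    gm <- simulateGeneModels(60, 3, seed = 4)
    ps <- simulateProbes(gm, sp0, seed = 4)
    cls <- assignEffectClasses(unique(ps$probes$gene_id), sp0, seed = 4)
    pe <- simulateExpression(ps, studyDesign(4), sp0, cls, seed = 4)
    live <- !rowData(pe)$dead
    fit <- stats::lm(assay(pe)[live, 1] ~ rowData(pe)$gc[live])
    expect_lt(abs(stats::coef(fit)[2]), 0.1)
})

test_that("cohort generator links planted genes to the phenotype", {
    genes <- sprintf("g%03d", 1:50)
    ## near-deterministic link: Spearman close to 1 for planted genes
    co <- simulateCohorts(genes, genes[1:10], studySizes = c(40, 40),
                         spec = effectSpec(phenoRho = 0.99), seed = 5)
    rho <- suppressWarnings(spearmanCC(co$study1$delta, co$study1$llm))$rho
    expect_true(all(rho[1:10] > 0.9))
    expect_lt(mean(abs(rho[11:50])), 0.3)
    ## no link: correlations centered on zero
    co0 <- simulateCohorts(genes, character(0), studySizes = c(40, 40), seed = 6)
    rho0 <- suppressWarnings(spearmanCC(co0$study1$delta, co0$study1$llm))$rho
    expect_lt(abs(mean(rho0)), 0.1)
})

test_that("enrichment series reaches its designed plateau and rate 0 is flat", {
    enr <- simulateEnrichment(list(trueRate = 0, noiseSd = 0), seed = 1)
    expect_true(all(enr$protein$ape_ala == 0))
    enr2 <- simulateEnrichment(list(plateau = 0.5, noiseSd = 0.002), seed = 2)
    ape <- apeExcess(enr2$saliva$day, enr2$saliva$delta2H)$ape
    maint <- ape[enr2$saliva$day >= 2]
    expect_equal(mean(maint), 0.5, tolerance = 0.02)
})

test_that("study serialization writes the documented plain-text outputs", {
    dir <- withr::local_tempdir()
    sim <- simulateStudy(nGenes = 5, nSubjects = 2, seed = 9)
    paths <- writeStudy(sim, dir)
    expect_true(all(file.exists(paths)))
    probes <- read.delim(paths[["probes"]])
    expect_true(all(c("probe_id", "region", "start", "end", "gc",
                      "sequence") %in% colnames(probes)))
    fa <- Biostrings::readDNAStringSet(paths[["transcriptome"]])
    expect_identical(as.character(fa), as.character(sim$transcriptome))
})
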