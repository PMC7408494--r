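## Shared fixtures, built once per test run. Small scales keep the suite
## fast; the acceptance tests build their own study-scale instances.

suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

## a default-noise paired study with every designed probe defect
fx_sim <- simulateStudy(nGenes = 100, nSubjects = 6, seed = 1)
fx_counts <- mapProbes(rowData(fx_sim$expr)$sequence, fx_sim$transcriptome)
fx_bg <- fitBackground(fx_sim$expr)
fx_flt <- filterProbes(fx_sim$expr, fx_counts, fx_bg)

## build a PairedDEResult from bare numbers (for classifier rule tests)
mkDE <- function(ids, meanDelta, q) {
    callDE(ids, meanDelta, q, d = meanDelta / 0.1)
}

## one-gene DE triple with chosen fold changes / q-values per region
mkTriple <- function(fcFL, qFL, fcU3, qU3, fcU5, qU5, tx = "TXA") {
    list(FL = mkDE(paste0(tx, ":FL"), log2(fcFL), qFL),
         UTR3 = mkDE(paste0(tx, ":UTR3"), log2(fcU3), qU3),
         UTR5 = mkDE(paste0(tx, ":UTR5"), log2(fcU5), qU5))
}

fx_annot <- data.frame(transcript_id = "TXA", gene_id = "GA")
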