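# utrflux

Region-resolved transcript regulation in paired muscle loading designs.

## The problem

Human skeletal muscle responds to loading (resistance training) with
hypertrophy and to unloading (immobilization) with atrophy, but both
responses are highly heterogeneous between people. Two design ideas sharpen
the molecular analysis of this adaptation:

* **A within-person paired contrast.** Training one leg while immobilizing
  the contralateral leg lets every subject serve as their own control. The
  per-subject differential response cancels shared between-subject
  responsiveness and markedly reduces the coefficient of variation of the
  muscle-size response.
* **Region-resolved transcript quantification.** On short-probe expression
  arrays, a transcript can be summarized from all of its probes
  (full-length, FL), from its 3' UTR probes only, or from its 5' UTR probes
  only. Untranslated regions regulate translational efficiency, and their
  signal can change with no change in the coding transcript — regulation
  that gene-level analysis cannot see.

utrflux implements the complete analysis chain as a tested R package, and
ships a seeded synthetic-data generator that reproduces the structure of
such a study (planted effect classes, GC-biased intensities, dead and
multi-mapping probes, phenotype-linked cohorts, deuterium enrichment
curves) so that every stage can be validated without any external data.

## The method

For probe `p` with GC fraction `gc` in sample `s`, probes are kept iff they
map to exactly one transcriptome location (exact matching, both strands),
have `0.20 <= gc <= 0.80`, and are detected above a per-sample background
(Gaussian fit to the lowest-intensity decile, detection at mean + 2 SD in
at least half of samples). Surviving probes are GC-corrected by
decile-binned median centering and summarized per probe set (FL / UTR3 /
UTR5 per transcript) as the member median in log2.

Differential expression uses the paired SAM statistic on within-subject
differences `delta = loaded - unloaded`:

    d = mean(delta) / (se(delta) + s0),    se = sd / sqrt(n)

with `s0` selected to decouple `d` from the variance level, a sign-flip
permutation null (fully enumerated when `2^n <= 10,000`), pooled plug-in
FDR q-values, and calls at q < 0.05 with linear fold change >= 1.2 (or
<= 1/1.2). A three-rule heuristic then classifies genes whose UTR response
diverges from the full-length fold change by more than 30% as
UTR-selective (or FL-selective, or 3'-vs-5' discordant).

Regulated genes are connected to phenotype by Spearman-correlating
per-subject expression changes with lean-mass changes in independent
cohorts; genes whose correlations share one sign in every study, with
|mean rho| >= 0.2, and which are regulated in the paired model form the
core growth signature. Co-expression networks keep edges at permutation
FDR < 1%, detect modules by greedy modularity with degree-preserving
rewiring significance (p < 0.01), and flag hubs above the 90th-percentile
within-module degree with binomial connectivity significance.

Physiology calculators implement the 1-RM prediction
`1RM = load / (1.0278 - 0.0278 * reps)`, the deuterium chain from saliva
delta-2H (per mil, VSMOW absolute ratio 0.00015595) to atom percent excess
(35x dilution), the precursor-product synthesis rate
`iMyoPS = dAPE_Ala / (APE_BW * 3.7 * t) * 100` (%/day), and the
response-heterogeneity CoV triplet for the trained leg, the unloaded leg
and their within-subject differential.

## Worked example

```r
library(utrflux)
library(SummarizedExperiment)

## a paired study: 100 genes, 6 subjects, planted effect classes
sim <- simulateStudy(nGenes = 100, nSubjects = 6, seed = 1)
table(sim$classes)
#> concordant_down   concordant_up  discordant_3v5    fl_selective
#>               5               5               5               5
#>            null  utr3_selective  utr5_selective
#>              70               5               5

## probe filtering against the generator's designed defects
counts <- mapProbes(rowData(sim$expr)$sequence, sim$transcriptome)
table(counts)                       # 90 designed multi-mapping probes
#> counts
#>    1    2
#> 1710   90
flt <- filterProbes(sim$expr, counts, fitBackground(sim$expr))
setequal(rowData(flt)$probe_id, sim$truth$probe_id[sim$truth$keep])
#> [1] TRUE

## region-wise paired differential expression
rs <- preprocessProbes(sim$expr, sim$transcriptome)
de <- regionDE(rs, nPerm = 200, seed = 3)
de$UTR3
#> PairedDEResult with 100 probe sets
#>   s0 = 0.2145 | permutations = 200 (full enumeration)
#>   called at q < 0.05 and FC >= 1.2 : 18 ( 14 up / 4 down )

## physiology
estimateOneRM(100, 10)
#> [1] 133.3689
enr <- simulateEnrichment(list(trueRate = 1.37, noiseSd = 0), seed = 1)
recoverSynthesisRate(enr)           # designed %/day recovered exactly
#> [1] 1.37
resp <- simulateResponses(seed = 3)
round(covTriplet(resp$rt, resp$ul), 1)
#>    rt    ul hypat
#> 123.9  76.5  43.5
```

The 90 duplicated probes are found by the exact-match mapper itself (their
sequences exist at a decoy locus), the kept probe set equals the designed
keep set exactly, the UTR3 analysis calls most of the planted UTR3-linked
classes at this small scale, and the paired response differential (`hypat`)
shows far less relative spread than either leg alone.

A full pipeline run — simulation, probe preprocessing, per-region DE,
UTR-pattern classification, cohort growth correlation, network modules and
turnover — is one call: `runPipeline(pipelineConfig(seed = 1), "out/")`.
It writes TSV outputs per stage plus a manifest with the configuration and
MD5 of every file; reruns are bit-identical. See the vignette
(`vignettes/region-resolved-regulation.Rmd`) for the model, parameter and
design discussion.

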