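#' Effect specification for the synthetic-data generator
#'
#' Bundles every knob of the generator: how genes are partitioned into planted
#' effect classes, the per-region log2 effect sizes, the intensity noise
#' model, the GC bias, and the designed fractions of dead and multi-mapping
#' probes. The defaults describe a plausible paired loading/unloading
#' experiment on a short-probe expression array and are shared by all
#' downstream property tests.
#'
#' Effect classes partition genes: \code{concordant_up}/\code{concordant_down}
#' shift all three regions by \code{effectConcordant} (up or down);
#' \code{utr3_selective}, \code{utr5_selective} and \code{fl_selective} shift
#' only the 3' UTR, 5' UTR or coding probes by \code{effectSelective};
#' \code{discordant_3v5} shifts the 3' UTR up and the 5' UTR down by
#' \code{effectConcordant}; the remaining genes are null.
#'
#' @slot classFractions named fractions of genes per non-null class (must sum
#'   to at most 1; the remainder is null).
#' @slot effectConcordant log2 effect for concordant and discordant classes
#'   (default \code{log2(1.5)}).
#' @slot effectSelective log2 effect for region-selective classes (default
#'   \code{log2(1.8)}, large enough that the fold-change divergence of a
#'   selective event is unambiguous).
#' @slot noiseSd residual SD of log2 intensity (default 0.25).
#' @slot subjectSd SD of the subject random intercept (default 0.3); cancels
#'   in within-subject differences.
#' @slot baseline mean log2 intensity of live probes (default 7.5).
#' @slot backgroundFloor,backgroundSd mean and SD of dead-probe log2
#'   intensity (defaults 4.0 and 0.2).
#' @slot gcSlope linear GC bias: added intensity is
#'   \code{gcSlope * (gc - 0.5)} (default 1).
#' @slot multimapFrac fraction of probes duplicated into a decoy locus so the
#'   exact-match mapper genuinely finds them twice (default 0.05).
#' @slot deadFrac fraction of probes emitting background-level signal
#'   (default 0.10).
#' @slot gcExtremeFrac fraction of probes designed with GC outside
#'   [0.20, 0.80] (default 0.05).
#' @slot phenoRho target Spearman correlation between a planted gene's
#'   expression change and the lean-mass change in the cohort generator
#'   (default 0.4).
#'
#' @return \code{effectSpec()} returns a validated \code{EffectSpec} object.
#' @examples
#' spec <- effectSpec(noiseSd = 0)
#' spec@effectConcordant
#' @export effectSpec
#' @exportClass EffectSpec
#' @aliases EffectSpec
setClass("EffectSpec",
    representation(classFractions = "numeric", effectConcordant = "numeric",
                   effectSelective = "numeric", noiseSd = "numeric",
                   subjectSd = "numeric", baseline = "numeric",
                   backgroundFloor = "numeric", backgroundSd = "numeric",
                   gcSlope = "numeric", multimapFrac = "numeric",
                   deadFrac = "numeric", gcExtremeFrac = "numeric",
                   phenoRho = "numeric"),
    prototype(classFractions = c(concordant_up = 0.05, concordant_down = 0.05,
                                 utr3_selective = 0.05, utr5_selective = 0.05,
                                 fl_selective = 0.05, discordant_3v5 = 0.05),
              effectConcordant = log2(1.5), effectSelective = log2(1.8),
              noiseSd = 0.25, subjectSd = 0.3, baseline = 7.5,
              backgroundFloor = 4.0, backgroundSd = 0.2, gcSlope = 1.0,
              multimapFrac = 0.05, deadFrac = 0.10, gcExtremeFrac = 0.05,
              phenoRho = 0.4))

setValidity("EffectSpec", function(object) {
    cls <- c("concordant_up", "concordant_down", "utr3_selective",
             "utr5_selective", "fl_selective", "discordant_3v5")
    if (!all(names(object@classFractions) %in% cls))
        return(paste("classFractions names must be among:",
                     paste(cls, collapse = ", ")))
    if (any(object@classFractions < 0) || sum(object@classFractions) > 1)
        return("classFractions must be non-negative and sum to at most 1")
    for (s in c("noiseSd", "subjectSd", "backgroundSd", "multimapFrac",
                "deadFrac", "gcExtremeFrac"))
        if (slot(object, s) < 0)
            return(paste(s, "must be non-negative"))
    if (object@multimapFrac + object@deadFrac + object@gcExtremeFrac >= 1)
        return("designed reject fractions leave no probes to keep")
    TRUE
})

#' @rdname EffectSpec-class
#' @param ... slots to override, by name (see the class documentation).
effectSpec <- function(...) new("EffectSpec", ...)

.EFFECT_CLASSES <- c("null", "concordant_up", "concordant_down",
                     "utr3_selective", "utr5_selective", "fl_selective",
                     "discordant_3v5")

## per-region log2 shift (loaded minus unloaded) implied by an effect class
.classEffects <- function(class, spec) {
    e <- c(CDS = 0, UTR3 = 0, UTR5 = 0)
    ec <- spec@effectConcordant
    es <- spec@effectSelective
    switch(class,
        concordant_up   = e + ec,
        concordant_down = e - ec,
        utr3_selective  = { e["UTR3"] <- es; e },
        utr5_selective  = { e["UTR5"] <- es; e },
        fl_selective    = { e["CDS"] <- es; e },
        discordant_3v5  = { e["UTR3"] <- ec; e["UTR5"] <- -ec; e },
        e)
}

## build one probe sequence with an exact designed G+C count
.probeSeq <- function(gcCount, len) {
    pos <- sample.int(len, gcCount)
    chars <- sample(c("A", "T"), len, replace = TRUE)
    chars[pos] <- sample(c("G", "C"), gcCount, replace = TRUE)
    paste(chars, collapse = "")
}

#' Generate synthetic gene models and a transcriptome
#'
#' Lays out one transcript per gene as 5' UTR, CDS and 3' UTR blocks, each
#' tiled end-to-end by probe-sized windows, and generates the transcript
#' sequence so that every probe window has a designed GC fraction. A fraction
#' \code{gcExtremeFrac} of windows receives GC outside [0.20, 0.80] so the
#' GC-extreme filter has designed targets.
#'
#' Coordinates in the returned model table are 0-based, half-open.
#'
#' @param nGenes number of genes (one transcript each).
#' @param probesPerRegion probes per region; a scalar (all regions) or a
#'   length-3 vector in the order CDS, UTR3, UTR5.
#' @param seed integer seed; the output is fully determined by it.
#' @param probeLength probe footprint in nucleotides (default 25).
#' @param gcExtremeFrac fraction of probe windows with extreme GC.
#' @return a list with \code{models} (DataFrame of region spans),
#'   \code{transcriptome} (a \code{DNAStringSet}), \code{probeWindows}
#'   (DataFrame of per-window placement and designed GC) and the generation
#'   parameters.
#' @examples
#' gm <- simulateGeneModels(2, 2, seed = 7)
#' gm$models
#' @export
simulateGeneModels <- function(nGenes, probesPerRegion, seed,
                               probeLength = 25L, gcExtremeFrac = 0.05) {
    nGenes <- .assertCount(nGenes, "nGenes")
    if (length(probesPerRegion) == 1L) probesPerRegion <- rep(probesPerRegion, 3L)
    if (length(probesPerRegion) != 3L || any(probesPerRegion < 1))
        stop("'probesPerRegion' must be a positive scalar or length-3 vector ",
             "(CDS, UTR3, UTR5)")
    probesPerRegion <- as.integer(probesPerRegion)
    names(probesPerRegion) <- c("CDS", "UTR3", "UTR5")
    probeLength <- .assertCount(probeLength, "probeLength")

    .withSeed(seed, {
        gene_ids <- sprintf("G%04d", seq_len(nGenes))
        tx_ids <- sprintf("TX%04d", seq_len(nGenes))
        ## transcript layout (5' -> 3'): UTR5 | CDS | UTR3
        lens <- probesPerRegion * probeLength
        starts <- c(UTR5 = 0L, CDS = lens[["UTR5"]],
                    UTR3 = lens[["UTR5"]] + lens[["CDS"]])
        region_order <- c("UTR5", "CDS", "UTR3")
        models <- DataFrame(
            gene_id = rep(gene_ids, each = 3L),
            transcript_id = rep(tx_ids, each = 3L),
            region = rep(region_order, nGenes),
            start = rep(unname(starts[region_order]), nGenes),
            end = rep(unname(starts[region_order] + lens[region_order]), nGenes))

        n_windows <- sum(probesPerRegion)
        total <- nGenes * n_windows
        extreme <- stats::runif(total) < gcExtremeFrac
        gc_target <- ifelse(extreme,
            ifelse(stats::runif(total) < 0.5,
                   stats::runif(total, 0.06, 0.16),
                   stats::runif(total, 0.84, 0.94)),
            stats::runif(total, 0.28, 0.72))
        gc_count <- as.integer(round(gc_target * probeLength))

        windows <- vector("list", nGenes)
        seqs <- character(nGenes)
        idx <- 0L
        for (g in seq_len(nGenes)) {
            region <- rep(region_order, times = probesPerRegion[region_order])
            w_start <- (seq_len(n_windows) - 1L) * probeLength
            w_seq <- vapply(gc_count[idx + seq_len(n_windows)],
                            .probeSeq, character(1), len = probeLength)
            seqs[g] <- paste(w_seq, collapse = "")
            windows[[g]] <- DataFrame(
                transcript_id = tx_ids[g], gene_id = gene_ids[g],
                region = region, start = w_start, end = w_start + probeLength,
                sequence = w_seq)
            idx <- idx + n_windows
        }
        transcriptome <- Biostrings::DNAStringSet(seqs)
        names(transcriptome) <- tx_ids
        list(models = models, transcriptome = transcriptome,
             probeWindows = do.call(rbind, windows),
             probeLength = probeLength, probesPerRegion = probesPerRegion)
    })
}

#' Generate probe records with designed dead and multi-mapping sets
#'
#' Derives one probe per tiling window of the gene models, computes its GC
#' fraction from the sequence, and designates a fraction of probes as dead
#' (background-level intensity) and a fraction as multi-mapping. Multi-mapping
#' is emulated honestly: the selected probe sequences are duplicated into a
#' decoy locus appended to the transcriptome, so an exact-match mapper
#' discovers the multiplicity rather than being told about it.
#'
#' @param geneModels output of [simulateGeneModels()].
#' @param spec an [EffectSpec-class] providing \code{deadFrac} and
#'   \code{multimapFrac}.
#' @param seed integer seed.
#' @return a list with \code{probes} (DataFrame: probe_id, transcript_id,
#'   gene_id, region, start, end, sequence, gc, dead, multimap),
#'   \code{transcriptome} (including the decoy locus), and \code{truth}
#'   (DataFrame of designed flags and the designed keep set).
#' @export
simulateProbes <- function(geneModels, spec = effectSpec(), seed = 1L) {
    if (is.null(geneModels$probeWindows) || !nrow(geneModels$probeWindows))
        stop("'geneModels' contains no probe windows; ",
             "run simulateGeneModels() first")
    probes <- geneModels$probeWindows
    n <- nrow(probes)
    probes$probe_id <- sprintf("P%06d", seq_len(n))
    gcat <- Biostrings::letterFrequency(
        Biostrings::DNAStringSet(probes$sequence), "GC")
    probes$gc <- as.numeric(gcat) / nchar(probes$sequence)

    .withSeed(seed, {
        dead <- logical(n)
        dead[sample.int(n, round(spec@deadFrac * n))] <- TRUE
        multimap <- logical(n)
        multimap[sample.int(n, round(spec@multimapFrac * n))] <- TRUE
        probes$dead <- dead
        probes$multimap <- multimap

        transcriptome <- geneModels$transcriptome
        if (any(multimap)) {
            decoy <- Biostrings::DNAStringSet(
                paste(sample(probes$sequence[multimap]), collapse = ""))
            names(decoy) <- "DECOY01"
            transcriptome <- c(transcriptome, decoy)
        }
        truth <- DataFrame(
            probe_id = probes$probe_id,
            dead = dead, multimap = multimap,
            gc_extreme = probes$gc < 0.20 | probes$gc > 0.80)
        truth$keep <- !truth$dead & !truth$multimap & !truth$gc_extreme
        list(probes = probes, transcriptome = transcriptome, truth = truth)
    })
}

#' Assign planted effect classes to genes
#'
#' Partitions the gene ids into the classes of an [EffectSpec-class]; the
#' assignment (and hence every downstream planted effect) is determined by
#' the seed.
#'
#' @param geneIds character vector of gene ids.
#' @param spec an [EffectSpec-class].
#' @param seed integer seed.
#' @return a named character vector: class per gene.
#' @export
assignEffectClasses <- function(geneIds, spec = effectSpec(), seed = 1L) {
    n <- length(geneIds)
    counts <- round(spec@classFractions * n)
    .withSeed(seed, {
        cls <- rep("null", n)
        pool <- sample.int(n)
        at <- 0L
        for (k in names(counts)) {
            take <- min(counts[[k]], n - at)
            if (take > 0) cls[pool[at + seq_len(take)]] <- k
            at <- at + take
        }
        names(cls) <- geneIds
        cls
    })
}

#' Paired study design table
#'
#' One sample per subject per condition; conditions default to
#' \code{"unloaded"} and \code{"loaded"} (the within-subject contrast is
#' loaded minus unloaded).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param conditions length-2 character vector, reference condition first.
#' @param studyId label stored with the design.
#' @return DataFrame with sample_id, subject_id, condition, study_id.
#' @export
studyDesign <- function(nSubjects, conditions = c("unloaded", "loaded"),
                        studyId = "paired") {
    nSubjects <- .assertCount(nSubjects, "nSubjects", min = 2L)
    if (length(conditions) != 2L || anyDuplicated(conditions))
        stop("'conditions' must be two distinct labels")
    subj <- sprintf("S%02d", seq_len(nSubjects))
    DataFrame(
        sample_id = paste(rep(subj, each = 2L), rep(conditions, nSubjects),
                          sep = "_"),
        subject_id = rep(subj, each = 2L),
        condition = rep(conditions, nSubjects),
        study_id = studyId)
}

#' Simulate probe-level log2 intensities
#'
#' Log2 intensity of a live probe is baseline + GC bias + subject random
#' intercept + the planted condition-by-region effect + Gaussian noise; dead
#' probes emit the background floor plus background noise in every sample.
#' The model is additive on the log2 scale throughout.
#'
#' @param probeSim output of [simulateProbes()].
#' @param design a design table from [studyDesign()].
#' @param spec an [EffectSpec-class].
#' @param classes named class-per-gene vector from [assignEffectClasses()].
#' @param seed integer seed.
#' @return a [ProbeExperiment-class].
#' @export
simulateExpression <- function(probeSim, design, spec = effectSpec(),
                               classes, seed = 1L) {
    probes <- probeSim$probes
    if (!nrow(probes)) stop("no probes to simulate")
    if (!all(c("sample_id", "subject_id", "condition") %in% colnames(design)))
        stop("'design' must have sample_id, subject_id and condition columns")
    if (missing(classes))
        classes <- structure(rep("null", length(unique(probes$gene_id))),
                             names = unique(probes$gene_id))
    if (!all(probes$gene_id %in% names(classes)))
        stop("every gene needs an effect class")

    n_probe <- nrow(probes)
    n_samp <- nrow(design)
    ## reference condition is the first label encountered; the other is "loaded"
    ref <- design$condition[1L]
    loaded <- design$condition != ref

    ## per-probe planted effect (applied in the loaded condition only)
    eff <- numeric(n_probe)
    for (g in unique(probes$gene_id)) {
        ce <- .classEffects(classes[[g]], spec)
        i <- probes$gene_id == g
        eff[i] <- ce[probes$region[i]]
    }

    .withSeed(seed, {
        subj <- unique(design$subject_id)
        b <- stats::rnorm(length(subj), 0, spec@subjectSd)
        names(b) <- subj
        base <- spec@baseline + spec@gcSlope * (probes$gc - 0.5)
        m <- matrix(0, n_probe, n_samp,
                    dimnames = list(probes$probe_id, design$sample_id))
        for (j in seq_len(n_samp)) {
            mu <- base + b[[design$subject_id[j]]] + if (loaded[j]) eff else 0
            m[, j] <- mu + stats::rnorm(n_probe, 0, spec@noiseSd)
            if (any(probes$dead))
                m[probes$dead, j] <- spec@backgroundFloor +
                    stats::rnorm(sum(probes$dead), 0, spec@backgroundSd)
        }
        rd <- probes[, c("probe_id", "transcript_id", "gene_id", "region",
                         "start", "end", "sequence", "gc", "dead", "multimap")]
        cd <- as(design, "DataFrame")
        rownames(cd) <- design$sample_id
        new("ProbeExperiment", SummarizedExperiment(
            assays = list(log2intensity = m), rowData = rd, colData = cd))
    })
}

#' One-call synthetic paired study
#'
#' Convenience wrapper chaining [simulateGeneModels()], [simulateProbes()],
#' [assignEffectClasses()], [studyDesign()] and [simulateExpression()] under a
#' single seed, returning every ground-truth table alongside the data. The
#' defaults describe the paired-cohort scale used throughout the package's
#' property tests: 1,000 genes, a 10/4/4 CDS/UTR3/UTR5 probe tiling and 12
#' paired subjects.
#'
#' @param nGenes,probesPerRegion,nSubjects study dimensions.
#' @param spec an [EffectSpec-class].
#' @param seed integer seed determining every random draw.
#' @return list with \code{expr} ([ProbeExperiment-class]),
#'   \code{transcriptome}, \code{design}, \code{classes} (ground-truth class
#'   per gene), \code{truth} (designed probe flags and keep set) and
#'   \code{models}.
#' @examples
#' sim <- simulateStudy(nGenes = 20, nSubjects = 4, seed = 1)
#' table(sim$classes)
#' @export
simulateStudy <- function(nGenes = 1000L,
                          probesPerRegion = c(CDS = 10L, UTR3 = 4L, UTR5 = 4L),
                          nSubjects = 12L, spec = effectSpec(), seed = 1L) {
    gm <- simulateGeneModels(nGenes, probesPerRegion, seed = seed,
                             gcExtremeFrac = spec@gcExtremeFrac)
    ps <- simulateProbes(gm, spec, seed = seed + 1L)
    classes <- assignEffectClasses(unique(ps$probes$gene_id), spec,
                                   seed = seed + 2L)
    design <- studyDesign(nSubjects)
    expr <- simulateExpression(ps, design, spec, classes, seed = seed + 3L)
    list(expr = expr, transcriptome = ps$transcriptome, design = design,
         classes = classes, truth = ps$truth, models = gm$models)
}

#' Simulate training cohorts with phenotype-linked expression changes
#'
#' Emulates independent pre/post training studies, each with a per-subject
#' lean-mass change (\code{llm}, in percent) and a probe-set level expression
#' matrix at both timepoints. Genes in \code{linkedGenes} change expression
#' monotonically with the latent growth that also drives \code{llm}; the link
#' strength is calibrated so that the population Spearman correlation equals
#' \code{spec@phenoRho}. All other genes change independently of growth.
#'
#' @param geneIds character vector of gene (or probe-set) ids simulated in
#'   every study.
#' @param linkedGenes subset of \code{geneIds} with a phenotype link.
#' @param linkSign named +1/-1 vector over \code{linkedGenes} (default +1).
#' @param studySizes subjects per study (default 34, 19 and 47; at least 2
#'   each).
#' @param spec an [EffectSpec-class] (uses \code{phenoRho}).
#' @param seed integer seed.
#' @return a named list of studies, each with \code{pre}, \code{post} (gene x
#'   subject log2 matrices), \code{delta} (= post - pre) and \code{llm}.
#' @export
simulateCohorts <- function(geneIds, linkedGenes = character(0),
                            linkSign = NULL, studySizes = c(34L, 19L, 47L),
                            spec = effectSpec(), seed = 1L) {
    if (any(studySizes < 2)) stop("every study needs at least 2 subjects")
    if (!all(linkedGenes %in% geneIds))
        stop("'linkedGenes' must be a subset of 'geneIds'")
    if (is.null(linkSign))
        linkSign <- structure(rep(1, length(linkedGenes)), names = linkedGenes)
    ## Spearman target -> Pearson under bivariate normality
    rho_p <- 2 * sin(pi * spec@phenoRho / 6)
    sigma_e <- sqrt(1 / rho_p^2 - 1)
    G <- length(geneIds)
    .withSeed(seed, {
        out <- vector("list", length(studySizes))
        for (s in seq_along(studySizes)) {
            n <- studySizes[s]
            growth <- stats::rnorm(n)
            llm <- 3 + 3 * growth
            delta <- matrix(stats::rnorm(G * n), G, n,
                            dimnames = list(geneIds, sprintf("V%02d", 1:n)))
            if (length(linkedGenes)) {
                i <- match(linkedGenes, geneIds)
                delta[i, ] <- linkSign[linkedGenes] *
                    rep(growth, each = length(i)) +
                    matrix(stats::rnorm(length(i) * n, 0, sigma_e),
                           length(i), n)
            }
            pre <- matrix(7 + stats::rnorm(G * n), G, n,
                          dimnames = dimnames(delta))
            out[[s]] <- list(pre = pre, post = pre + delta, delta = delta,
                             llm = llm)
        }
        names(out) <- sprintf("study%d", seq_along(studySizes))
        out
    })
}

#' Simulate a deuterated-water enrichment time course
#'
#' Emulates oral heavy-water dosing: the body-water pool is enriched during a
#' short loading phase and then held at a plateau (atom percent excess, APE)
#' through maintenance dosing. Saliva enrichment is reported on the delta
#' notation scale (per mil versus the VSMOW standard) after the 35-fold
#' sample dilution used at measurement, so the analysis-side conversion chain
#' can be exercised end to end. Protein-bound alanine enrichment accumulates
#' according to a designed true fractional synthesis rate through the
#' precursor-product relation, making rate recovery testable.
#'
#' @param schedule list with \code{loadingDays}, \code{maintenanceDays},
#'   \code{plateau} (body-water APE, default 0.5), \code{trueRate} (percent
#'   per day), \code{biopsyDays} and optional \code{noiseSd} (APE noise on
#'   the saliva series) and \code{backgroundDelta} (baseline per-mil value).
#' @param seed integer seed.
#' @return list with \code{saliva} (day, delta2H, true body-water APE),
#'   \code{protein} (biopsy day, protein-bound alanine APE), and the design
#'   values (\code{trueRate}, \code{plateau}, \code{dilution}).
#' @export
simulateEnrichment <- function(schedule = list(), seed = 1L) {
    if (!length(schedule)) stop("'schedule' must not be empty")
    s <- utils::modifyList(list(loadingDays = 1, maintenanceDays = 17,
                                plateau = 0.5, trueRate = 1.37,
                                biopsyDays = c(1, 4, 18), noiseSd = 0.005,
                                backgroundDelta = -60), schedule)
    days <- 0:(s$loadingDays + s$maintenanceDays)
    ape_bw <- pmin(days / s$loadingDays, 1) * s$plateau
    .withSeed(seed, {
        ape_obs <- ape_bw
        if (s$noiseSd > 0 && length(days) > 1)
            ape_obs[-1] <- ape_obs[-1] +
                stats::rnorm(length(days) - 1, 0, s$noiseSd)
        ## saliva series on the measured (diluted) delta scale:
        ## AP_sample = AP_background + APE / dilution, then invert Eq. AP(delta)
        ap_bg <- deltaToAtomPercent(s$backgroundDelta)
        ap <- ap_bg + ape_obs / 35
        ratio <- ap / (100 - ap)
        delta2H <- (ratio / 0.00015595 - 1) * 1000
        ## protein-bound alanine APE: precursor-product forward model
        ## d(APE_Ala)/dt = trueRate/100 * 3.7 * APE_BW(t)
        cumald <- c(0, cumsum((ape_bw[-1] + ape_bw[-length(ape_bw)]) / 2))
        ape_ala_daily <- s$trueRate / 100 * 3.7 * cumald
        bi <- match(s$biopsyDays, days)
        if (anyNA(bi)) stop("biopsyDays must be whole days within the schedule")
        list(saliva = data.frame(day = days, delta2H = delta2H,
                                 ape_bw = ape_bw),
             protein = data.frame(day = s$biopsyDays,
                                  ape_ala = ape_ala_daily[bi]),
             trueRate = s$trueRate, plateau = s$plateau, dilution = 35)
    })
}

#' Simulate paired loading/unloading physiological responses
#'
#' Per-subject percent changes in muscle size for the trained (RT) and
#' immobilized (UL) leg, sharing a subject-level responsiveness component
#' \code{b}: responsive subjects gain more with training and lose less with
#' immobilization. The within-subject differential (RT - UL) cancels \code{b},
#' which is what makes the paired contrast less heterogeneous than either leg
#' alone. Defaults are calibrated to give response dispersion comparable to
#' observed training/immobilization studies (coefficients of variation near
#' 90\%, 88\% and 49\% for RT, UL and the differential).
#'
#' @param nSubjects number of subjects.
#' @param meanRT,meanUL mean percent change per leg.
#' @param sdShared SD of the shared responsiveness component.
#' @param sdRT,sdUL residual SDs per leg.
#' @param seed integer seed.
#' @return data.frame with per-subject \code{rt}, \code{ul} and
#'   \code{hypat} (= rt - ul) percent changes.
#' @export
simulateResponses <- function(nSubjects = 12L, meanRT = 5, meanUL = -3.4,
                              sdShared = 2.49, sdRT = 3.74, sdUL = 1.67,
                              seed = 1L) {
    nSubjects <- .assertCount(nSubjects, "nSubjects", min = 2L)
    .withSeed(seed, {
        b <- stats::rnorm(nSubjects, 0, sdShared)
        rt <- meanRT + b + stats::rnorm(nSubjects, 0, sdRT)
        ul <- meanUL + b + stats::rnorm(nSubjects, 0, sdUL)
        data.frame(subject = sprintf("S%02d", seq_len(nSubjects)),
                   rt = rt, ul = ul, hypat = rt - ul)
    })
}

#' Write generator outputs as plain-text files
#'
#' Serializes a [simulateStudy()] result to a directory: transcriptome FASTA,
#' probe annotation TSV (0-based half-open coordinates), intensity TSV,
#' design TSV and ground-truth TSVs. All outputs are deterministic given the
#' simulation.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeStudy <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
        transcriptome = file.path(dir, "transcriptome.fa"),
        probes = file.path(dir, "probes.tsv"),
        intensity = file.path(dir, "intensity.tsv"),
        design = file.path(dir, "design.tsv"),
        truth_probes = file.path(dir, "truth_probes.tsv"),
        truth_classes = file.path(dir, "truth_classes.tsv"))
    Biostrings::writeXStringSet(sim$transcriptome, paths[["transcriptome"]])
    .writeTSV(as.data.frame(rowData(sim$expr)), paths[["probes"]])
    m <- assay(sim$expr, "log2intensity")
    .writeTSV(data.frame(probe_id = rownames(m), m, check.names = FALSE),
              paths[["intensity"]])
    .writeTSV(as.data.frame(sim$design), paths[["design"]])
    .writeTSV(as.data.frame(sim$truth), paths[["truth_probes"]])
    .writeTSV(data.frame(gene_id = names(sim$classes), class = sim$classes),
              paths[["truth_classes"]])
    invisible(paths)
}
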