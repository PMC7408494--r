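#' Count exact probe occurrences in a transcriptome
#'
#' Exact-substring mapper: the mapping count of a probe is the number of
#' distinct (sequence, offset) occurrences of the probe across the
#' transcriptome, counting reverse-complement matches as well. Probes that
#' were duplicated into a second locus therefore come back with a count of 2.
#'
#' @param probeSequences character vector (or \code{DNAStringSet}) of probe
#'   sequences; all the same length, ACGT only.
#' @param transcriptome a \code{DNAStringSet} of target sequences.
#' @return integer vector of mapping counts, one per probe.
#' @examples
#' tx <- Biostrings::DNAStringSet(c(t1 = "ACGTACGTACGT"))
#' mapProbes(c("ACGTA", "TTTTT"), tx)
#' @export
mapProbes <- function(probeSequences, transcriptome) {
    if (is.character(probeSequences)) {
        if (any(grepl("[^ACGT]", probeSequences)))
            stop("probe sequences must contain only A, C, G, T")
        probeSequences <- Biostrings::DNAStringSet(probeSequences)
    }
    if (length(unique(Biostrings::width(probeSequences))) > 1L)
        stop("all probes must have the same length")
    if (any(Biostrings::width(probeSequences) >
            min(Biostrings::width(transcriptome))))
        stop("probe length exceeds the shortest target sequence")
    fwd <- Biostrings::PDict(probeSequences)
    counts <- rowSums(Biostrings::vcountPDict(fwd, transcriptome))
    rev <- Biostrings::PDict(Biostrings::reverseComplement(probeSequences))
    counts <- counts + rowSums(Biostrings::vcountPDict(rev, transcriptome))
    as.integer(counts)
}

#' Fit a per-sample background model
#'
#' Models background signal per sample as a Gaussian fitted to the
#' lowest-intensity decile of probes in that sample; the dataset itself thus
#' defines its own background. A probe is later declared detected in a sample
#' when it exceeds \code{mu + k * sigma}.
#'
#' @param x a [ProbeExperiment-class] or a probes x samples log2 matrix.
#' @param decile fraction of lowest-intensity probes used per sample.
#' @param k detection stringency in background SDs.
#' @return a [BackgroundModel-class].
#' @export
fitBackground <- function(x, decile = 0.1, k = 2) {
    m <- if (is(x, "SummarizedExperiment")) assay(x, "log2intensity") else x
    if (!nrow(m)) stop("no probes to fit a background from")
    nlow <- max(2L, floor(decile * nrow(m)))
    mu <- sigma <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        low <- sort(m[, j], partial = nlow)[seq_len(nlow)]
        mu[j] <- mean(low)
        sigma[j] <- stats::sd(low)
    }
    names(mu) <- names(sigma) <- colnames(m)
    new("BackgroundModel", mu = mu, sigma = sigma, k = k, decile = decile)
}

#' Detection-above-background calls
#'
#' @param x a [ProbeExperiment-class] or log2 matrix.
#' @param background a fitted [BackgroundModel-class].
#' @param minFraction fraction of samples in which a probe must exceed the
#'   background threshold to count as detected (default 0.5).
#' @return logical vector, one entry per probe.
#' @export
detectedAboveBackground <- function(x, background, minFraction = 0.5) {
    m <- if (is(x, "SummarizedExperiment")) assay(x, "log2intensity") else x
    if (ncol(m) != length(background@mu))
        stop("background model was fitted on a different number of samples")
    thr <- background@mu + background@k * background@sigma
    hits <- sweep(m, 2L, thr, ">")
    rowMeans(hits) >= minFraction
}

#' Probe filtering: unique mapping, GC window, above background
#'
#' Applies the three probe-level filters in one conjunction: a probe is kept
#' iff its mapping count is exactly 1, its GC fraction lies within
#' \code{[gcLow, gcHigh]} (defaults 0.20 and 0.80; probes outside are removed
#' because GC correction is unreliable at the extremes), and it is detected
#' above the per-sample background in at least half the samples. The kept set
#' is a pure conjunction, so it does not depend on the order of the filters;
#' the rejection log attributes one primary reason per dropped probe using
#' the fixed priority mapping > GC > background.
#'
#' @param pe a [ProbeExperiment-class] with intensities and \code{gc} in
#'   \code{rowData}.
#' @param mappingCounts integer vector from [mapProbes()] (same probe order).
#' @param background a fitted [BackgroundModel-class].
#' @param gcLow,gcHigh inclusive GC window.
#' @param minFraction detection fraction passed to
#'   [detectedAboveBackground()].
#' @return the filtered [ProbeExperiment-class]; attribute
#'   \code{"rejectionLog"} holds a data.frame (probe_id, reason) for every
#'   dropped probe.
#' @export
filterProbes <- function(pe, mappingCounts, background,
                         gcLow = 0.20, gcHigh = 0.80, minFraction = 0.5) {
    if (!is(background, "BackgroundModel"))
        stop("'background' must be a fitted BackgroundModel")
    if (length(mappingCounts) != nrow(pe))
        stop("one mapping count per probe is required")
    gc <- rowData(pe)$gc
    ok_map <- mappingCounts == 1L
    ok_gc <- gc >= gcLow & gc <= gcHigh
    ok_bg <- detectedAboveBackground(pe, background, minFraction)
    keep <- ok_map & ok_gc & ok_bg
    reason <- rep(NA_character_, nrow(pe))
    reason[!ok_bg] <- "background"
    reason[!ok_gc] <- "gc"
    reason[!ok_map] <- "multimap"
    log <- data.frame(probe_id = rowData(pe)$probe_id[!keep],
                      reason = reason[!keep])
    out <- pe[keep, ]
    attr(out, "rejectionLog") <- log
    out
}

#' GC correction by decile-binned median centering
#'
#' Probes are binned into deciles of their GC fraction (empty bins merge into
#' their neighbor by construction, since bin edges are GC quantiles). Within
#' each sample, the bin median is subtracted and the sample's global median
#' added back, removing the systematic GC trend while preserving rank order
#' within a bin and the overall signal level.
#'
#' @param pe a (filtered) [ProbeExperiment-class].
#' @param nBins number of GC quantile bins (default 10).
#' @return the [ProbeExperiment-class] with a corrected
#'   \code{log2intensity} assay.
#' @export
gcCorrect <- function(pe, nBins = 10L) {
    m <- assay(pe, "log2intensity")
    gc <- rowData(pe)$gc
    breaks <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(breaks) < 2L) {
        bins <- factor(rep(1L, length(gc)))      # all probes share one GC value
    } else {
        bins <- cut(gc, breaks, include.lowest = TRUE)
    }
    for (j in seq_len(ncol(m))) {
        med_all <- stats::median(m[, j])
        med_bin <- tapply(m[, j], bins, stats::median)
        m[, j] <- m[, j] - med_bin[as.integer(bins)] + med_all
    }
    assays(pe)$log2intensity <- m
    pe
}

#' Build the custom probe-set definition (CDF)
#'
#' Groups surviving probes into probe sets: for every transcript, a
#' full-length set (\code{FL}: all remaining probes of the transcript), a
#' \code{UTR3} set and a \code{UTR5} set restricted to probes in the
#' respective untranslated region. Sets left empty by filtering are dropped
#' and recorded in the \code{"droppedSets"} attribute.
#'
#' @param pe a filtered [ProbeExperiment-class].
#' @return data.frame with columns probe_set_id, transcript_id, gene_id,
#'   region (FL/UTR3/UTR5) and probe_id (one row per membership).
#' @export
buildCDF <- function(pe) {
    rd <- as.data.frame(rowData(pe))
    mk <- function(sub, tag) {
        if (!nrow(sub)) return(NULL)
        data.frame(probe_set_id = paste(sub$transcript_id, tag, sep = ":"),
                   transcript_id = sub$transcript_id, gene_id = sub$gene_id,
                   region = tag, probe_id = sub$probe_id)
    }
    cdf <- rbind(mk(rd, "FL"),
                 mk(rd[rd$region == "UTR3", ], "UTR3"),
                 mk(rd[rd$region == "UTR5", ], "UTR5"))
    ## transcripts whose UTR sets vanished entirely under filtering
    all_tx <- unique(rd$transcript_id)
    expected <- c(paste(all_tx, "FL", sep = ":"),
                  paste(all_tx, "UTR3", sep = ":"),
                  paste(all_tx, "UTR5", sep = ":"))
    attr(cdf, "droppedSets") <- setdiff(expected, unique(cdf$probe_set_id))
    cdf
}

#' Summarize probe sets into region-level signal
#'
#' The probe-set value in each sample is the median of its member probes'
#' (GC-corrected) log2 intensities: a robust summary that is monotone in
#' every member probe and invariant to probe order.
#'
#' @param pe a filtered, GC-corrected [ProbeExperiment-class].
#' @param cdf probe-set definition from [buildCDF()].
#' @return a [RegionExperiment-class] (probe sets x samples).
#' @export
summarizeProbeSets <- function(pe, cdf) {
    m <- assay(pe, "log2intensity")
    idx <- match(cdf$probe_id, rowData(pe)$probe_id)
    if (anyNA(idx)) stop("CDF refers to probes absent from the experiment")
    sets <- unique(cdf[, c("probe_set_id", "transcript_id", "gene_id",
                           "region")])
    members <- split(idx, cdf$probe_set_id)[sets$probe_set_id]
    sig <- t(vapply(members, function(i)
        if (length(i) == 1L) m[i, ] else apply(m[i, , drop = FALSE], 2L,
                                               stats::median),
        numeric(ncol(m))))
    rd <- DataFrame(probe_set_id = sets$probe_set_id,
                    transcript_id = sets$transcript_id,
                    gene_id = sets$gene_id, region = sets$region,
                    n_probes = lengths(members))
    rownames(sig) <- sets$probe_set_id
    new("RegionExperiment", SummarizedExperiment(
        assays = list(log2signal = sig), rowData = rd,
        colData = colData(pe)))
}

#' Full probe-level preprocessing in one call
#'
#' Chains [mapProbes()], [fitBackground()], [filterProbes()], [gcCorrect()],
#' [buildCDF()] and [summarizeProbeSets()].
#'
#' @param pe a [ProbeExperiment-class].
#' @param transcriptome a \code{DNAStringSet} to map probes against.
#' @param gcLow,gcHigh GC window for [filterProbes()].
#' @return a [RegionExperiment-class]; attributes \code{"rejectionLog"} and
#'   \code{"cdf"} carry the intermediate results.
#' @export
preprocessProbes <- function(pe, transcriptome, gcLow = 0.20, gcHigh = 0.80) {
    counts <- mapProbes(rowData(pe)$sequence, transcriptome)
    bg <- fitBackground(pe)
    flt <- filterProbes(pe, counts, bg, gcLow = gcLow, gcHigh = gcHigh)
    log <- attr(flt, "rejectionLog")
    flt <- gcCorrect(flt)
    cdf <- buildCDF(flt)
    rs <- summarizeProbeSets(flt, cdf)
    attr(rs, "rejectionLog") <- log
    attr(rs, "cdf") <- cdf
    rs
}
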