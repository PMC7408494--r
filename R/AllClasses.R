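#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Probe-level intensity container
#'
#' A \linkS4class{SummarizedExperiment} holding one log2 intensity matrix
#' (probes x samples) together with the per-probe annotation required by the
#' filtering pipeline: probe sequence, GC fraction, transcript/region
#' assignment and (once computed) genomic mapping multiplicity.
#'
#' Required \code{rowData} columns: \code{probe_id}, \code{transcript_id},
#' \code{gene_id}, \code{region} (one of \code{"CDS"}, \code{"UTR3"},
#' \code{"UTR5"}), \code{start}, \code{end} (0-based, half-open coordinates on
#' the transcript), \code{sequence}, \code{gc}.
#'
#' @export
setClass("ProbeExperiment", contains = "SummarizedExperiment")

setValidity("ProbeExperiment", function(object) {
    req <- c("probe_id", "transcript_id", "gene_id", "region",
             "start", "end", "sequence", "gc")
    rd <- rowData(object)
    miss <- setdiff(req, colnames(rd))
    if (length(miss))
        return(paste("missing rowData column(s):", paste(miss, collapse = ", ")))
    if (!"log2intensity" %in% names(assays(object)))
        return("assay 'log2intensity' is required")
    if (nrow(object) && (any(rd$gc < 0) || any(rd$gc > 1)))
        return("gc fractions must lie in [0, 1]")
    if (!all(rd$region %in% c("CDS", "UTR3", "UTR5")))
        return("region must be one of 'CDS', 'UTR3', 'UTR5'")
    if (anyDuplicated(rd$probe_id))
        return("probe_id values must be unique")
    TRUE
})

#' Region-level (probe-set) signal container
#'
#' A \linkS4class{SummarizedExperiment} of summarized log2 expression, one row
#' per probe set, i.e. per (transcript, region tag) pair where the region tag
#' is \code{"FL"} (all probes of the transcript), \code{"UTR3"} or
#' \code{"UTR5"}.
#'
#' @export
setClass("RegionExperiment", contains = "SummarizedExperiment")

setValidity("RegionExperiment", function(object) {
    req <- c("probe_set_id", "transcript_id", "gene_id", "region", "n_probes")
    rd <- rowData(object)
    miss <- setdiff(req, colnames(rd))
    if (length(miss))
        return(paste("missing rowData column(s):", paste(miss, collapse = ", ")))
    if (!"log2signal" %in% names(assays(object)))
        return("assay 'log2signal' is required")
    if (!all(rd$region %in% c("FL", "UTR3", "UTR5")))
        return("region tag must be one of 'FL', 'UTR3', 'UTR5'")
    if (nrow(object) && any(rd$n_probes < 1))
        return("probe sets must contain at least one probe")
    if (nrow(object) && !all(is.finite(assay(object, "log2signal"))))
        return("summarized signal must be finite")
    TRUE
})

#' Per-sample additive Gaussian background model
#'
#' Fitted from the lowest-intensity decile of probes in each sample; a probe
#' is detected in a sample when its log2 intensity exceeds
#' \code{mu + k * sigma} for that sample.
#'
#' @slot mu per-sample mean of the lowest-decile intensities.
#' @slot sigma per-sample standard deviation of the lowest-decile intensities.
#' @slot k detection stringency in background SDs (default 2).
#' @slot decile fraction of probes used to fit the background (default 0.1).
#' @export
setClass("BackgroundModel",
    representation(mu = "numeric", sigma = "numeric",
                   k = "numeric", decile = "numeric"))

setValidity("BackgroundModel", function(object) {
    if (length(object@mu) != length(object@sigma))
        return("mu and sigma must have one value per sample")
    if (object@k <= 0) return("k must be positive")
    TRUE
})

#' Paired SAM differential expression result
#'
#' Holds the per-probe-set paired statistics for one region tag: mean paired
#' log2 difference, linear fold change (oriented so that values > 1 mean
#' higher in the loaded condition), the regularized d statistic, the
#' permutation q-value and the final call under the FDR/fold-change gate.
#'
#' @slot results a \code{DataFrame} with one row per probe set.
#' @slot s0 the exchangeability (fudge) factor used in the d statistic.
#' @slot nPerm number of sign-flip permutations (full enumeration when
#'   feasible).
#' @slot enumerated logical; \code{TRUE} when all 2^n sign patterns were used.
#' @slot fdrCut,fcCut thresholds used by the call.
#' @export
setClass("PairedDEResult",
    representation(results = "DataFrame", s0 = "numeric", nPerm = "numeric",
                   enumerated = "logical", fdrCut = "numeric", fcCut = "numeric"))

setValidity("PairedDEResult", function(object) {
    req <- c("probe_set_id", "mean_delta", "fc", "d", "q", "called", "direction")
    miss <- setdiff(req, colnames(object@results))
    if (length(miss))
        return(paste("missing results column(s):", paste(miss, collapse = ", ")))
    q <- object@results$q
    if (length(q) && (any(q < 0) || any(q > 1)))
        return("q-values must lie in [0, 1]")
    TRUE
})

#' Co-expression network with permutation-gated modules
#'
#' @slot graph an \code{igraph} object; edge attribute \code{rho} stores the
#'   signed Spearman correlation, \code{weight} its absolute value.
#' @slot edges data.frame of retained edges (from, to, rho, p, q).
#' @slot modules list of character vectors of node ids (disjoint).
#' @slot moduleP permutation significance per module.
#' @slot moduleKeep logical; module p below the significance gate.
#' @slot hubs character vector of hub node ids.
#' @slot nullEdgeRate estimated probability that a null node pair passes the
#'   edge FDR gate (used for hub connectivity significance).
#' @slot nSamples number of samples the correlations were computed from.
#' @slot params list of thresholds used.
#' @export
setClass("CoexpressionNetwork",
    representation(graph = "ANY", edges = "data.frame", modules = "list",
                   moduleP = "numeric", moduleKeep = "logical",
                   hubs = "character", nullEdgeRate = "numeric",
                   nSamples = "numeric", params = "list"))

setValidity("CoexpressionNetwork", function(object) {
    if (length(object@modules) != length(object@moduleP))
        return("one significance value per module is required")
    if (length(object@modules) > 1) {
        all_nodes <- unlist(object@modules)
        if (anyDuplicated(all_nodes))
            return("modules must be disjoint")
    }
    if (length(object@hubs) &&
        !all(object@hubs %in% unlist(object@modules)))
        return("every hub must belong to a module")
    TRUE
})
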