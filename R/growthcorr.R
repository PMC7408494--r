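#' Pre/post expression change per subject
#'
#' @param pre,post gene x subject log2 matrices with identical dimnames.
#' @return matrix of differences (post minus pre). Subjects present in only
#'   one matrix are excluded, with a message listing them.
#' @export
studyDelta <- function(pre, post) {
    common <- intersect(colnames(pre), colnames(post))
    lost <- setdiff(union(colnames(pre), colnames(post)), common)
    if (length(lost))
        message("excluding unpaired subject(s): ", paste(lost, collapse = ", "))
    if (!length(common)) stop("no paired subjects")
    post[, common, drop = FALSE] - pre[, common, drop = FALSE]
}

#' Spearman correlation of expression change with lean-mass change
#'
#' Row-wise Spearman rank correlation (midranks for ties) between each
#' gene's expression change and the per-subject phenotype change. Genes with
#' zero variance are returned as \code{NA} and flagged.
#'
#' @param deltaExpr gene x subject matrix of expression changes.
#' @param deltaLLM numeric phenotype change per subject (same order).
#' @param warnSmall warn when fewer than this many subjects are available
#'   (default 30, below which rank correlations are unreliable).
#' @return data.frame with gene id, \code{rho} and \code{n}.
#' @export
spearmanCC <- function(deltaExpr, deltaLLM, warnSmall = 30L) {
    if (is.null(dim(deltaExpr)))
        deltaExpr <- matrix(deltaExpr, nrow = 1)
    if (is.null(rownames(deltaExpr)))
        rownames(deltaExpr) <- sprintf("gene%04d", seq_len(nrow(deltaExpr)))
    n <- ncol(deltaExpr)
    if (n != length(deltaLLM)) stop("one phenotype value per subject required")
    if (n < 3L) stop("at least 3 subjects are required")
    if (n < warnSmall)
        warning(sprintf("n = %d subjects: correlations below n = %d are unreliable",
                        n, warnSmall))
    if (stats::sd(deltaLLM) == 0) stop("phenotype has zero variance")
    ry <- rank(deltaLLM)
    rx <- t(apply(deltaExpr, 1L, rank))
    rho <- suppressWarnings(as.numeric(stats::cor(t(rx), ry)))
    rho[apply(deltaExpr, 1L, stats::sd) == 0] <- NA_real_
    data.frame(gene_id = rownames(deltaExpr), rho = rho, n = n)
}

#' Aggregate growth correlations across studies into a core signature
#'
#' A gene is directionally consistent when its correlation coefficient has
#' the same (nonzero) sign in every study. The core signature intersects
#' consistency with an absolute mean-correlation floor and with the set of
#' genes regulated in the paired loading model; the regulated set is taken
#' at the gene level (regulated at any region).
#'
#' @param ccTable data.frame with columns \code{gene_id}, \code{study},
#'   \code{rho} (long format; every gene must appear in every study).
#' @param regulatedGenes character vector of genes regulated in the paired
#'   model.
#' @param minCC absolute mean correlation required for core membership
#'   (default 0.2).
#' @param aggregate \code{"mean"} (default) or \code{"fisher"}: how per-study
#'   coefficients are averaged (Fisher z-transform mean for the latter).
#' @return DataFrame per gene: per-study rho, \code{consistent},
#'   \code{mean_cc}, \code{in_core}.
#' @export
aggregateConsistent <- function(ccTable, regulatedGenes = character(0),
                                minCC = 0.2,
                                aggregate = c("mean", "fisher")) {
    aggregate <- match.arg(aggregate)
    need <- c("gene_id", "study", "rho")
    if (!all(need %in% colnames(ccTable)))
        stop("'ccTable' needs gene_id, study and rho columns")
    studies <- unique(ccTable$study)
    if (length(studies) < 2L) stop("at least 2 studies are required")
    cover <- table(ccTable$gene_id)
    if (any(cover != length(studies)))
        stop("missing study entries for gene(s): ",
             paste(utils::head(names(cover)[cover != length(studies)], 5),
                   collapse = ", "))
    wide <- stats::reshape(as.data.frame(ccTable[, need]), idvar = "gene_id",
                           timevar = "study", direction = "wide")
    rho <- as.matrix(wide[, -1, drop = FALSE])
    sgn <- sign(rho)
    consistent <- unname(apply(sgn, 1L, function(s)
        !anyNA(s) && all(s != 0) && length(unique(s)) == 1L))
    mean_cc <- unname(if (aggregate == "mean") rowMeans(rho) else
        tanh(rowMeans(atanh(pmin(pmax(rho, -0.999999), 0.999999)))))
    in_core <- consistent & !is.na(mean_cc) & abs(mean_cc) >= minCC &
        wide$gene_id %in% regulatedGenes
    rownames(rho) <- NULL
    out <- DataFrame(gene_id = wide$gene_id, rho,
                     consistent = consistent, mean_cc = mean_cc,
                     in_core = in_core, check.names = FALSE)
    out <- out[order(out$gene_id), ]
    rownames(out) <- NULL
    out
}

#' Cross-study growth correlation in one call
#'
#' Computes per-study Spearman correlations of expression change against
#' lean-mass change and aggregates them with [aggregateConsistent()].
#'
#' @param studies list of studies, each with \code{delta} (gene x subject)
#'   and \code{llm}, as produced by [simulateCohorts()].
#' @param regulatedGenes,minCC,aggregate passed to [aggregateConsistent()].
#' @param warnSmall passed to [spearmanCC()].
#' @return the [aggregateConsistent()] table.
#' @export
growthCorrelation <- function(studies, regulatedGenes = character(0),
                              minCC = 0.2, aggregate = "mean",
                              warnSmall = 30L) {
    cc <- do.call(rbind, lapply(names(studies), function(s) {
        x <- spearmanCC(studies[[s]]$delta, studies[[s]]$llm,
                        warnSmall = warnSmall)
        x$study <- s
        x
    }))
    aggregateConsistent(cc, regulatedGenes, minCC = minCC,
                        aggregate = aggregate)
}
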