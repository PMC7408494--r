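#' Fold-change divergence between two regions
#'
#' Measures how different two linear fold changes are, for the rule that a
#' UTR response counts as distinct from the full-length response when the
#' fold changes differ by more than 30 percent. Both fold changes are first
#' oriented to the up scale (values below 1 are inverted, their direction
#' remembered); responses in opposite directions are infinitely divergent.
#' The reference (denominator) is the second argument, by convention the UTR
#' fold change.
#'
#' @param fcA,fcB positive linear fold changes; \code{fcB} is the reference.
#' @param scale \code{"linear"} (default) compares oriented linear fold
#'   changes; \code{"log2"} compares absolute log2 fold changes.
#' @return non-negative divergence (possibly \code{Inf}).
#' @examples
#' fcDivergence(1.2, 2.0)    # 0.4: divergent at the 30 percent rule
#' fcDivergence(1.5, 1/1.5)  # Inf: opposite directions
#' @export
fcDivergence <- function(fcA, fcB, scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    if (fcA <= 0 || fcB <= 0) stop("fold changes must be positive")
    dirA <- sign(log2(fcA))
    dirB <- sign(log2(fcB))
    if (dirA != 0 && dirB != 0 && dirA != dirB) return(Inf)
    a <- max(fcA, 1 / fcA)
    b <- max(fcB, 1 / fcB)
    if (scale == "log2") {
        la <- log2(a); lb <- log2(b)
        if (lb == 0) return(if (la == 0) 0 else Inf)
        return(abs(la - lb) / lb)
    }
    abs(a - b) / b
}

.UTR_CLASSES <- c("concordant", "utr3_selective", "utr5_selective",
                  "fl_selective", "discordant_3v5", "unclassified")

## classify one gene given its three DE records (each: fc, q, called,
## direction); returns the class label
.classifyOne <- function(fl, utr3, utr5, divergence = 0.30,
                         scale = "linear") {
    ## rule 1 gate: at least one of the three comparisons is called
    if (!(fl$called || utr3$called || utr5$called)) return("unclassified")
    ## discordant 3' vs 5': both UTRs called, opposite directions
    if (utr3$called && utr5$called &&
        utr3$direction != utr5$direction) return("discordant_3v5")
    div3 <- if (utr3$called) fcDivergence(fl$fc, utr3$fc, scale) else NA_real_
    div5 <- if (utr5$called) fcDivergence(fl$fc, utr5$fc, scale) else NA_real_
    sel3 <- isTRUE(div3 > divergence)
    sel5 <- isTRUE(div5 > divergence)
    if (sel3 && sel5) return(if (div3 >= div5) "utr3_selective"
                             else "utr5_selective")
    if (sel3) return("utr3_selective")
    if (sel5) return("utr5_selective")
    if (fl$called && !utr3$called && !utr5$called &&
        fcDivergence(fl$fc, utr3$fc, scale) > divergence &&
        fcDivergence(fl$fc, utr5$fc, scale) > divergence)
        return("fl_selective")
    "concordant"
}

#' Classify genes by region-selective regulation
#'
#' Applies the three-rule heuristic for UTR-selective regulation to the
#' region-wise differential expression results. A gene is considered at all
#' only if at least one of its three comparisons (full length, 3' UTR,
#' 5' UTR) is called (rule 1). A called UTR response whose fold change
#' diverges from the full-length fold change by more than the divergence
#' threshold (default 30 percent, on the oriented linear scale, with the UTR
#' as reference) marks the gene as UTR-selective, whether or not the full
#' length is itself called. A called full-length response with no called UTR
#' and divergent fold changes against both UTRs is full-length-selective.
#' Called 3' and 5' UTR responses in opposite directions are discordant.
#' Everything else eligible is concordant.
#'
#' Transcripts are classified individually; the gene-level class is taken
#' from the transcript with the most extreme supporting divergence (here:
#' the first non-concordant transcript, falling back to concordant).
#'
#' @param deList named list of [PairedDEResult-class] objects with elements
#'   \code{FL}, \code{UTR3}, \code{UTR5} (as from [regionDE()]).
#' @param annotation data.frame mapping \code{transcript_id} to
#'   \code{gene_id} (e.g. unique rows of a [buildCDF()] result).
#' @param divergence relative fold-change difference above which responses
#'   count as distinct (default 0.30).
#' @param scale passed to [fcDivergence()].
#' @return DataFrame with one row per gene: class plus the supporting fold
#'   changes and q-values. Genes missing any of the three records are
#'   skipped and listed in the \code{"skipped"} attribute.
#' @export
classifyUTR <- function(deList, annotation, divergence = 0.30,
                        scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    need <- c("FL", "UTR3", "UTR5")
    if (!all(need %in% names(deList)))
        stop("'deList' must contain FL, UTR3 and UTR5 results")
    tab <- lapply(deList[need], function(r) {
        x <- deTable(r)
        x$transcript_id <- sub(":(FL|UTR3|UTR5)$", "", x$probe_set_id)
        x
    })
    tx <- unique(annotation[, c("transcript_id", "gene_id")])
    rows <- vector("list", nrow(tx))
    skipped <- character(0)
    for (k in seq_len(nrow(tx))) {
        id <- tx$transcript_id[k]
        rec <- lapply(tab, function(x) {
            i <- match(id, x$transcript_id)
            if (is.na(i)) return(NULL)
            list(fc = x$fc[i], q = x$q[i], called = x$called[i],
                 direction = x$direction[i])
        })
        if (any(vapply(rec, is.null, logical(1)))) {
            skipped <- c(skipped, id)
            next
        }
        cls <- .classifyOne(rec$FL, rec$UTR3, rec$UTR5, divergence, scale)
        rows[[k]] <- DataFrame(
            gene_id = tx$gene_id[k], transcript_id = id, class = cls,
            fc_fl = rec$FL$fc, fc_utr3 = rec$UTR3$fc, fc_utr5 = rec$UTR5$fc,
            q_fl = rec$FL$q, q_utr3 = rec$UTR3$q, q_utr5 = rec$UTR5$q)
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) out <- DataFrame(gene_id = character(0))
    ## gene-level reduction: most informative transcript (selective and
    ## discordant classes dominate concordant, which dominates unclassified)
    prio <- c(discordant_3v5 = 5, utr3_selective = 4, utr5_selective = 4,
              fl_selective = 3, concordant = 2, unclassified = 1)
    if (nrow(out) > 0) {
        ord <- order(out$gene_id, -prio[out$class])
        out <- out[ord, ]
        out <- out[!duplicated(out$gene_id), ]
    }
    attr(out, "skipped") <- skipped
    out
}
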