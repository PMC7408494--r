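#' @include AllClasses.R
NULL

#' Accessors for utrflux result objects
#'
#' \code{deTable} returns the per-probe-set results of a paired SAM analysis;
#' \code{calledSets} the probe-set ids passing the FDR and fold-change gate;
#' \code{s0} the exchangeability factor. \code{networkEdges},
#' \code{networkModules}, \code{moduleSignificance} and \code{hubGenes}
#' expose the components of a \linkS4class{CoexpressionNetwork}.
#'
#' @param object a \linkS4class{PairedDEResult} or
#'   \linkS4class{CoexpressionNetwork}.
#' @param significantOnly for \code{networkModules}, return only modules whose
#'   permutation p passes the significance gate.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases deTable calledSets s0 networkEdges networkModules
#'   moduleSignificance hubGenes
NULL

#' @rdname accessors
#' @export
setGeneric("deTable", function(object) standardGeneric("deTable"))

#' @rdname accessors
#' @export
setGeneric("calledSets", function(object) standardGeneric("calledSets"))

#' @rdname accessors
#' @export
setGeneric("s0", function(object) standardGeneric("s0"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkModules",
    function(object, significantOnly = FALSE) standardGeneric("networkModules"))

#' @rdname accessors
#' @export
setGeneric("moduleSignificance",
    function(object) standardGeneric("moduleSignificance"))

#' @rdname accessors
#' @export
setGeneric("hubGenes", function(object) standardGeneric("hubGenes"))

#' @rdname accessors
#' @export
setMethod("deTable", "PairedDEResult", function(object) object@results)

#' @rdname accessors
#' @export
setMethod("calledSets", "PairedDEResult", function(object)
    object@results$probe_set_id[object@results$called])

#' @rdname accessors
#' @export
setMethod("s0", "PairedDEResult", function(object) object@s0)

#' @rdname accessors
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("networkModules", "CoexpressionNetwork",
    function(object, significantOnly = FALSE) {
        if (significantOnly) object@modules[object@moduleKeep] else object@modules
    })

#' @rdname accessors
#' @export
setMethod("moduleSignificance", "CoexpressionNetwork",
    function(object) object@moduleP)

#' @rdname accessors
#' @export
setMethod("hubGenes", "CoexpressionNetwork", function(object) object@hubs)

#' @noRd
#' @export
setMethod("show", "PairedDEResult", function(object) {
    res <- object@results
    cat("PairedDEResult with", nrow(res), "probe sets\n")
    cat("  s0 =", format(object@s0, digits = 4),
        "| permutations =", object@nPerm,
        if (object@enumerated) "(full enumeration)" else "(sampled)", "\n")
    cat("  called at q <", object@fdrCut, "and FC >=", object@fcCut, ":",
        sum(res$called), "(", sum(res$called & res$direction == "up"), "up /",
        sum(res$called & res$direction == "down"), "down )\n")
})

#' @noRd
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
    cat("CoexpressionNetwork:", nrow(object@edges), "edges,",
        length(object@modules), "modules (",
        sum(object@moduleKeep), "significant ),",
        length(object@hubs), "hubs\n")
})

#' @noRd
#' @export
setMethod("show", "BackgroundModel", function(object) {
    cat("BackgroundModel over", length(object@mu), "samples;",
        "detection at mu +", object@k, "sd of lowest",
        format(100 * object@decile), "% of probes\n")
})
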