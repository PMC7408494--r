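#' Null distribution of Spearman rho under independent permutation
#'
#' Draws \code{nPerm} Spearman coefficients between a fixed rank vector and
#' independently permuted ranks of the same length: the exchangeability null
#' for a correlation between two unrelated variables observed on n samples.
#' @noRd
.nullRho <- function(n, nPerm) {
    base <- seq_len(n)
    vapply(seq_len(nPerm), function(b)
        stats::cor(base, sample(base), method = "spearman"), numeric(1))
}

#' Permutation-FDR thresholded co-expression edges
#'
#' All pairwise Spearman correlations between nodes; each pair's permutation
#' p-value is computed against \code{nPerm} sample-permutation draws of the
#' null rho (which depends only on the sample count), and the
#' Benjamini-Hochberg procedure keeps edges at \code{q < fdr}. Constant
#' nodes are excluded before correlation and listed in the
#' \code{"excluded"} attribute.
#'
#' @param x samples x nodes matrix of (change in) expression.
#' @param nPerm number of permutations for the null (default 10000).
#' @param fdr edge FDR threshold (default 0.01).
#' @param seed integer seed.
#' @return data.frame of retained edges (from, to, rho, p, q); attribute
#'   \code{"nullEdgeRate"} estimates the probability that a null pair
#'   passes the gate, attribute \code{"nSamples"} records n.
#' @export
edgeFDR <- function(x, nPerm = 10000L, fdr = 0.01, seed = 1L) {
    if (nrow(x) < 10L) stop("at least 10 samples are required")
    if (ncol(x) < 2L) stop("at least 2 nodes are required")
    if (is.null(colnames(x))) colnames(x) <- sprintf("n%04d", seq_len(ncol(x)))
    const <- apply(x, 2L, stats::sd) == 0
    x <- x[, !const, drop = FALSE]
    if (any(const))
        message("excluding constant node(s): ",
                paste(names(const)[const], collapse = ", "))
    n <- nrow(x)
    rho <- stats::cor(x, method = "spearman")
    pair <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[pair]
    null_abs <- .withSeed(seed, sort(abs(.nullRho(n, nPerm))))
    exceed <- nPerm - findInterval(abs(r) * (1 - 1e-12) - 1e-300, null_abs)
    p <- (1 + exceed) / (nPerm + 1)
    q <- stats::p.adjust(p, method = "BH")
    keep <- q < fdr
    edges <- data.frame(from = colnames(x)[pair[, 1L]],
                        to = colnames(x)[pair[, 2L]],
                        rho = r, p = p, q = q)[keep, , drop = FALSE]
    rownames(edges) <- NULL
    ## effective |rho| threshold -> null pass rate, used for hub significance
    rate <- if (any(keep)) {
        thr <- min(abs(edges$rho))
        (1 + (nPerm - findInterval(thr * (1 - 1e-12) - 1e-300, null_abs))) /
            (nPerm + 1)
    } else 1 / (nPerm + 1)
    structure(edges, nullEdgeRate = rate, nSamples = n,
              excluded = names(const)[const], nNodes = ncol(x))
}

## mean within-module edge weight of the best (heaviest) module found by
## greedy modularity clustering of graph g
.bestModuleWeight <- function(g, minSize = 3L) {
    if (igraph::ecount(g) == 0) return(0)
    cm <- igraph::cluster_fast_greedy(g)
    best <- 0
    for (mod in igraph::groups(cm)) {
        if (length(mod) < minSize) next
        sub <- igraph::induced_subgraph(g, mod)
        if (igraph::ecount(sub) == 0) next
        w <- mean(igraph::E(sub)$weight)
        if (w > best) best <- w
    }
    best
}

#' Detect co-expression modules with permutation significance
#'
#' Builds a graph from the retained edges (edge weight = |rho|), partitions
#' it by greedy modularity optimization, and assigns each module a
#' permutation p-value: the fraction of degree-preserving edge rewirings
#' (with edge weights permuted) whose best-scoring module reaches at least
#' the observed module's mean intra-module |rho|. Modules pass the gate at
#' \code{p < moduleP}.
#'
#' @param edges edge data.frame from [edgeFDR()] (or any from/to/rho table).
#' @param nPerm number of rewired null graphs (default 1000; the permutation
#'   p resolution is 1/(nPerm+1)).
#' @param moduleP module significance threshold (default 0.01).
#' @param minSize smallest module considered (default 3 nodes).
#' @param seed integer seed.
#' @return a [CoexpressionNetwork-class] (without hubs; see
#'   [identifyHubs()]). An empty edge set yields an empty module list.
#' @export
detectModules <- function(edges, nPerm = 1000L, moduleP = 0.01,
                          minSize = 3L, seed = 1L) {
    params <- list(nPerm = nPerm, moduleP = moduleP, minSize = minSize)
    rate <- attr(edges, "nullEdgeRate")
    nsamp <- attr(edges, "nSamples")
    if (is.null(rate)) rate <- NA_real_
    if (is.null(nsamp)) nsamp <- NA_real_
    if (!nrow(edges)) {
        return(new("CoexpressionNetwork",
                   graph = igraph::make_empty_graph(directed = FALSE),
                   edges = edges, modules = list(), moduleP = numeric(0),
                   moduleKeep = logical(0), hubs = character(0),
                   nullEdgeRate = rate, nSamples = nsamp, params = params))
    }
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       directed = FALSE)
    igraph::E(g)$rho <- edges$rho
    igraph::E(g)$weight <- abs(edges$rho)
    cm <- igraph::cluster_fast_greedy(g)
    modules <- igraph::groups(cm)           # 1-d array of member vectors
    modules <- lapply(seq_along(modules),
                      function(i) as.character(modules[[i]]))
    modules <- modules[lengths(modules) >= minSize]
    obs <- vapply(modules, function(mod) {
        sub <- igraph::induced_subgraph(g, mod)
        mean(igraph::E(sub)$weight)
    }, numeric(1))
    pvals <- .withSeed(seed, {
        nullBest <- vapply(seq_len(nPerm), function(b) {
            gr <- igraph::rewire(g, igraph::keeping_degseq(
                niter = 10 * igraph::ecount(g)))
            igraph::E(gr)$weight <- sample(igraph::E(g)$weight)
            .bestModuleWeight(gr, minSize)
        }, numeric(1))
        vapply(obs, function(o) (1 + sum(nullBest >= o)) / (nPerm + 1),
               numeric(1))
    })
    new("CoexpressionNetwork", graph = g, edges = edges, modules = modules,
        moduleP = pvals, moduleKeep = pvals < moduleP, hubs = character(0),
        nullEdgeRate = rate, nSamples = nsamp, params = params)
}

#' Identify hub nodes within modules
#'
#' A node is a hub when its within-module degree strictly exceeds the
#' module's 90th-percentile degree (so fully symmetric modules such as
#' cliques have no hubs) and its degree is improbable under the edge-level
#' permutation null: the connectivity p-value is the binomial tail
#' probability of observing at least that many of its possible edges under
#' the null edge-pass rate estimated by [edgeFDR()].
#'
#' @param net a [CoexpressionNetwork-class] from [detectModules()].
#' @param degreeQuantile within-module degree quantile a hub must exceed
#'   (default 0.9).
#' @param connectivityP connectivity significance threshold (default 0.01).
#' @return the network with its \code{hubs} slot filled; per-module vectors
#'   of node connectivity p-values are recorded in
#'   \code{object@params$connectivity}.
#' @export
identifyHubs <- function(net, degreeQuantile = 0.9, connectivityP = 0.01) {
    if (!length(net@modules)) {
        net@hubs <- character(0)
        return(net)
    }
    g <- net@graph
    rate <- net@nullEdgeRate
    n_possible <- max(igraph::vcount(g) - 1L, 1L)
    hubs <- character(0)
    conn <- list()
    for (mod in net@modules) {
        if (length(mod) < 2L) next
        sub <- igraph::induced_subgraph(g, mod)
        deg <- igraph::degree(sub)
        cut <- stats::quantile(deg, degreeQuantile)
        p_conn <- stats::pbinom(deg - 1L, n_possible, rate,
                                lower.tail = FALSE)
        conn[[length(conn) + 1L]] <- p_conn
        hubs <- c(hubs, names(deg)[deg > cut & p_conn < connectivityP])
    }
    net@hubs <- hubs
    net@params$connectivity <- conn
    net
}

#' Co-expression network analysis in one call
#'
#' Chains [edgeFDR()], [detectModules()] and [identifyHubs()].
#'
#' @param x samples x nodes matrix.
#' @param nPermEdges,edgeQ passed to [edgeFDR()].
#' @param nPermModules,moduleP,minSize passed to [detectModules()].
#' @param seed integer seed.
#' @return a [CoexpressionNetwork-class].
#' @export
coexpressionNetwork <- function(x, nPermEdges = 10000L, edgeQ = 0.01,
                                nPermModules = 1000L, moduleP = 0.01,
                                minSize = 3L, seed = 1L) {
    edges <- edgeFDR(x, nPerm = nPermEdges, fdr = edgeQ, seed = seed)
    net <- detectModules(edges, nPerm = nPermModules, moduleP = moduleP,
                         minSize = minSize, seed = seed + 1L)
    identifyHubs(net)
}
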