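#' Within-subject paired log2 differences
#'
#' For every probe set, the per-subject difference between the loaded and
#' unloaded condition (loaded minus unloaded, so positive values mean higher
#' expression under loading). Every subject must contribute exactly one
#' sample per condition.
#'
#' @param rs a [RegionExperiment-class] (or any SummarizedExperiment with a
#'   \code{log2signal} assay and \code{subject_id}/\code{condition} columns
#'   in \code{colData}).
#' @param conditions length-2 character vector: unloaded (reference) label
#'   first, loaded label second.
#' @return matrix of paired differences, probe sets x subjects.
#' @export
pairedDifferences <- function(rs, conditions = c("unloaded", "loaded")) {
    cd <- colData(rs)
    if (!all(c("subject_id", "condition") %in% colnames(cd)))
        stop("colData needs subject_id and condition columns")
    m <- assay(rs, "log2signal")
    subj <- unique(cd$subject_id)
    i_un <- match(paste(subj, conditions[1L]),
                  paste(cd$subject_id, cd$condition))
    i_lo <- match(paste(subj, conditions[2L]),
                  paste(cd$subject_id, cd$condition))
    bad <- subj[is.na(i_un) | is.na(i_lo)]
    if (length(bad))
        stop("subject(s) missing a condition: ", paste(bad, collapse = ", "))
    delta <- m[, i_lo, drop = FALSE] - m[, i_un, drop = FALSE]
    colnames(delta) <- subj
    delta
}

#' Choose the SAM exchangeability factor s0
#'
#' Selects s0 among the percentiles (0, 5, ..., 100) of the per-probe-set
#' standard errors so that the dispersion of the d statistic (its median
#' absolute deviation) is as uniform as possible across standard-error bins,
#' i.e. the coefficient of variation of the bin-wise MADs is minimized. This
#' decouples the significance of a probe set from its variance level.
#'
#' @param delta paired-difference matrix (probe sets x subjects).
#' @param nBins number of standard-error quantile bins (default 10).
#' @return the chosen s0 (non-negative scalar). Degenerate input with no
#'   variance anywhere returns a small positive floor, with a warning.
#' @export
chooseS0 <- function(delta, nBins = 10L) {
    if (ncol(delta) < 2L) stop("at least 2 subjects are required")
    n <- ncol(delta)
    se <- apply(delta, 1L, stats::sd) / sqrt(n)
    if (all(se < 1e-12)) {
        warning("no variance anywhere; returning floor s0")
        return(1e-6)
    }
    means <- rowMeans(delta)
    cand <- unique(stats::quantile(se, probs = seq(0, 1, by = 0.05)))
    breaks <- unique(stats::quantile(se, probs = seq(0, 1,
                                                     length.out = nBins + 1)))
    bins <- if (length(breaks) < 2L) factor(rep(1L, length(se))) else
        cut(se, breaks, include.lowest = TRUE)
    cv <- vapply(cand, function(a) {
        d <- means / (se + a + 1e-9)
        disp <- tapply(d, bins, stats::mad)
        disp <- disp[is.finite(disp) & disp > 0]
        if (length(disp) < 2L) return(Inf)
        stats::sd(disp) / mean(disp)
    }, numeric(1))
    s0 <- unname(cand[which.min(cv)])
    max(s0, 0)
}

#' Paired SAM d statistic
#'
#' \code{d = mean(delta) / (se(delta) + s0)} per probe set, with
#' \code{se = sd / sqrt(n)} floored at 1e-9 so probe sets with zero variance
#' stay finite.
#'
#' @param delta paired-difference matrix (probe sets x subjects).
#' @param s0 exchangeability factor (>= 0), e.g. from [chooseS0()].
#' @return numeric vector of d statistics.
#' @export
samStatistic <- function(delta, s0 = 0) {
    if (ncol(delta) < 2L) stop("at least 2 subjects are required")
    if (s0 < 0) stop("'s0' must be non-negative")
    n <- ncol(delta)
    se <- pmax(apply(delta, 1L, stats::sd) / sqrt(n), 1e-9)
    rowMeans(delta) / (se + s0)
}

## counts of |values| >= t for each threshold t, given sorted |values|
.exceedances <- function(t, sortedAbs) {
    length(sortedAbs) - findInterval(t * (1 - 1e-12) - 1e-300, sortedAbs)
}

#' Permutation q-values for the paired SAM statistic
#'
#' The null distribution is generated by flipping the sign of each subject's
#' difference column (the exchangeability null of a paired design). When
#' 2^n <= \code{nPerm} all sign patterns are enumerated, making the result
#' exact and independent of the seed; otherwise \code{nPerm} patterns are
#' sampled under the seed. For each threshold t = |d_i| the estimated FDR is
#' the expected number of null exceedances per permutation divided by the
#' observed number of exceedances (the pooled plug-in estimator; a
#' median-across-permutations variant is available), and the q-value of a
#' probe set is the minimum estimated FDR over all thresholds at which it
#' would be called, which makes q non-increasing in |d|.
#'
#' @param delta paired-difference matrix (probe sets x subjects).
#' @param s0 exchangeability factor.
#' @param nPerm number of sign-flip permutations (>= 100).
#' @param seed integer seed (used only when sampling is needed).
#' @param estimator \code{"mean"} (default) or \code{"median"}: how the null
#'   exceedance counts are aggregated across permutations.
#' @return numeric vector of q-values in [0, 1]; attributes \code{"d"} and
#'   \code{"enumerated"} carry the observed statistics and whether full
#'   enumeration was used.
#' @export
permutationFDR <- function(delta, s0 = 0, nPerm = 10000L, seed = 1L,
                           estimator = c("mean", "median")) {
    estimator <- match.arg(estimator)
    if (nPerm < 100L) stop("'nPerm' must be at least 100 for a stable estimate")
    n <- ncol(delta)
    G <- nrow(delta)
    if (n < 2L) stop("at least 2 subjects are required")
    d_obs <- samStatistic(delta, s0)
    t_obs <- abs(d_obs)

    enumerated <- 2^n <= nPerm
    S <- if (enumerated) {
        t(as.matrix(expand.grid(rep(list(c(-1, 1)), n))))
    } else {
        .withSeed(seed,
                  matrix(sample(c(-1, 1), n * nPerm, replace = TRUE), n, nPerm))
    }
    B <- ncol(S)

    ## under column sign flips only the row mean changes; row sums of squares
    ## are invariant, so the whole null ensemble reduces to one matrix product
    M <- (delta %*% S) / n
    rowSq <- rowSums(delta^2)
    V <- (rowSq - n * M^2) / (n - 1)
    V[V < 0] <- 0
    SE <- pmax(sqrt(V / n), 1e-9)
    Dnull <- abs(M / (SE + s0))

    obs_exc <- .exceedances(t_obs, sort(t_obs))
    if (estimator == "mean") {
        null_per_perm <- .exceedances(t_obs, sort(as.vector(Dnull))) / B
    } else {
        cnt <- matrix(0L, G, B)
        for (b in seq_len(B))
            cnt[, b] <- .exceedances(t_obs, sort(Dnull[, b]))
        null_per_perm <- apply(cnt, 1L, stats::median)
    }
    fdr_raw <- pmin(pmax(null_per_perm / pmax(obs_exc, 1L), 0), 1)

    ## q-value: minimum estimated FDR over thresholds at which the probe set
    ## is included in the call set (all t <= |d_i|)
    ord <- order(t_obs)
    q <- numeric(G)
    q[ord] <- cummin(fdr_raw[ord])
    structure(q, d = d_obs, enumerated = enumerated)
}

#' Call differential probe sets at an FDR and fold-change gate
#'
#' A probe set is called when its permutation q-value is below \code{fdr} and
#' its linear fold change (2^mean paired log2 difference) is at least
#' \code{fc} up or at most 1/\code{fc} down.
#'
#' @param probeSetIds character ids, one per row of the analysis.
#' @param meanDelta mean paired log2 differences.
#' @param q permutation q-values.
#' @param d d statistics.
#' @param s0,nPerm,enumerated bookkeeping stored in the result.
#' @param fdr q-value cutoff (default 0.05).
#' @param fc linear fold-change cutoff (default 1.2; must be >= 1).
#' @return a [PairedDEResult-class].
#' @export
callDE <- function(probeSetIds, meanDelta, q, d, s0 = 0, nPerm = 0,
                   enumerated = FALSE, fdr = 0.05, fc = 1.2) {
    if (fc < 1) stop("'fc' must be >= 1")
    fold <- 2^meanDelta
    called <- q < fdr & (fold >= fc | fold <= 1 / fc)
    direction <- ifelse(!called, "none", ifelse(meanDelta > 0, "up", "down"))
    res <- DataFrame(probe_set_id = probeSetIds, mean_delta = meanDelta,
                     fc = fold, d = d, q = q, called = called,
                     direction = direction)
    new("PairedDEResult", results = res, s0 = s0, nPerm = nPerm,
        enumerated = enumerated, fdrCut = fdr, fcCut = fc)
}

#' Paired SAM analysis of one difference matrix
#'
#' Convenience wrapper: chooses s0, computes d statistics, sign-flip
#' permutation q-values and the FDR/fold-change call.
#'
#' @param delta paired-difference matrix (probe sets x subjects) with row
#'   names.
#' @param nPerm,seed,estimator passed to [permutationFDR()].
#' @param fdr,fc passed to [callDE()].
#' @param s0 optional fixed s0; chosen by [chooseS0()] when \code{NULL}.
#' @return a [PairedDEResult-class].
#' @examples
#' delta <- matrix(rnorm(50 * 6), 50, 6,
#'                 dimnames = list(paste0("ps", 1:50), NULL))
#' res <- pairedSAM(delta, nPerm = 100)
#' res
#' @export
pairedSAM <- function(delta, nPerm = 10000L, seed = 1L, fdr = 0.05, fc = 1.2,
                      s0 = NULL, estimator = c("mean", "median")) {
    if (is.null(rownames(delta)))
        rownames(delta) <- sprintf("ps%05d", seq_len(nrow(delta)))
    if (is.null(s0)) s0 <- chooseS0(delta)
    q <- permutationFDR(delta, s0, nPerm = nPerm, seed = seed,
                        estimator = match.arg(estimator))
    callDE(rownames(delta), rowMeans(delta), as.numeric(q), attr(q, "d"),
           s0 = s0, nPerm = nPerm, enumerated = attr(q, "enumerated"),
           fdr = fdr, fc = fc)
}

#' Region-wise paired SAM
#'
#' Splits a [RegionExperiment-class] by region tag (FL, UTR3, UTR5), forms
#' paired differences and runs [pairedSAM()] on each region separately.
#'
#' @param rs a [RegionExperiment-class].
#' @param conditions passed to [pairedDifferences()].
#' @param ... passed to [pairedSAM()].
#' @return named list of [PairedDEResult-class] objects (FL, UTR3, UTR5).
#' @export
regionDE <- function(rs, conditions = c("unloaded", "loaded"), ...) {
    delta <- pairedDifferences(rs, conditions)
    region <- rowData(rs)$region
    out <- lapply(c(FL = "FL", UTR3 = "UTR3", UTR5 = "UTR5"), function(tag) {
        i <- region == tag
        if (!any(i)) return(NULL)
        pairedSAM(delta[i, , drop = FALSE], ...)
    })
    out[!vapply(out, is.null, logical(1))]
}
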