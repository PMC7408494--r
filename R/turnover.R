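#' Estimate one-repetition maximum from a submaximal set
#'
#' \code{1RM = load / (1.0278 - 0.0278 * reps)}: the standard repetitions-to-
#' failure prediction equation. The denominator reaches zero just below 37
#' repetitions, so rep counts of 37 or more are rejected.
#'
#' @param load weight lifted, kg (> 0).
#' @param reps repetitions completed to failure (1 to 36).
#' @return estimated one-repetition maximum, kg.
#' @examples
#' estimateOneRM(100, 1)   # 100: one rep is the 1RM itself
#' estimateOneRM(100, 10)  # 133.37
#' @export
estimateOneRM <- function(load, reps) {
    if (any(load <= 0)) stop("'load' must be positive")
    if (any(reps < 1) || any(reps != as.integer(reps)))
        stop("'reps' must be a positive whole number")
    if (any(reps >= 37)) stop("'reps' must be below 37 (denominator <= 0)")
    load / (1.0278 - 0.0278 * reps)
}

## absolute 2H/1H ratio of the VSMOW standard
.AR_VSMOW <- 0.00015595

#' Convert saliva delta-2H (per mil) to atom percent
#'
#' \code{AP = 100 * AR * (delta/1000 + 1) / (1 + AR * (delta/1000 + 1))}
#' with AR the absolute deuterium/protium ratio of the VSMOW standard
#' (0.00015595). Strictly increasing in delta; delta at or below -1000 per
#' mil would imply a non-positive isotope ratio and is rejected.
#'
#' @param delta2H per-mil delta values (> -1000).
#' @return atom percent (numeric, same length).
#' @examples
#' deltaToAtomPercent(0)  # natural abundance, about 0.0155926
#' @export
deltaToAtomPercent <- function(delta2H) {
    if (any(delta2H <= -1000)) stop("'delta2H' must exceed -1000 per mil")
    r <- .AR_VSMOW * (delta2H * 0.001 + 1)
    100 * r / (1 + r)
}

#' Atom percent excess of an enrichment series
#'
#' Subtracts the background enrichment (the t = 0 sample) from each
#' timepoint and multiplies by the sample dilution factor (35 by default,
#' matching the dilution applied before isotope-ratio measurement).
#'
#' @param time sampling times (the baseline must be at \code{time == 0}).
#' @param delta2H per-mil enrichment at each time.
#' @param dilution dilution correction factor (default 35; 1 disables it).
#' @return data.frame with time and APE (atom percent excess); APE at the
#'   baseline is exactly 0.
#' @export
apeExcess <- function(time, delta2H, dilution = 35) {
    if (length(time) != length(delta2H))
        stop("'time' and 'delta2H' must have equal length")
    i0 <- which(time == 0)
    if (length(i0) != 1L) stop("exactly one baseline sample at time 0 is required")
    ap <- deltaToAtomPercent(delta2H)
    data.frame(time = time, ape = (ap - ap[i0]) * dilution)
}

#' Integrated myofibrillar protein synthesis rate
#'
#' The precursor-product relation:
#' \code{iMyoPS = dAPE_Ala / (APE_BW * 3.7 * t) * 100} in percent per day,
#' where \code{dAPE_Ala} is the change in protein-bound alanine enrichment
#' between biopsies, \code{APE_BW} the body-water enrichment, 3.7 the
#' correction for the number of labeled carbon-hydrogen bonds in alanine
#' relative to body water, and \code{t} the incorporation time in days.
#'
#' @param deltaAPEAla change in protein-bound alanine APE.
#' @param apeBW body-water APE (> 0).
#' @param t incorporation time in days (> 0).
#' @param bondFactor carbon-hydrogen bond correction (default 3.7).
#' @return synthesis rate, percent per day.
#' @examples
#' iMyoPS(0.037, 0.5, 2)  # 1 percent per day
#' @export
iMyoPS <- function(deltaAPEAla, apeBW, t, bondFactor = 3.7) {
    if (any(apeBW <= 0)) stop("'apeBW' must be positive")
    if (any(t <= 0)) stop("'t' must be positive")
    deltaAPEAla / (apeBW * bondFactor * t) * 100
}

#' Coefficients of variation for paired loading responses
#'
#' Per-subject percent changes for the trained (RT) and immobilized (UL) leg
#' are combined into the within-subject differential (RT minus UL), and the
#' coefficient of variation \code{100 * sd / |mean|} is reported for all
#' three response columns. Because the differential cancels shared
#' between-subject responsiveness, its CoV is expected to be markedly lower
#' than either leg's.
#'
#' @param rt,ul equal-length numeric vectors of percent changes (n >= 2).
#' @return named numeric vector: CoV of RT, UL and the differential
#'   (percent). A zero mean makes the corresponding CoV \code{NaN}, with a
#'   warning.
#' @examples
#' covTriplet(c(10, 20), c(-5, -10))
#' @export
covTriplet <- function(rt, ul) {
    if (length(rt) != length(ul)) stop("'rt' and 'ul' must have equal length")
    if (length(rt) < 2L) stop("at least 2 subjects are required")
    hypat <- rt - ul
    cov1 <- function(x) {
        if (mean(x) == 0) {
            warning("zero mean: CoV undefined")
            return(NaN)
        }
        100 * stats::sd(x) / abs(mean(x))
    }
    c(rt = cov1(rt), ul = cov1(ul), hypat = cov1(hypat))
}

#' Recover the synthesis rate from a simulated enrichment course
#'
#' Convenience inversion used in validation: converts the saliva series to
#' APE, takes the maintenance-phase mean as the body-water precursor
#' enrichment, and applies [iMyoPS()] to the protein-bound alanine change
#' over a biopsy interval.
#'
#' @param enrichment output of [simulateEnrichment()].
#' @param interval length-2 vector of biopsy days (must be present in the
#'   simulated biopsy schedule).
#' @return estimated synthesis rate, percent per day.
#' @export
recoverSynthesisRate <- function(enrichment, interval = NULL) {
    prot <- enrichment$protein
    if (is.null(interval)) interval <- range(prot$day)
    i <- match(interval, prot$day)
    if (anyNA(i)) stop("'interval' days must be biopsy days")
    ape <- apeExcess(enrichment$saliva$day, enrichment$saliva$delta2H,
                     dilution = enrichment$dilution)
    maint <- ape$ape[ape$time >= interval[1] & ape$time <= interval[2] &
                     ape$time > 0]
    iMyoPS(prot$ape_ala[i[2]] - prot$ape_ala[i[1]], mean(maint),
           diff(interval))
}
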