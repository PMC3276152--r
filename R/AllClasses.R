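#' @import methods
#' @importFrom S4Vectors metadata DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges assay
#'   assayNames colData
NULL

.FEATURE_CATEGORIES <- c("checked_origin", "unchecked_origin", "centromere",
                         "cut_site", "other")
.SITE_RULES <- c("above_median", "local_peak", "manual")

#' Categorized point features on a genome
#'
#' A \code{FeatureSet} holds point features (replication origins, centromeres,
#' restriction/endonuclease cut sites, ...) as genomic intervals reduced to
#' real-valued midpoints on the BED (0-based, half-open) coordinate scale.
#' Every distance computation in the package is midpoint-to-midpoint, so
#' features are collapsed to points immediately on construction; the original
#' interval is retained only so that BED round-trips are exact.
#'
#' @slot features A \code{GRanges} with metadata columns \code{midpoint}
#'   (numeric, 0-based), \code{category} (one of \code{checked_origin},
#'   \code{unchecked_origin}, \code{centromere}, \code{cut_site},
#'   \code{other}) and \code{name}.
#' @export
setClass("FeatureSet", slots = c(features = "GRanges"))

setValidity("FeatureSet", function(object) {
  gr <- object@features
  mc <- mcols(gr)
  need <- c("midpoint", "category", "name")
  if (!all(need %in% colnames(mc)))
    return(paste("features must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (!all(mc$category %in% .FEATURE_CATEGORIES))
    return(paste("category must be one of:",
                 paste(.FEATURE_CATEGORIES, collapse = ", ")))
  sl <- seqlengths(gr)
  if (any(is.na(sl)))
    return("all feature chromosomes must have known lengths (use a layout)")
  lim <- sl[as.character(seqnames(gr))]
  if (length(gr) && (any(mc$midpoint < 0) || any(mc$midpoint > lim)))
    return("feature midpoints must lie within [0, chromosome length]")
  TRUE
})

#' Two-channel array measurements over a probe universe
#'
#' An \code{ArraySample} is a \code{RangedSummarizedExperiment} with one row
#' per probe and two columns, \code{exp} (experimental channel) and \code{ctl}
#' (control channel), carrying \code{signal} and \code{background}
#' fluorescence assays. Row ranges are the probes with \code{id} and
#' \code{flagged} (QC-anomalous spot) metadata columns. For unflagged probes
#' signal is at least background; flagged probes may violate this and are
#' removed before any ratio is formed.
#'
#' @export
setClass("ArraySample", contains = "RangedSummarizedExperiment")

setValidity("ArraySample", function(object) {
  if (!all(c("signal", "background") %in% assayNames(object)))
    return("assays 'signal' and 'background' are required")
  if (!identical(colnames(object), c("exp", "ctl")))
    return("columns must be exactly c('exp', 'ctl')")
  mc <- mcols(rowRanges(object))
  if (!all(c("id", "flagged") %in% colnames(mc)))
    return("probes must carry 'id' and 'flagged' metadata columns")
  if (anyDuplicated(mc$id))
    return("probe ids must be unique")
  sig <- assay(object, "signal")
  bg <- assay(object, "background")
  if (any(bg < 0) || any(is.na(sig)))
    return("background must be non-negative and signal non-missing")
  ok <- !mc$flagged
  if (any(sig[ok, ] < bg[ok, ]))
    return("signal must be >= background for unflagged probes")
  TRUE
})

#' Normalized ratio profile along the genome
#'
#' A \code{RatioProfile} is a \code{RangedSummarizedExperiment} with one row
#' per retained (unflagged, positive-control-signal) probe and a single
#' column. The \code{raw} assay holds the per-probe ratio of
#' background-subtracted, total-signal-normalized experimental to control
#' signal; the \code{smoothed} assay, present after \code{\link{lowessSmooth}},
#' holds the locally weighted regression fit at the same probe coordinates.
#' \code{metadata()} records the normalization totals, the counts of dropped
#' probes, and the smoothing window width in bp.
#'
#' @export
setClass("RatioProfile", contains = "RangedSummarizedExperiment")

setValidity("RatioProfile", function(object) {
  if (!"raw" %in% assayNames(object))
    return("assay 'raw' is required")
  if (ncol(object) != 1L)
    return("a RatioProfile holds a single sample column")
  mc <- mcols(rowRanges(object))
  if (!all(c("id", "midpoint") %in% colnames(mc)))
    return("probes must carry 'id' and 'midpoint' metadata columns")
  if (any(assay(object, "raw") < 0))
    return("raw ratios must be non-negative")
  if ("smoothed" %in% assayNames(object)) {
    w <- metadata(object)$windowBp
    if (is.null(w) || !is.numeric(w) || w <= 0)
      return("smoothed profiles must record a positive windowBp")
  }
  TRUE
})

#' Called breakage/ssDNA sites
#'
#' A \code{SiteSet} records the probe-resolution positions whose smoothed
#' ratio satisfies a calling rule: \code{above_median} (strictly greater than
#' the genome-wide median of the smoothed profile), \code{local_peak}
#' (prominence-filtered local maxima), or \code{manual} (externally supplied,
#' e.g. loaded from a BED file or drawn for a null calibration).
#'
#' @slot sites A \code{GRanges} sorted by (chromosome, position) with
#'   metadata columns \code{midpoint} (numeric, 0-based) and \code{score}
#'   (the smoothed ratio, \code{NA} for manual sets without one).
#' @slot threshold Numeric threshold the rule was applied against
#'   (\code{NA} for manual sets).
#' @slot rule Character; one of \code{above_median}, \code{local_peak},
#'   \code{manual}.
#' @slot profileId Character id of the source profile.
#' @export
setClass("SiteSet", slots = c(sites = "GRanges", threshold = "numeric",
                              rule = "character", profileId = "character"))

setValidity("SiteSet", function(object) {
  gr <- object@sites
  mc <- mcols(gr)
  if (!all(c("midpoint", "score") %in% colnames(mc)))
    return("sites must carry 'midpoint' and 'score' metadata columns")
  if (!object@rule %in% .SITE_RULES)
    return(paste("rule must be one of:", paste(.SITE_RULES, collapse = ", ")))
  key <- paste(as.character(seqnames(gr)), mc$midpoint)
  if (anyDuplicated(key))
    return("duplicate site coordinates are not allowed")
  ord <- order(as.integer(seqnames(gr)), mc$midpoint)
  if (!identical(ord, seq_along(gr)))
    return("sites must be sorted by (chromosome, midpoint)")
  if (object@rule == "above_median" && length(gr) &&
      !all(mc$score > object@threshold))
    return("above_median sites must all exceed the recorded threshold")
  TRUE
})

#' Planted truth for the synthetic array simulator
#'
#' Describes the enrichment structure a simulated experimental channel
#' carries on top of a flat control: a baseline experimental/control ratio
#' plus localized peaks. Gaussian peaks contribute
#' \code{amplitude * exp(-(x - center)^2 / (2 * width^2))} to the fold
#' enrichment at coordinate \code{x}; \code{point} peaks add their amplitude
#' to the single probe whose interval covers the center (an idealized
#' restriction/endonuclease cut end-label).
#'
#' @slot peaks A \code{data.frame} with columns \code{chrom}, \code{center}
#'   (bp), \code{amplitude} (fold enrichment, >= 0), \code{width} (bp, > 0
#'   for gaussian peaks) and \code{shape} ("gaussian" or "point").
#' @slot baselineRatio Positive baseline experimental/control ratio.
#' @export
setClass("SyntheticTruth",
         slots = c(peaks = "data.frame", baselineRatio = "numeric"))

setValidity("SyntheticTruth", function(object) {
  pk <- object@peaks
  need <- c("chrom", "center", "amplitude", "width", "shape")
  if (!all(need %in% colnames(pk)))
    return(paste("peaks needs columns:", paste(need, collapse = ", ")))
  if (!all(pk$shape %in% c("gaussian", "point")))
    return("peak shape must be 'gaussian' or 'point'")
  if (any(pk$amplitude < 0))
    return("peak amplitudes must be non-negative")
  if (any(pk$shape == "gaussian" & pk$width <= 0))
    return("gaussian peaks need width > 0")
  if (length(object@baselineRatio) != 1L || object@baselineRatio <= 0)
    return("baselineRatio must be a single positive number")
  TRUE
})

#' Result of the break-site/feature randomization test
#'
#' Records the observed number of sites with a feature within the cutoff,
#' the Monte Carlo null distribution of that count obtained by redrawing an
#' equal number of positions from the unflagged probe universe, and the
#' upper-tail p-value \code{p_upper = #(null >= observed) / n_sims}.
#'
#' @export
setClass("AssociationResult",
         slots = c(observedCount = "integer", nSites = "integer",
                   nFeatures = "integer", cutoffBp = "numeric",
                   nSims = "integer", nullCounts = "integer",
                   pUpper = "numeric", seed = "integer"))

setValidity("AssociationResult", function(object) {
  if (object@observedCount < 0L || object@observedCount > object@nSites)
    return("observedCount must lie in [0, nSites]")
  if (length(object@nullCounts) != object@nSims)
    return("nullCounts must have length nSims")
  pExp <- sum(object@nullCounts >= object@observedCount) / object@nSims
  if (!isTRUE(all.equal(pExp, object@pUpper, tolerance = 1e-12)))
    return("pUpper must equal #(null >= observed) / nSims exactly")
  TRUE
})

#' Two-sample proportion test result
#'
#' Pearson chi-square on the 2x2 table with Yates continuity correction
#' (two-sided, 1 df), as used to compare the fraction of break sites near
#' checked vs unchecked replication origins.
#'
#' @export
setClass("ProportionTestResult",
         slots = c(x1 = "integer", n1 = "integer", x2 = "integer",
                   n2 = "integer", p1Hat = "numeric", p2Hat = "numeric",
                   statistic = "numeric", pValue = "numeric"))
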