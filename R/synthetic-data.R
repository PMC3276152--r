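#' Tile a genome with an evenly spaced probe grid
#'
#' Emulates the probe density of a 4x44K-style yeast tiling array: probes of
#' \code{probeLength} bp placed every \code{spacing} bp along each
#' chromosome, with a random subset marked as QC-flagged spots.
#'
#' @param layout A \code{Seqinfo} coordinate universe.
#' @param spacing Center-to-center probe spacing in bp.
#' @param probeLength Probe length in bp (\code{0 < probeLength <= spacing}).
#' @param flagFraction Expected fraction of probes flagged as anomalous.
#' @param seed Integer seed (required when \code{flagFraction > 0}).
#' @return A \code{GRanges} of probes with \code{id} and \code{flagged}
#'   metadata columns.
#' @examples
#' layout <- GenomeInfoDb::Seqinfo(c("chrA"), 10000)
#' makeProbeGrid(layout, spacing = 1000, probeLength = 60)
#' @export
makeProbeGrid <- function(layout, spacing = 290, probeLength = 60,
                          flagFraction = 0, seed = NULL) {
  stopifnot(spacing > 0, probeLength > 0, probeLength <= spacing,
            flagFraction >= 0, flagFraction < 1)
  sl <- seqlengths(layout)
  if (spacing > min(sl))
    stop("spacing (", spacing, ") exceeds the smallest chromosome (",
         min(sl), ")")
  nPer <- floor(sl / spacing)
  chrom <- rep(seqnames(layout), nPer)
  offs <- unlist(lapply(nPer, function(n) seq_len(n) - 1), use.names = FALSE)
  start0 <- offs * spacing
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = start0 + probeLength),
                seqinfo = layout)
  mcols(gr)$id <- sprintf("p_%s_%06d", chrom, offs + 1)
  flagged <- rep(FALSE, length(gr))
  if (flagFraction > 0) {
    if (is.null(seed))
      stop("a seed is required when flagFraction > 0")
    flagged <- withSeed(seed, stats::runif(length(gr)) < flagFraction)
  }
  mcols(gr)$flagged <- flagged
  gr
}

#' Construct a SyntheticTruth
#'
#' @param peaks \code{data.frame} with columns \code{chrom}, \code{center},
#'   \code{amplitude}, \code{width}, \code{shape}; may have zero rows for a
#'   flat (null) truth.
#' @param baselineRatio Baseline experimental/control fold ratio.
#' @return A \code{\link{SyntheticTruth}}.
#' @export
SyntheticTruth <- function(peaks = NULL, baselineRatio = 1) {
  if (is.null(peaks))
    peaks <- data.frame(chrom = character(), center = numeric(),
                        amplitude = numeric(), width = numeric(),
                        shape = character())
  if (is.null(peaks$shape)) peaks$shape <- "gaussian"
  if (is.null(peaks$width)) peaks$width <- 1
  new("SyntheticTruth", peaks = peaks, baselineRatio = baselineRatio)
}

# Expected fold enrichment (1 + sum of peak contributions) at each probe.
# Gaussian peaks act on the probe midpoint; point peaks load the probes whose
# interval covers the center.
.enrichmentAt <- function(probes, truth) {
  x <- probeMidpoints(probes)
  chrom <- .chromOf(probes)
  enr <- rep(1, length(probes))
  pk <- truth@peaks
  for (i in seq_len(nrow(pk))) {
    on <- chrom == pk$chrom[i]
    if (pk$shape[i] == "gaussian") {
      enr[on] <- enr[on] + pk$amplitude[i] *
        exp(-(x[on] - pk$center[i])^2 / (2 * pk$width[i]^2))
    } else {
      hit <- on & GenomicRanges::start(probes) - 1 <= pk$center[i] &
        GenomicRanges::end(probes) > pk$center[i]
      enr[hit] <- enr[hit] + pk$amplitude[i]
    }
  }
  enr
}

#' Simulate a two-channel array hybridization
#'
#' The control channel has constant expectation; the experimental channel
#' expectation is \code{baselineRatio * (1 + sum of peak contributions)} at
#' each probe midpoint. Both channels are multiplied by independent
#' log-normal noise with coefficient of variation \code{noiseCv} (mean 1),
#' and a constant background is added to both and reported in the background
#' columns, so background subtraction recovers the noisy foreground exactly.
#' Flagged probes receive anomalous (sub-background) intensities, emulating
#' spots a feature-extraction QC would flag.
#'
#' @param probes Probe \code{GRanges} from \code{\link{makeProbeGrid}}.
#' @param truth A \code{\link{SyntheticTruth}}.
#' @param noiseCv Coefficient of variation of the multiplicative channel
#'   noise (0 disables noise).
#' @param backgroundLevel Constant background fluorescence added to both
#'   channels.
#' @param seed Integer seed.
#' @param baseSignal Control-channel foreground expectation (fluorescence
#'   units); sets the overall scale only.
#' @return An \code{\link{ArraySample}}.
#' @export
simulateSample <- function(probes, truth, noiseCv = 0.1,
                           backgroundLevel = 100, seed, baseSignal = 1000) {
  stopifnot(is(truth, "SyntheticTruth"), noiseCv >= 0, backgroundLevel >= 0)
  n <- length(probes)
  enr <- .enrichmentAt(probes, truth)
  muExp <- baseSignal * truth@baselineRatio * enr
  muCtl <- rep(baseSignal, n)
  draw <- function() {
    if (noiseCv == 0) return(rep(1, n))
    s <- sqrt(log(1 + noiseCv^2))
    exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
  }
  withSeed(seed, {
    fgExp <- muExp * draw()
    fgCtl <- muCtl * draw()
    flagged <- mcols(probes)$flagged
    if (any(flagged)) {
      # anomalous spots: intensities below background
      fgExp[flagged] <- -backgroundLevel * stats::runif(sum(flagged))
      fgCtl[flagged] <- -backgroundLevel * stats::runif(sum(flagged))
    }
    signal <- cbind(exp = fgExp + backgroundLevel,
                    ctl = fgCtl + backgroundLevel)
    background <- cbind(exp = rep(backgroundLevel, n),
                        ctl = rep(backgroundLevel, n))
    se <- SummarizedExperiment(
      assays = list(signal = signal, background = background),
      rowRanges = probes,
      colData = S4Vectors::DataFrame(channel = c("exp", "ctl"),
                                     row.names = c("exp", "ctl")))
    new("ArraySample", se)
  })
}

#' Simulate an end-labeled cut-site control sample
#'
#' Positive-control fixture emulating a restriction-digest or endonuclease
#' end-labeling experiment: gaussian enrichment of fixed amplitude and width
#' centered on each cut-site midpoint, over a flat baseline.
#'
#' @param probes Probe \code{GRanges}.
#' @param sites A \code{\link{FeatureSet}} of category \code{cut_site}.
#' @param amplitude Fold enrichment at each cut site.
#' @param width Gaussian width (bp) of the end-label signal.
#' @inheritParams simulateSample
#' @return An \code{\link{ArraySample}}.
#' @export
simulateCutSites <- function(probes, sites, amplitude = 8, width = 1000,
                             noiseCv = 0.1, seed, backgroundLevel = 100,
                             baseSignal = 1000) {
  stopifnot(is(sites, "FeatureSet"))
  if (length(sites) && !all(featureCategories(sites) == "cut_site"))
    stop("all features must have category 'cut_site'")
  pk <- data.frame(chrom = .chromOf(granges(sites)),
                   center = featureMidpoints(sites),
                   amplitude = amplitude, width = width, shape = "gaussian")
  truth <- SyntheticTruth(peaks = pk, baselineRatio = 1)
  simulateSample(probes, truth, noiseCv = noiseCv,
                 backgroundLevel = backgroundLevel, seed = seed,
                 baseSignal = baseSignal)
}

#' @rdname ArraySample-class
#' @export
setMethod("probes", "ArraySample", function(x) rowRanges(x))

#' Channel accessors
#'
#' @param x An \code{\link{ArraySample}}.
#' @return Numeric vector over probes.
#' @name channel-accessors
NULL

#' @rdname channel-accessors
#' @export
expSignal <- function(x) assay(x, "signal")[, "exp"]
#' @rdname channel-accessors
#' @export
ctlSignal <- function(x) assay(x, "signal")[, "ctl"]
#' @rdname channel-accessors
#' @export
expBackground <- function(x) assay(x, "background")[, "exp"]
#' @rdname channel-accessors
#' @export
ctlBackground <- function(x) assay(x, "background")[, "ctl"]
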