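#' Compute per-probe normalized ratios from a two-channel sample
#'
#' QC-flagged spots are removed first. For each remaining probe the
#' background-subtracted net signal is formed in each channel; each channel
#' is then normalized to its genome-wide total so both normalized channels
#' sum to 1, and the raw ratio is the normalized experimental over the
#' normalized control value. Probes whose net control signal is not positive
#' cannot carry a ratio and are dropped with a message (their count is
#' recorded in the profile metadata); they are never imputed.
#'
#' @param sample An \code{\link{ArraySample}}.
#' @param profileId Identifier recorded with the profile (defaults to
#'   \code{"sample"}).
#' @return A \code{\link{RatioProfile}} with the \code{raw} assay filled.
#' @export
computeRatios <- function(sample, profileId = "sample") {
  stopifnot(is(sample, "ArraySample"))
  pr <- probes(sample)
  flagged <- mcols(pr)$flagged
  keep <- !flagged
  netExp <- (expSignal(sample) - expBackground(sample))[keep]
  netCtl <- (ctlSignal(sample) - ctlBackground(sample))[keep]
  pr <- pr[keep]
  pos <- netCtl > 0
  nDropped <- sum(!pos)
  if (nDropped > 0)
    message(nDropped, " probe(s) dropped for non-positive control signal")
  if (!any(pos))
    stop("no probes with positive control signal remain")
  netExp <- netExp[pos]
  netCtl <- netCtl[pos]
  pr <- pr[pos]
  expTotal <- sum(netExp)
  ctlTotal <- sum(netCtl)
  normExp <- netExp / expTotal
  normCtl <- netCtl / ctlTotal
  raw <- normExp / normCtl
  gr <- granges(pr)
  mcols(gr)$id <- mcols(pr)$id
  mcols(gr)$midpoint <- probeMidpoints(pr)
  se <- SummarizedExperiment(
    assays = list(raw = matrix(raw, ncol = 1,
                               dimnames = list(NULL, profileId))),
    rowRanges = gr)
  prof <- new("RatioProfile", se)
  prof <- sortProfile(prof)
  S4Vectors::metadata(prof) <- list(
    profileId = profileId,
    normalization = list(expTotal = expTotal, ctlTotal = ctlTotal,
                         normExpSum = sum(normExp), normCtlSum = sum(normCtl)),
    droppedFlagged = sum(flagged),
    droppedNonPositiveControl = nDropped)
  prof
}

# Sort a profile by (chromosome, midpoint); all smoothing and site calling
# assume this order.
sortProfile <- function(profile) {
  gr <- rowRanges(profile)
  ord <- order(as.integer(seqnames(gr)), mcols(gr)$midpoint)
  profile[ord, ]
}

# Local linear fit at each x with tricube weights over a fixed genomic
# half-window h; x sorted ascending. Closed-form weighted least squares.
.lowessFixedWindow <- function(x, y, h) {
  n <- length(x)
  out <- numeric(n)
  lo <- findInterval(x - h, x) + 1L        # first index with x >= x_i - h
  hi <- findInterval(x + h, x)             # last index with x <= x_i + h
  for (i in seq_len(n)) {
    idx <- lo[i]:hi[i]
    if (length(idx) == 1L) {
      out[i] <- y[i]
      next
    }
    d <- abs(x[idx] - x[i]) / h
    w <- (1 - pmin(d, 1)^3)^3
    sw <- sum(w)
    xb <- sum(w * x[idx]) / sw
    yb <- sum(w * y[idx]) / sw
    dx <- x[idx] - xb
    sxx <- sum(w * dx * dx)
    if (sxx <= .Machine$double.eps * sw * max(1, xb^2)) {
      out[i] <- yb
    } else {
      b <- sum(w * dx * (y[idx] - yb)) / sxx
      out[i] <- yb + b * (x[i] - xb)
    }
  }
  out
}

#' Smooth a ratio profile with a fixed genomic window Lowess
#'
#' Each probe's smoothed value is a locally weighted linear regression
#' (degree 1, tricube weights on genomic distance, no robustness
#' iterations) over the probes within \code{windowBp / 2} bp of its
#' midpoint on the same chromosome. Smoothing never crosses chromosome
#' boundaries. The window is a fixed genomic span — not a fraction of the
#' probe count — so the bandwidth matches the proximity cutoff used by the
#' association test.
#'
#' @param profile A \code{\link{RatioProfile}} with the \code{raw} assay.
#' @param windowBp Total window span in bp (default 6000, i.e. +/- 3 kb).
#' @return The profile with the \code{smoothed} assay filled and
#'   \code{windowBp} recorded in its metadata.
#' @export
lowessSmooth <- function(profile, windowBp = 6000) {
  stopifnot(is(profile, "RatioProfile"), windowBp > 0)
  profile <- sortProfile(profile)
  gr <- rowRanges(profile)
  chrom <- .chromOf(gr)
  x <- mcols(gr)$midpoint
  y <- as.numeric(assay(profile, "raw"))
  h <- windowBp / 2
  sm <- numeric(length(y))
  nSingleton <- 0L
  for (ch in unique(chrom)) {
    on <- chrom == ch
    if (sum(on) < 2L) {
      sm[on] <- y[on]
      nSingleton <- nSingleton + sum(on)
      next
    }
    xi <- x[on]
    lo <- findInterval(xi - h, xi) + 1L
    hi <- findInterval(xi + h, xi)
    nSingleton <- nSingleton + sum(hi - lo == 0L)
    sm[on] <- .lowessFixedWindow(xi, y[on], h)
  }
  if (nSingleton > 0)
    warning(nSingleton,
            " probe(s) had a single-probe window; smoothed = raw there")
  md <- S4Vectors::metadata(profile)
  md$windowBp <- windowBp
  md$lowess <- list(degree = 1L, kernel = "tricube", robustIterations = 0L)
  assays <- list(raw = assay(profile, "raw"),
                 smoothed = matrix(sm, ncol = 1,
                                   dimnames = dimnames(assay(profile, "raw"))))
  se <- SummarizedExperiment(assays = assays, rowRanges = rowRanges(profile),
                             metadata = md)
  new("RatioProfile", se)
}

#' Correlate two smoothed profiles
#'
#' Profiles are intersected on probe id (coordinates must agree on the
#' shared probes) and the correlation of their smoothed ratios is returned.
#' Pearson is the default; Spearman is available.
#'
#' @param a,b Smoothed \code{\link{RatioProfile}} objects.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Correlation coefficient in [-1, 1].
#' @export
profileCorrelation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(isSmoothed(a), isSmoothed(b))
  ida <- mcols(rowRanges(a))$id
  idb <- mcols(rowRanges(b))$id
  common <- intersect(ida, idb)
  if (length(common) == 0L)
    stop("profiles share no probes")
  ia <- match(common, ida)
  ib <- match(common, idb)
  if (!identical(mcols(rowRanges(a))$midpoint[ia],
                 mcols(rowRanges(b))$midpoint[ib]))
    stop("shared probe ids have mismatched coordinates")
  va <- smoothedRatio(a)[ia]
  vb <- smoothedRatio(b)[ib]
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("correlation undefined: a profile has zero variance")
  stats::cor(va, vb, method = method)
}

#' @rdname RatioProfile-class
#' @export
setMethod("rawRatio", "RatioProfile",
          function(x) as.numeric(assay(x, "raw")))

#' @rdname RatioProfile-class
#' @export
setMethod("smoothedRatio", "RatioProfile", function(x) {
  if (!isSmoothed(x))
    stop("profile has not been smoothed; run lowessSmooth() first")
  as.numeric(assay(x, "smoothed"))
})

#' @rdname RatioProfile-class
#' @export
setMethod("isSmoothed", "RatioProfile",
          function(x) "smoothed" %in% assayNames(x))

#' @rdname RatioProfile-class
#' @export
setMethod("probes", "RatioProfile", function(x) rowRanges(x))
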