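#' Call significant sites against the genome-wide median
#'
#' The significance rule for breakage/ssDNA sites: a probe is a site when
#' its smoothed ratio is strictly greater than the median of all smoothed
#' ratios genome-wide. The threshold therefore scales with the profile, so
#' site calls are invariant to uniform rescaling. A constant profile yields
#' an empty site set with a warning.
#'
#' @param profile A smoothed \code{\link{RatioProfile}}.
#' @return A \code{\link{SiteSet}} with rule \code{above_median}.
#' @export
callSignificantSites <- function(profile) {
  stopifnot(is(profile, "RatioProfile"), isSmoothed(profile))
  profile <- sortProfile(profile)
  sm <- smoothedRatio(profile)
  thr <- stats::median(sm)
  keep <- sm > thr
  if (!any(keep))
    warning("no probes exceed the median; empty site set")
  gr <- rowRanges(profile)[keep]
  out <- granges(gr)
  mcols(out)$midpoint <- mcols(gr)$midpoint
  mcols(out)$score <- sm[keep]
  new("SiteSet", sites = out, threshold = thr, rule = "above_median",
      profileId = as.character(S4Vectors::metadata(profile)$profileId %||%
                                 "profile"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict local maxima of y (plateaus collapse to their middle index) and
# their topographic prominence: peak height minus the key saddle, i.e. the
# higher of the minimal descents toward higher ground on either side (or
# toward the chromosome end if no higher ground exists on that side).
.peakIndices <- function(y, minProminence) {
  n <- length(y)
  if (n < 3L) return(integer())
  r <- rle(y)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isMax <- logical(k)
  for (j in seq_len(k)) {
    leftOk <- j == 1L || r$values[j - 1L] < r$values[j]
    rightOk <- j == k || r$values[j + 1L] < r$values[j]
    isMax[j] <- leftOk && rightOk && j > 1L && j < k
  }
  cand <- which(isMax)
  idx <- integer()
  for (j in cand) {
    i <- (starts[j] + ends[j]) %/% 2L
    h <- y[i]
    leftHigher <- rev(which(y[seq_len(i - 1L)] > h))
    mL <- if (length(leftHigher)) min(y[leftHigher[1L]:(i - 1L)]) else NA
    rightHigher <- which(y[(i + 1L):n] > h)
    mR <- if (length(rightHigher)) min(y[(i + 1L):(i + rightHigher[1L])])
          else NA
    saddle <- if (is.na(mL) && is.na(mR)) min(y)
              else if (is.na(mL)) mR
              else if (is.na(mR)) mL
              else max(mL, mR)
    if (h - saddle >= minProminence) idx <- c(idx, i)
  }
  idx
}

#' Call peaks in a smoothed profile
#'
#' Local maxima of the smoothed ratio per chromosome, filtered by
#' topographic prominence relative to flanking minima. The default
#' prominence floor is half the interquartile range of the smoothed
#' profile, a declared convention of this package.
#'
#' @param profile A smoothed \code{\link{RatioProfile}}.
#' @param minProminence Minimum prominence; default
#'   \code{0.5 * IQR(smoothedRatio(profile))}.
#' @return A \code{\link{SiteSet}} with rule \code{local_peak}.
#' @export
callPeaks <- function(profile, minProminence = NULL) {
  stopifnot(is(profile, "RatioProfile"), isSmoothed(profile))
  profile <- sortProfile(profile)
  sm <- smoothedRatio(profile)
  if (is.null(minProminence))
    # floor guards the degenerate noiseless case (IQR 0), where numerical
    # ripples of ~1e-16 would otherwise qualify as peaks
    minProminence <- max(0.5 * stats::IQR(sm), 1e-8 * max(abs(sm), 1))
  gr <- rowRanges(profile)
  chrom <- .chromOf(gr)
  keep <- integer()
  for (ch in unique(chrom)) {
    on <- which(chrom == ch)
    keep <- c(keep, on[.peakIndices(sm[on], minProminence)])
  }
  keep <- sort(keep)
  out <- granges(gr[keep])
  mcols(out)$midpoint <- mcols(gr)$midpoint[keep]
  mcols(out)$score <- sm[keep]
  new("SiteSet", sites = out, threshold = minProminence, rule = "local_peak",
      profileId = as.character(S4Vectors::metadata(profile)$profileId %||%
                                 "profile"))
}

#' Construct a manual SiteSet from coordinates
#'
#' Used for externally supplied site lists (e.g. loaded from BED) and for
#' null-calibration draws from the probe universe.
#'
#' @param chrom Chromosome names.
#' @param midpoint Numeric midpoints (0-based bp).
#' @param layout A \code{Seqinfo}.
#' @param score Optional scores (default \code{NA}).
#' @param profileId Identifier string.
#' @return A \code{\link{SiteSet}} with rule \code{manual}.
#' @export
SiteSet <- function(chrom, midpoint, layout, score = NA_real_,
                    profileId = "manual") {
  chrom <- rep_len(chrom, length(midpoint))
  ord <- order(match(chrom, seqnames(layout)), midpoint)
  chrom <- chrom[ord]
  midpoint <- midpoint[ord]
  score <- rep_len(score, length(midpoint))[ord]
  iv <- .intervalForMidpoint(midpoint)
  gr <- GRanges(chrom, IRanges(start = iv$start0 + 1, end = iv$end0),
                seqinfo = layout)
  mcols(gr)$midpoint <- as.numeric(midpoint)
  mcols(gr)$score <- score
  new("SiteSet", sites = gr, threshold = NA_real_, rule = "manual",
      profileId = profileId)
}

#' @rdname SiteSet-class
#' @export
setMethod("siteMidpoints", "SiteSet", function(x) mcols(x@sites)$midpoint)

#' @rdname SiteSet-class
#' @export
setMethod("siteRule", "SiteSet", function(x) x@rule)

#' @rdname SiteSet-class
#' @export
setMethod("siteThreshold", "SiteSet", function(x) x@threshold)

#' @rdname SiteSet-class
#' @export
setMethod("granges", "SiteSet", function(x, ...) x@sites)

#' @rdname SiteSet-class
#' @export
setMethod("length", "SiteSet", function(x) length(x@sites))

setMethod("show", "SiteSet", function(object) {
  cat("SiteSet of", length(object), "sites | rule:", object@rule,
      "| threshold:", format(object@threshold, digits = 4),
      "| profile:", object@profileId, "\n")
})
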