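# Nearest same-chromosome feature midpoint distance for each query point.
# Features on other chromosomes contribute infinity. Real-valued, no
# rounding.
.nearestDistance <- function(chrom, midpoint, featChrom, featMid) {
  out <- rep(Inf, length(midpoint))
  if (length(featMid) == 0L) return(out)
  byChrom <- split(featMid, featChrom)
  for (ch in names(byChrom)) {
    q <- which(chrom == ch)
    if (!length(q)) next
    f <- sort(byChrom[[ch]])
    pos <- findInterval(midpoint[q], f)
    dLeft <- ifelse(pos >= 1L, midpoint[q] - f[pmax(pos, 1L)], Inf)
    dRight <- ifelse(pos < length(f), f[pmin(pos + 1L, length(f))] -
                       midpoint[q], Inf)
    out[q] <- pmin(dLeft, dRight)
  }
  out
}

#' Distance from each site to its nearest feature
#'
#' Distances are measured midpoint to midpoint on the same chromosome;
#' features on other chromosomes are infinitely far. An infinite distance
#' (no feature on the site's chromosome) is a valid result.
#'
#' @param sites A \code{\link{SiteSet}} or \code{GRanges}.
#' @param features A \code{\link{FeatureSet}}.
#' @return Numeric vector of distances in bp (possibly \code{Inf}).
#' @export
nearestFeatureDistance <- function(sites, features) {
  stopifnot(is(features, "FeatureSet"))
  gr <- if (is(sites, "SiteSet")) granges(sites) else sites
  mid <- if (is(sites, "SiteSet")) siteMidpoints(sites)
         else mcols(gr)$midpoint %||% probeMidpoints(gr)
  .nearestDistance(.chromOf(gr), mid,
                   .chromOf(granges(features)), featureMidpoints(features))
}

.countWithinCore <- function(chrom, midpoint, features, cutoffBp) {
  d <- .nearestDistance(chrom, midpoint,
                        .chromOf(granges(features)),
                        featureMidpoints(features))
  sum(d <= cutoffBp)
}

#' @rdname countWithin
#' @export
setMethod("countWithin", signature(sites = "SiteSet"),
          function(sites, features, cutoffBp = 6000) {
  stopifnot(is(features, "FeatureSet"), cutoffBp > 0)
  .countWithinCore(.chromOf(granges(sites)), siteMidpoints(sites),
                   features, cutoffBp)
})

#' @rdname countWithin
#' @export
setMethod("countWithin", signature(sites = "GRanges"),
          function(sites, features, cutoffBp = 6000) {
  stopifnot(is(features, "FeatureSet"), cutoffBp > 0)
  mid <- mcols(sites)$midpoint %||% probeMidpoints(sites)
  .countWithinCore(.chromOf(sites), mid, features, cutoffBp)
})

.simTestCore <- function(chrom, midpoint, features, probeUniverse, cutoffBp,
                         nSims, seed) {
  stopifnot(is(features, "FeatureSet"), cutoffBp > 0, nSims >= 1)
  flagged <- mcols(probeUniverse)$flagged
  if (is.null(flagged)) flagged <- rep(FALSE, length(probeUniverse))
  uni <- probeUniverse[!flagged]
  nSites <- length(midpoint)
  if (nSites > length(uni))
    stop("more sites (", nSites, ") than unflagged probes (",
         length(uni), ") in the universe")
  observed <- .countWithinCore(chrom, midpoint, features, cutoffBp)
  # the universe is fixed, so each probe's nearest-feature distance is
  # computed once; a random placement then counts its sampled probes that
  # fall within the cutoff
  within <- .nearestDistance(.chromOf(uni), probeMidpoints(uni),
                             .chromOf(granges(features)),
                             featureMidpoints(features)) <= cutoffBp
  nUni <- length(uni)
  nulls <- withSeed(seed, vapply(seq_len(nSims), function(i)
    sum(within[sample.int(nUni, nSites)]), integer(1)))
  new("AssociationResult",
      observedCount = as.integer(observed), nSites = as.integer(nSites),
      nFeatures = length(features), cutoffBp = as.numeric(cutoffBp),
      nSims = as.integer(nSims), nullCounts = nulls,
      pUpper = sum(nulls >= observed) / nSims, seed = as.integer(seed))
}

#' @rdname randomSimulationTest
#' @export
setMethod("randomSimulationTest", signature(sites = "SiteSet"),
          function(sites, features, probeUniverse, cutoffBp = 6000,
                   nSims = 10000, seed) {
  .simTestCore(.chromOf(granges(sites)), siteMidpoints(sites), features,
               probeUniverse, cutoffBp, nSims, seed)
})

#' @rdname randomSimulationTest
#' @export
setMethod("randomSimulationTest", signature(sites = "GRanges"),
          function(sites, features, probeUniverse, cutoffBp = 6000,
                   nSims = 10000, seed) {
  mid <- mcols(sites)$midpoint %||% probeMidpoints(sites)
  .simTestCore(.chromOf(sites), mid, features, probeUniverse, cutoffBp,
               nSims, seed)
})

#' Exact null distribution of the within-cutoff count
#'
#' Enumerates every equally likely placement of \code{nSites} positions on
#' the unflagged probe universe and tabulates the within-cutoff count,
#' giving the exact probability mass function that
#' \code{\link{randomSimulationTest}} approximates by Monte Carlo. Only
#' feasible for small instances (\code{choose(N, nSites) <= 1e6}).
#'
#' @param nSites Number of site positions per placement.
#' @param features A \code{\link{FeatureSet}}.
#' @param probeUniverse \code{GRanges} of probes.
#' @param cutoffBp Inclusive distance cutoff in bp.
#' @return \code{data.frame} with columns \code{count} and \code{prob}.
#' @export
exhaustiveNull <- function(nSites, features, probeUniverse, cutoffBp = 6000) {
  stopifnot(is(features, "FeatureSet"), cutoffBp > 0, nSites >= 1)
  flagged <- mcols(probeUniverse)$flagged
  if (is.null(flagged)) flagged <- rep(FALSE, length(probeUniverse))
  uni <- probeUniverse[!flagged]
  N <- length(uni)
  if (nSites > N) stop("nSites exceeds the probe universe")
  if (choose(N, nSites) > 1e6)
    stop("choose(N, nSites) > 1e6; use randomSimulationTest (Monte Carlo)")
  within <- .nearestDistance(.chromOf(uni), probeMidpoints(uni),
                             .chromOf(granges(features)),
                             featureMidpoints(features)) <= cutoffBp
  combos <- utils::combn(N, nSites)
  counts <- colSums(matrix(within[combos], nrow = nSites))
  tab <- table(factor(counts, levels = 0:nSites))
  data.frame(count = 0:nSites,
             prob = as.numeric(tab) / sum(tab))
}

#' Upper-tail probability from an exact null
#'
#' @param null A \code{data.frame} from \code{\link{exhaustiveNull}}.
#' @param observed Observed within-cutoff count.
#' @return Exact \code{P(count >= observed)} under the null.
#' @export
exactPUpper <- function(null, observed) {
  sum(null$prob[null$count >= observed])
}

#' Two-sample proportion test with continuity correction
#'
#' Pearson chi-square on the 2x2 table with Yates continuity correction
#' (two-sided, 1 df), via \code{\link[stats]{prop.test}}; the statistic is
#' floored at 0 when the correction exceeds the absolute difference.
#' A degenerate pooled proportion of 0 or 1 returns statistic 0, p = 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return A \code{\link{ProportionTestResult}}.
#' @examples
#' proportionTest(266, 639, 75, 639)  # checked vs unchecked origin fractions
#' @export
proportionTest <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    stat <- 0
    p <- 1
  } else {
    ht <- stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  new("ProportionTestResult", x1 = as.integer(x1), n1 = as.integer(n1),
      x2 = as.integer(x2), n2 = as.integer(n2),
      p1Hat = x1 / n1, p2Hat = x2 / n2, statistic = stat, pValue = p)
}

#' @rdname AssociationResult-class
#' @param object An \code{AssociationResult}.
#' @export
pUpper <- function(object) object@pUpper

#' @rdname AssociationResult-class
#' @export
observedCount <- function(object) object@observedCount

#' @rdname AssociationResult-class
#' @export
nullCounts <- function(object) object@nullCounts

setMethod("show", "AssociationResult", function(object) {
  cat("AssociationResult:", object@observedCount, "of", object@nSites,
      "sites within", object@cutoffBp, "bp of", object@nFeatures,
      "features\n  null:", object@nSims, "simulations (seed",
      paste0(object@seed, ")"), "| upper-tail P =",
      format(object@pUpper, digits = 4), "\n")
})

setMethod("show", "ProportionTestResult", function(object) {
  cat(sprintf(
    "Two-sample proportion test (Yates): %d/%d (%.1f%%) vs %d/%d (%.1f%%)\n",
    object@x1, object@n1, 100 * object@p1Hat,
    object@x2, object@n2, 100 * object@p2Hat))
  cat(sprintf("  X-squared = %.4g, df = 1, p-value = %.4g\n",
              object@statistic, object@pValue))
})
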