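suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# --- fixtures -------------------------------------------------------------

# two 200 kb chromosomes: the default sub-second mini-genome
miniLayout <- function(n = 2L, len = 200000L) {
  GenomeInfoDb::Seqinfo(paste0("chr", LETTERS[seq_len(n)]), rep(len, n))
}

writeChromSizes <- function(layout, path = tempfile(fileext = ".sizes")) {
  writeLines(sprintf("%s\t%d", GenomeInfoDb::seqnames(layout),
                     GenomeInfoDb::seqlengths(layout)), path)
  path
}

# build an ArraySample from explicit foreground values (bg added to signal)
sampleFromValues <- function(probes, fgExp, fgCtl, bg = 100) {
  n <- length(probes)
  se <- SummarizedExperiment(
    assays = list(signal = cbind(exp = fgExp + bg, ctl = fgCtl + bg),
                  background = cbind(exp = rep(bg, n), ctl = rep(bg, n))),
    rowRanges = probes,
    colData = S4Vectors::DataFrame(channel = c("exp", "ctl"),
                                   row.names = c("exp", "ctl")))
  new("ArraySample", se)
}

# build a RatioProfile directly from values (for smoothing/site-call tests)
profileFromValues <- function(probes, raw, smoothed = NULL,
                              windowBp = 6000, id = "fixture") {
  gr <- granges(probes)
  mcols(gr)$id <- mcols(probes)$id
  mcols(gr)$midpoint <- probeMidpoints(probes)
  assays <- list(raw = matrix(raw, ncol = 1, dimnames = list(NULL, id)))
  md <- list(profileId = id)
  if (!is.null(smoothed)) {
    assays$smoothed <- matrix(smoothed, ncol = 1,
                              dimnames = list(NULL, id))
    md$windowBp <- windowBp
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = gr, metadata = md)
  new("RatioProfile", se)
}

# the planted-truth study scenario: gaussian breakage peaks at every
# "checked" origin, none at "unchecked" origins, on the mini-genome
plantedScenario <- function(layout = miniLayout(), spacing = 500,
                            amplitude = 6, width = 2000, noiseCv = 0.1,
                            seed = 101) {
  chroms <- GenomeInfoDb::seqnames(layout)
  checkedPos <- c(30000, 60000, 90000, 120000, 150000)
  uncheckedPos <- c(45000, 75000, 105000, 135000, 165000)
  checked <- FeatureSet(rep(chroms, each = length(checkedPos)),
                        rep(checkedPos, length(chroms)),
                        "checked_origin", layout)
  unchecked <- FeatureSet(rep(chroms, each = length(uncheckedPos)),
                          rep(uncheckedPos, length(chroms)),
                          "unchecked_origin", layout)
  probes <- makeProbeGrid(layout, spacing = spacing, probeLength = 60)
  truth <- SyntheticTruth(peaks = data.frame(
    chrom = rep(chroms, each = length(checkedPos)),
    center = rep(checkedPos, length(chroms)),
    amplitude = amplitude, width = width, shape = "gaussian"),
    baselineRatio = 1)
  sample <- simulateSample(probes, truth, noiseCv = noiseCv, seed = seed)
  list(layout = layout, probes = probes, truth = truth, sample = sample,
       checked = checked, unchecked = unchecked)
}

# --- independent oracles --------------------------------------------------

# O(n^2) locally weighted linear regression with tricube weights over a
# fixed half-window h, via lm() at every point
bruteLowess <- function(x, y, h) {
  vapply(seq_along(x), function(i) {
    d <- abs(x - x[i]) / h
    w <- ifelse(d <= 1, (1 - d^3)^3, 0)
    use <- w > 0
    if (sum(use) == 1L) return(y[i])
    if (length(unique(x[use])) == 1L)
      return(sum(w[use] * y[use]) / sum(w[use]))
    fit <- lm(y ~ x, data = data.frame(x = x[use], y = y[use]),
              weights = w[use])
    unname(predict(fit, newdata = data.frame(x = x[i])))
  }, numeric(1))
}

# exhaustive pairwise minimum distance, same-chromosome rule
bruteNearest <- function(chrom, mid, fchrom, fmid) {
  vapply(seq_along(mid), function(i) {
    d <- abs(mid[i] - fmid[fchrom == chrom[i]])
    if (length(d) == 0L) Inf else min(d)
  }, numeric(1))
}

# textbook Yates-corrected chi-square on the 2x2 table
yatesChiSquare <- function(x1, n1, x2, n2) {
  N <- n1 + n2
  num <- abs(x1 * (n2 - x2) - x2 * (n1 - x1)) - N / 2
  num <- max(num, 0)
  stat <- N * num^2 / (n1 * n2 * (x1 + x2) * (N - x1 - x2))
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# exact null pmf of the within-cutoff count by direct enumeration over all
# placements, with brute-force distances (independent of the package path)
bruteNullPmf <- function(nSites, probeUniverse, features, cutoffBp) {
  mid <- probeMidpoints(probeUniverse)
  chrom <- as.character(seqnames(probeUniverse))
  fgr <- granges(features)
  d <- bruteNearest(chrom, mid, as.character(seqnames(fgr)),
                    featureMidpoints(features))
  within <- d <= cutoffBp
  combos <- combn(length(mid), nSites)
  counts <- colSums(matrix(within[combos], nrow = nSites))
  tab <- table(factor(counts, levels = 0:nSites))
  data.frame(count = 0:nSites, prob = as.numeric(tab) / sum(tab))
}
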