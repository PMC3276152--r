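test_that("ratios are normalized to total channel signal", {
  layout <- miniLayout(1L, 10000L)
  pr <- makeProbeGrid(layout, spacing = 500, probeLength = 60)
  n <- length(pr)

  flat <- simulateSample(pr, SyntheticTruth(), noiseCv = 0, seed = 1)
  prof <- computeRatios(flat)
  expect_equal(rawRatio(prof), rep(1, n), tolerance = 1e-12)

  # uniform rescaling of one channel cancels in the normalization
  s1 <- sampleFromValues(pr, fgExp = seq_len(n) * 10, fgCtl = rep(500, n))
  s2 <- sampleFromValues(pr, fgExp = seq_len(n) * 20, fgCtl = rep(500, n))
  expect_equal(rawRatio(computeRatios(s1)), rawRatio(computeRatios(s2)),
               tolerance = 1e-12)

  # closed form for one amplitude-3 point peak over n probes
  truth <- SyntheticTruth(peaks = data.frame(
    chrom = "chrA", center = probeMidpoints(pr)[7], amplitude = 3,
    width = 1, shape = "point"))
  s <- simulateSample(pr, truth, noiseCv = 0, seed = 1)
  raw <- rawRatio(computeRatios(s))
  expect_equal(raw[7], 4 * n / (n + 3), tolerance = 1e-12)
  expect_equal(raw[-7], rep(n / (n + 3), n - 1), tolerance = 1e-12)

  # conservation: both normalized channel totals are exactly 1
  norm <- S4Vectors::metadata(computeRatios(s))$normalization
  expect_equal(norm$normExpSum, 1, tolerance = 1e-14)
  expect_equal(norm$normCtlSum, 1, tolerance = 1e-14)
})

test_that("flagged and non-positive-control probes are excluded, not imputed", {
  layout <- miniLayout(1L, 10000L)
  pr <- makeProbeGrid(layout, spacing = 500, probeLength = 60,
                      flagFraction = 0.3, seed = 9)
  nFlagged <- sum(mcols(pr)$flagged)
  expect_gt(nFlagged, 0)
  s <- simulateSample(pr, SyntheticTruth(), noiseCv = 0.05, seed = 4)
  prof <- computeRatios(s)
  expect_identical(nrow(prof), length(pr) - nFlagged)
  expect_identical(S4Vectors::metadata(prof)$droppedFlagged, nFlagged)
  expect_true(all(!mcols(probes(prof))$id %in%
                    mcols(pr)$id[mcols(pr)$flagged]))

  # zero net control signal cannot carry a ratio
  pr2 <- makeProbeGrid(layout, spacing = 500, probeLength = 60)
  fgCtl <- rep(1000, length(pr2)); fgCtl[3] <- 0
  s2 <- sampleFromValues(pr2, fgExp = rep(1000, length(pr2)), fgCtl = fgCtl)
  expect_message(prof2 <- computeRatios(s2), "1 probe")
  expect_identical(S4Vectors::metadata(prof2)$droppedNonPositiveControl, 1L)
  expect_identical(nrow(prof2), length(pr2) - 1L)

  s3 <- sampleFromValues(pr2, fgExp = rep(1000, length(pr2)),
                         fgCtl = rep(0, length(pr2)))
  expect_error(suppressMessages(computeRatios(s3)), "no probes")
})

test_that("fixed-window lowess reproduces constants and linear trends", {
  layout <- miniLayout(1L, 50000L)
  pr <- makeProbeGrid(layout, spacing = 500, probeLength = 60)
  x <- probeMidpoints(pr)

  cprof <- lowessSmooth(profileFromValues(pr, rep(2.5, length(pr))))
  expect_equal(smoothedRatio(cprof), rep(2.5, length(pr)), tolerance = 1e-12)

  lin <- 1 + 3e-5 * x
  lprof <- lowessSmooth(profileFromValues(pr, lin))
  expect_equal(smoothedRatio(lprof), lin, tolerance = 1e-9)
})

test_that("lowess agrees with a brute-force weighted regression oracle", {
  layout <- miniLayout(1L, 60000L)
  pr <- makeProbeGrid(layout, spacing = 400, probeLength = 60)
  x <- probeMidpoints(pr)
  step <- ifelse(x < 30000, 1, 2)
  prof <- lowessSmooth(profileFromValues(pr, step), windowBp = 6000)
  expect_equal(smoothedRatio(prof), bruteLowess(x, step, 3000),
               tolerance = 1e-9)

  set.seed(31)
  noisy <- exp(rnorm(length(x), sd = 0.2))
  nprof <- lowessSmooth(profileFromValues(pr, noisy), windowBp = 6000)
  expect_equal(smoothedRatio(nprof), bruteLowess(x, noisy, 3000),
               tolerance = 1e-9)
})

test_that("smoothing respects chromosome boundaries and mass", {
  layout <- miniLayout()
  pr <- makeProbeGrid(layout, spacing = 500, probeLength = 60)
  chrom <- as.character(seqnames(pr))
  x <- probeMidpoints(pr)
  # linear on chrA, constant on chrB: neither bleeds into the other
  y <- ifelse(chrom == "chrA", 1 + 2e-5 * x, 3)
  sm <- smoothedRatio(lowessSmooth(profileFromValues(pr, y)))
  expect_equal(sm[chrom == "chrB"], rep(3, sum(chrom == "chrB")),
               tolerance = 1e-9)
  expect_equal(sm[chrom == "chrA"], y[chrom == "chrA"], tolerance = 1e-9)

  # flat-plus-symmetric-peak: mean is conserved within 1%
  peak <- 1 + 4 * exp(-(x - 100000)^2 / (2 * 3000^2)) * (chrom == "chrA")
  smp <- smoothedRatio(lowessSmooth(profileFromValues(pr, peak)))
  expect_lt(abs(mean(smp) - mean(peak)) / mean(peak), 0.01)
})

test_that("profile correlation behaves as Pearson on shared probes", {
  layout <- miniLayout()
  sc <- plantedScenario(layout, seed = 41)
  profA <- lowessSmooth(computeRatios(simulateSample(
    sc$probes, sc$truth, noiseCv = 0.1, seed = 42), "a"))
  expect_equal(profileCorrelation(profA, profA), 1)

  # affine negation about the median gives exactly -1
  profFull <- lowessSmooth(computeRatios(simulateSample(
    sc$probes, sc$truth, noiseCv = 0, seed = 1), "a"))
  smF <- smoothedRatio(profFull)
  negF <- profileFromValues(sc$probes, rawRatio(profFull),
                            smoothed = 2 * median(smF) - smF)
  expect_equal(profileCorrelation(profFull, negF), -1)

  # replicates simulated from the same truth correlate strongly
  profB <- lowessSmooth(computeRatios(simulateSample(
    sc$probes, sc$truth, noiseCv = 0.1, seed = 43), "b"))
  expect_gt(profileCorrelation(profA, profB), 0.9)

  flat <- profileFromValues(sc$probes, rep(1, length(sc$probes)),
                            smoothed = rep(1, length(sc$probes)))
  expect_error(profileCorrelation(profA, flat), "zero variance")
})
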