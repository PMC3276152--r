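test_that("nearest-feature distances follow the same-chromosome midpoint rule", {
  layout <- GenomeInfoDb::Seqinfo(c("chrI", "chrII"), c(300000L, 300000L))
  fs1 <- FeatureSet("chrI", 100, "other", layout)
  one <- SiteSet("chrI", 100, layout)
  expect_equal(nearestFeatureDistance(one, fs1), 0)

  fs2 <- FeatureSet(c("chrI", "chrII"), c(5000, 100), "other", layout)
  expect_equal(nearestFeatureDistance(one, fs2), 4900)

  # no feature on the site's chromosome: infinite distance is valid
  fs3 <- FeatureSet("chrII", 100, "other", layout)
  expect_identical(nearestFeatureDistance(one, fs3), Inf)

  # random instance vs exhaustive pairwise oracle
  set.seed(7)
  sChrom <- sample(c("chrI", "chrII"), 100, replace = TRUE)
  sMid <- sample.int(299000, 100)
  fChrom <- sample(c("chrI", "chrII"), 20, replace = TRUE)
  fMid <- sample.int(299000, 20)
  ss <- SiteSet(sChrom, sMid, layout)
  ff <- FeatureSet(fChrom, fMid, "other", layout)
  got <- nearestFeatureDistance(ss, ff)
  sgr <- granges(ss)
  want <- bruteNearest(as.character(seqnames(sgr)), siteMidpoints(ss),
                       fChrom, fMid)
  expect_equal(got, want)
  expect_identical(countWithin(ss, ff, 6000), sum(want <= 6000))
})

test_that("the 6 kb cutoff boundary is inclusive", {
  layout <- miniLayout(1L, 100000L)
  fs <- FeatureSet("chrA", 50000, "checked_origin", layout)
  atBoundary <- SiteSet("chrA", 44000, layout)
  expect_identical(countWithin(atBoundary, fs, 6000), 1L)
  justBeyond <- SiteSet("chrA", 43999.5, layout)
  expect_identical(countWithin(justBeyond, fs, 6000), 0L)
  coincident <- SiteSet(rep("chrA", 3), c(49999, 50000, 50001), layout)
  expect_identical(countWithin(coincident, fs, 6000), 3L)
})

test_that("proportion test matches the textbook Yates formula", {
  same <- proportionTest(10, 100, 10, 100)
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  r <- proportionTest(25, 100, 10, 100)
  oracle <- yatesChiSquare(25, 100, 10, 100)
  expect_equal(r@statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(r@pValue, oracle$p, tolerance = 1e-10)
  expect_equal(r@p1Hat, 0.25)

  # degenerate pooled proportions
  expect_equal(proportionTest(0, 50, 0, 60)@pValue, 1)
  expect_equal(proportionTest(50, 50, 60, 60)@statistic, 0)

  # checked- vs unchecked-origin site fractions: 41.6% vs 11.7% of 639
  pub <- proportionTest(266, 639, 75, 639)
  expect_lt(pub@pValue, 1e-15)
})

test_that("randomization test handles saturated and empty feature sets", {
  layout <- miniLayout(1L, 20000L)
  pr <- makeProbeGrid(layout, spacing = 1000, probeLength = 60)
  # every probe is within the cutoff of some feature
  sat <- FeatureSet("chrA", 10000, "checked_origin", layout)
  ss <- SiteSet("chrA", probeMidpoints(pr)[c(8, 12)], layout)
  res <- randomSimulationTest(ss, sat, pr, cutoffBp = 20000, nSims = 200,
                              seed = 1)
  expect_identical(observedCount(res), 2L)
  expect_true(all(nullCounts(res) == 2L))
  expect_equal(pUpper(res), 1)

  emptyFs <- FeatureSet(character(), numeric(), character(), layout)
  res0 <- randomSimulationTest(ss, emptyFs, pr, nSims = 100, seed = 2)
  expect_identical(observedCount(res0), 0L)
  expect_equal(pUpper(res0), 1)

  big <- SiteSet("chrA", probeMidpoints(pr), layout)
  expect_error(randomSimulationTest(big, sat, pr[1:5], nSims = 10, seed = 1),
               "more sites")
})

test_that("exhaustive null enumerates the exact placement distribution", {
  layout <- miniLayout(1L, 20000L)
  pr <- makeProbeGrid(layout, spacing = 1000, probeLength = 60)  # 20 probes
  # all probes near the feature: mass 1 at the site count
  sat <- FeatureSet("chrA", 10000, "checked_origin", layout)
  nullAll <- exhaustiveNull(2, sat, pr[1:4], cutoffBp = 20000)
  expect_equal(nullAll$prob[nullAll$count == 2], 1)

  # 3 of 10 probes near features: P(count = 1) = 0.3 for one site
  fs <- FeatureSet("chrA", probeMidpoints(pr)[2], "checked_origin", layout)
  null1 <- exhaustiveNull(1, fs, pr[1:10], cutoffBp = 1000)
  expect_equal(null1$prob[null1$count == 1], 0.3)

  # matches the independent brute-force enumeration on a random instance
  set.seed(11)
  uni <- pr[sort(sample.int(length(pr), 9))]
  ff <- FeatureSet(rep("chrA", 2), sort(sample.int(19000, 2)), "other",
                   layout)
  got <- exhaustiveNull(3, ff, uni, cutoffBp = 2500)
  want <- bruteNullPmf(3, uni, ff, cutoffBp = 2500)
  expect_equal(got, want)

  expect_error(exhaustiveNull(20, sat, makeProbeGrid(
    miniLayout(), spacing = 500, probeLength = 60), 6000), "1e6")
})

test_that("simulation draws are reproducible and seed-sensitive", {
  layout <- miniLayout()
  sc <- plantedScenario(layout, seed = 31)
  prof <- lowessSmooth(computeRatios(sc$sample))
  sites <- callSignificantSites(prof)
  a <- randomSimulationTest(sites, sc$checked, sc$probes, nSims = 300,
                            seed = 5)
  b <- randomSimulationTest(sites, sc$checked, sc$probes, nSims = 300,
                            seed = 5)
  c <- randomSimulationTest(sites, sc$checked, sc$probes, nSims = 300,
                            seed = 6)
  expect_identical(nullCounts(a), nullCounts(b))
  expect_false(identical(nullCounts(a), nullCounts(c)))
})

test_that("p-values are invariant to translation and relabeling", {
  layout <- GenomeInfoDb::Seqinfo(c("chrI", "chrII"), c(100000L, 100000L))
  pr <- makeProbeGrid(layout, spacing = 1000, probeLength = 60)
  fs <- FeatureSet(c("chrI", "chrII"), c(20000, 70000), "other", layout)
  ss <- SiteSet(c("chrI", "chrI", "chrII"), c(19500.5, 60500.5, 69500.5),
                layout)
  base <- randomSimulationTest(ss, fs, pr, nSims = 500, seed = 9)

  # translate everything on chrI by a constant
  shift <- 5000
  layout2 <- GenomeInfoDb::Seqinfo(c("chrI", "chrII"),
                                   c(100000L + shift, 100000L))
  prM <- probeMidpoints(pr)
  prChrom <- as.character(seqnames(pr))
  mids2 <- ifelse(prChrom == "chrI", prM + shift, prM)
  pr2 <- GRanges(prChrom, IRanges(start = floor(mids2 - 29),
                                  end = floor(mids2 + 30)),
                 seqinfo = layout2)
  mcols(pr2)$id <- mcols(pr)$id
  mcols(pr2)$flagged <- mcols(pr)$flagged
  fs2 <- FeatureSet(c("chrI", "chrII"), c(20000 + shift, 70000), "other",
                    layout2)
  ss2 <- SiteSet(c("chrI", "chrI", "chrII"),
                 c(19500.5 + shift, 60500.5 + shift, 69500.5), layout2)
  trans <- randomSimulationTest(ss2, fs2, pr2, nSims = 500, seed = 9)
  expect_identical(nullCounts(base), nullCounts(trans))
  expect_identical(pUpper(base), pUpper(trans))

  # relabel chromosomes
  layout3 <- GenomeInfoDb::Seqinfo(c("alpha", "beta"), c(100000L, 100000L))
  map <- c(chrI = "alpha", chrII = "beta")
  pr3 <- GRanges(unname(map[prChrom]), IRanges(start(pr), end(pr)),
                 seqinfo = layout3)
  mcols(pr3) <- mcols(pr)
  fs3 <- FeatureSet(c("alpha", "beta"), c(20000, 70000), "other", layout3)
  ss3 <- SiteSet(c("alpha", "alpha", "beta"), c(19500.5, 60500.5, 69500.5),
                 layout3)
  rel <- randomSimulationTest(ss3, fs3, pr3, nSims = 500, seed = 9)
  expect_identical(pUpper(base), pUpper(rel))
})

test_that("enlarging the cutoff never decreases any count", {
  layout <- miniLayout()
  sc <- plantedScenario(layout, seed = 51)
  prof <- lowessSmooth(computeRatios(sc$sample))
  sites <- callSignificantSites(prof)
  small <- randomSimulationTest(sites, sc$checked, sc$probes,
                                cutoffBp = 3000, nSims = 400, seed = 12)
  large <- randomSimulationTest(sites, sc$checked, sc$probes,
                                cutoffBp = 9000, nSims = 400, seed = 12)
  expect_gte(observedCount(large), observedCount(small))
  expect_true(all(nullCounts(large) >= nullCounts(small)))
})
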