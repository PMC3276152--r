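#' Run the profile stage: sample TSV to smoothed profile files
#'
#' Composes \code{\link{readArraySample}} (or takes an
#' \code{\link{ArraySample}} directly), \code{\link{computeRatios}} and
#' \code{\link{lowessSmooth}}, writing a bedGraph, a raw+smoothed TSV and a
#' plain-text log recording every filtering action (flagged spots removed,
#' probes dropped for non-positive control signal) and the normalization
#' totals. Outputs are deterministic for fixed inputs.
#'
#' @param sample Path to a sample TSV, or an \code{ArraySample}.
#' @param layout A \code{Seqinfo} (required when \code{sample} is a path).
#' @param windowBp Smoothing window in bp (default 6000).
#' @param outDir Output directory (created if needed).
#' @param name Basename for the output files.
#' @param columnMap Passed to \code{\link{readArraySample}}.
#' @return The smoothed \code{\link{RatioProfile}}, invisibly.
#' @export
runProfile <- function(sample, layout = NULL, windowBp = 6000,
                       outDir = ".", name = "profile", columnMap = NULL) {
  if (is.character(sample)) {
    if (is.null(layout)) stop("a layout is required to read a sample TSV")
    sample <- readArraySample(sample, layout, columnMap = columnMap)
  }
  stopifnot(is(sample, "ArraySample"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  prof <- withCallingHandlers(
    computeRatios(sample, profileId = name),
    message = function(m) invokeRestart("muffleMessage"))
  prof <- suppressWarnings(lowessSmooth(prof, windowBp = windowBp))
  md <- S4Vectors::metadata(prof)
  exportProfile(prof,
                bedGraphPath = file.path(outDir, paste0(name, ".bedGraph")),
                tsvPath = file.path(outDir, paste0(name, ".tsv")))
  logLines <- c(
    sprintf("profile: %s", name),
    sprintf("probes_in_sample: %d", length(probes(sample))),
    sprintf("flagged_probes_removed: %d", md$droppedFlagged),
    sprintf("nonpositive_control_probes_dropped: %d",
            md$droppedNonPositiveControl),
    sprintf("probes_in_profile: %d", nrow(prof)),
    sprintf("normalization_exp_total: %.10g", md$normalization$expTotal),
    sprintf("normalization_ctl_total: %.10g", md$normalization$ctlTotal),
    sprintf("window_bp: %g", windowBp))
  writeLines(logLines, file.path(outDir, paste0(name, ".log")))
  invisible(prof)
}

#' Run the full fragility analysis
#'
#' End-to-end composition for one experimental sample: ratio profile,
#' Lowess smoothing, site calling, per-feature-category proximity counts
#' and randomization tests, plus pairwise correlations across any
#' additional profiles supplied. Writes a JSON report (with the full null
#' count histograms), a human-readable table, and echoes the effective
#' configuration and seed into the output directory.
#'
#' @param sample An \code{\link{ArraySample}} or sample TSV path.
#' @param featureSets Named list of \code{\link{FeatureSet}} objects, one
#'   per category to test.
#' @param layout A \code{Seqinfo} (required when \code{sample} is a path).
#' @param probeUniverse \code{GRanges} of probes used for the null
#'   randomization (defaults to the probes of \code{sample}).
#' @param otherProfiles Optional named list of smoothed
#'   \code{\link{RatioProfile}} objects to correlate against.
#' @param windowBp,cutoffBp,nSims,rule,seed Analysis parameters; defaults
#'   6000 bp, 6000 bp, 10000 simulations, "above_median".
#' @param outDir Output directory.
#' @param name Run name.
#' @return A list (the report) with elements \code{sites},
#'   \code{associations}, \code{correlations}, invisibly written to
#'   \code{outDir}.
#' @export
runFullAnalysis <- function(sample, featureSets, layout = NULL,
                            probeUniverse = NULL, otherProfiles = list(),
                            windowBp = 6000, cutoffBp = 6000, nSims = 10000,
                            rule = c("above_median", "local_peak"),
                            seed, outDir = ".", name = "run") {
  rule <- match.arg(rule)
  stopifnot(length(featureSets) >= 1, !is.null(names(featureSets)))
  if (is.character(sample)) {
    if (is.null(layout)) stop("a layout is required to read a sample TSV")
    sample <- readArraySample(sample, layout)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(probeUniverse)) probeUniverse <- probes(sample)
  prof <- runProfile(sample, windowBp = windowBp, outDir = outDir,
                     name = name)
  sites <- if (rule == "above_median") callSignificantSites(prof)
           else callPeaks(prof)
  exportSites(sites, file.path(outDir, paste0(name, "_sites.bed")))

  associations <- list()
  for (cat in names(featureSets)) {
    associations[[cat]] <- randomSimulationTest(
      sites, featureSets[[cat]], probeUniverse,
      cutoffBp = cutoffBp, nSims = nSims, seed = seed)
  }

  correlations <- list()
  if (length(otherProfiles)) {
    if (length(sites) == 0L)
      warning("empty site set; correlations computed on profiles only")
    for (nm in names(otherProfiles))
      correlations[[nm]] <- profileCorrelation(prof, otherProfiles[[nm]])
  }

  report <- list(
    name = name,
    seed = seed,
    parameters = list(windowBp = windowBp, cutoffBp = cutoffBp,
                      nSims = nSims, rule = rule),
    nSites = length(sites),
    siteThreshold = siteThreshold(sites),
    associations = lapply(associations, function(a) list(
      observedCount = a@observedCount, nSites = a@nSites,
      nFeatures = a@nFeatures, cutoffBp = a@cutoffBp, nSims = a@nSims,
      pUpper = a@pUpper,
      nullHistogram = as.list(table(a@nullCounts)))),
    correlations = correlations)
  jsonlite::write_json(report, file.path(outDir, paste0(name, "_report.json")),
                       auto_unbox = TRUE, digits = NA)

  tabLines <- c(
    sprintf("Run: %s (seed %s)", name, format(seed)),
    sprintf("Significant sites (%s): %d (threshold %.4g)", rule,
            length(sites), siteThreshold(sites)),
    sprintf("%-20s %12s %12s %10s", "feature category", "sites near",
            "of n sites", "P (upper)"),
    vapply(names(associations), function(cat) {
      a <- associations[[cat]]
      sprintf("%-20s %12d %12d %10.4g", cat, a@observedCount, a@nSites,
              a@pUpper)
    }, character(1)))
  if (length(correlations))
    tabLines <- c(tabLines, "",
                  vapply(names(correlations), function(nm)
                    sprintf("correlation vs %s: %.4f", nm,
                            correlations[[nm]]), character(1)))
  writeLines(tabLines, file.path(outDir, paste0(name, "_table.txt")))

  cfg <- list(name = name, seed = seed, windowBp = windowBp,
              cutoffBp = cutoffBp, nSims = nSims, rule = rule,
              featureCategories = names(featureSets))
  yaml::write_yaml(cfg, file.path(outDir, paste0(name, "_config.yaml")))

  invisible(list(profile = prof, sites = sites, associations = associations,
                 correlations = correlations, report = report))
}
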