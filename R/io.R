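.ARRAY_TSV_COLS <- c("probe_id", "chrom", "start", "end", "flagged",
                     "exp_signal", "exp_bg", "ctl_signal", "ctl_bg")

#' Write an ArraySample as TSV
#'
#' Columns: \code{probe_id, chrom, start, end, flagged, exp_signal, exp_bg,
#' ctl_signal, ctl_bg}; \code{start}/\code{end} are BED-convention (0-based,
#' half-open).
#'
#' @param x An \code{\link{ArraySample}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeArraySample <- function(x, path) {
  pr <- probes(x)
  df <- data.frame(probe_id = mcols(pr)$id,
                   chrom = .chromOf(pr),
                   start = start(pr) - 1L,
                   end = end(pr),
                   flagged = as.integer(mcols(pr)$flagged),
                   exp_signal = expSignal(x), exp_bg = expBackground(x),
                   ctl_signal = ctlSignal(x), ctl_bg = ctlBackground(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ArraySample from TSV
#'
#' Accepts the dialect written by \code{\link{writeArraySample}}, or any
#' tab-separated table via \code{columnMap}, a named list mapping the
#' canonical column names to the names used in the file. Malformed rows are
#' rejected with the offending line number, never coerced.
#'
#' @param path Input TSV path.
#' @param layout A \code{Seqinfo}.
#' @param columnMap Optional named list, e.g.
#'   \code{list(probe_id = "FeatureID", ...)}.
#' @return An \code{\link{ArraySample}}.
#' @export
readArraySample <- function(path, layout, columnMap = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.null(columnMap)) {
    for (canon in names(columnMap)) {
      if (!columnMap[[canon]] %in% colnames(df))
        stop("column '", columnMap[[canon]], "' (mapped to '", canon,
             "') not found in ", path)
      colnames(df)[colnames(df) == columnMap[[canon]]] <- canon
    }
  }
  missing <- setdiff(.ARRAY_TSV_COLS, colnames(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "),
         "; expected: ", paste(.ARRAY_TSV_COLS, collapse = ", "))
  num <- c("start", "end", "exp_signal", "exp_bg", "ctl_signal", "ctl_bg")
  for (cc in num) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("non-numeric value in column '", cc, "' at line ",
           which(is.na(v))[1L] + 1L, " of ", path)
    df[[cc]] <- v
  }
  if (!all(df$chrom %in% seqnames(layout)))
    stop("unknown chromosome at line ",
         which(!df$chrom %in% seqnames(layout))[1L] + 1L, " of ", path)
  if (any(df$start < 0 | df$end <= df$start))
    stop("invalid interval at line ",
         which(df$start < 0 | df$end <= df$start)[1L] + 1L, " of ", path)
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end),
                seqinfo = layout)
  mcols(gr)$id <- as.character(df$probe_id)
  mcols(gr)$flagged <- as.logical(as.integer(df$flagged))
  se <- SummarizedExperiment(
    assays = list(signal = cbind(exp = df$exp_signal, ctl = df$ctl_signal),
                  background = cbind(exp = df$exp_bg, ctl = df$ctl_bg)),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(channel = c("exp", "ctl"),
                                   row.names = c("exp", "ctl")))
  new("ArraySample", se)
}

#' Export a profile as bedGraph and TSV
#'
#' The bedGraph carries the smoothed ratio over the probe intervals
#' (browser-loadable); the TSV carries both raw and smoothed columns.
#'
#' @param profile A smoothed \code{\link{RatioProfile}}.
#' @param bedGraphPath Output bedGraph path (\code{NULL} to skip).
#' @param tsvPath Output TSV path (\code{NULL} to skip).
#' @return Invisibly, the written paths.
#' @export
exportProfile <- function(profile, bedGraphPath = NULL, tsvPath = NULL) {
  stopifnot(is(profile, "RatioProfile"))
  profile <- sortProfile(profile)
  gr <- granges(rowRanges(profile))
  sm <- if (isSmoothed(profile)) smoothedRatio(profile) else
    rawRatio(profile)
  if (!is.null(bedGraphPath)) {
    out <- gr
    mcols(out)$score <- sm
    rtracklayer::export(out, bedGraphPath, format = "bedGraph")
  }
  if (!is.null(tsvPath)) {
    df <- data.frame(probe_id = mcols(rowRanges(profile))$id,
                     chrom = .chromOf(gr),
                     start = start(gr) - 1L, end = end(gr),
                     midpoint = mcols(rowRanges(profile))$midpoint,
                     raw_ratio = rawRatio(profile),
                     smoothed_ratio = if (isSmoothed(profile)) sm else NA)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bedGraph = bedGraphPath, tsv = tsvPath))
}

#' Read a profile TSV back into a RatioProfile
#'
#' @param path TSV written by \code{\link{exportProfile}}.
#' @param layout A \code{Seqinfo}.
#' @param windowBp Smoothing window recorded in the file's provenance
#'   (default 6000).
#' @return A \code{\link{RatioProfile}}.
#' @export
readProfile <- function(path, layout, windowBp = 6000) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "start", "end", "midpoint", "raw_ratio",
            "smoothed_ratio")
  if (!all(need %in% colnames(df)))
    stop("expected columns: ", paste(need, collapse = ", "))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end), seqinfo = layout)
  mcols(gr)$id <- as.character(df$probe_id)
  mcols(gr)$midpoint <- df$midpoint
  hasSm <- !anyNA(df$smoothed_ratio)
  assays <- list(raw = matrix(df$raw_ratio, ncol = 1,
                              dimnames = list(NULL, "profile")))
  md <- list(profileId = "profile")
  if (hasSm) {
    assays$smoothed <- matrix(df$smoothed_ratio, ncol = 1,
                              dimnames = list(NULL, "profile"))
    md$windowBp <- windowBp
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = gr, metadata = md)
  sortProfile(new("RatioProfile", se))
}

#' Export a SiteSet as BED with scores
#'
#' @param x A \code{\link{SiteSet}}.
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
exportSites <- function(x, path) {
  gr <- granges(x)
  df <- data.frame(chrom = .chromOf(gr), start = start(gr) - 1L,
                   end = end(gr),
                   name = sprintf("site_%d", seq_along(gr)),
                   score = mcols(gr)$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.CONFIG_DEFAULTS <- list(windowBp = 6000, cutoffBp = 6000, nSims = 10000,
                         rule = "above_median")

#' Read a run configuration from YAML
#'
#' Required keys: \code{layout} (chrom.sizes path), \code{samples} (named
#' list of sample TSV paths), \code{features} (named list
#' category -> BED path), \code{seed}, \code{outDir}. Optional keys with
#' defaults: \code{windowBp} 6000, \code{cutoffBp} 6000, \code{nSims}
#' 10000, \code{rule} "above_median", \code{columnMap}.
#'
#' @param path YAML path.
#' @return A validated named list of class \code{fragileMapConfig}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in names(.CONFIG_DEFAULTS))
    if (is.null(cfg[[k]])) cfg[[k]] <- .CONFIG_DEFAULTS[[k]]
  need <- c("layout", "samples", "seed", "outDir")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  if (!cfg$rule %in% c("above_median", "local_peak"))
    stop("rule must be 'above_median' or 'local_peak'")
  structure(cfg, class = "fragileMapConfig")
}

#' Write a run configuration to YAML
#'
#' @param cfg A config list.
#' @param path Output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
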