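#' Load a chromosome layout from a chrom.sizes file
#'
#' Reads a UCSC-style two-column text file (chromosome name, length in bp)
#' into a \code{Seqinfo} that defines the coordinate universe for all
#' downstream stages. File order is preserved as the iteration order.
#'
#' @param path Path to a whitespace-delimited chrom.sizes file.
#' @return A \code{\link[GenomeInfoDb]{Seqinfo}}.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrI\t230218", "chrII\t813184"), f)
#' loadLayout(f)
#' @export
loadLayout <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("layout file '", path, "' contains no chromosomes")
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("layout line ", bad[1L], " does not have two columns: '",
         lines[bad[1L]], "'")
  nm <- vapply(parts, `[[`, character(1), 1L)
  len <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(len) || any(len <= 0) || any(len != floor(len)))
    stop("chromosome lengths must be positive integers (line ",
         which(is.na(len) | len <= 0 | len != floor(len))[1L], ")")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: '", nm[duplicated(nm)][1L], "'")
  Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

# Synthesize a minimal BED-convention interval whose 0-based midpoint is m.
# Midpoints from BED intervals are always half-integral.
.intervalForMidpoint <- function(midpoint) {
  if (any(abs(midpoint * 2 - round(midpoint * 2)) > 1e-9))
    stop("midpoints must be half-integral (BED interval midpoints)")
  start0 <- ifelse(midpoint >= 1, ifelse(midpoint %% 1 == 0, midpoint - 1,
                                         midpoint - 0.5),
                   0)
  end0 <- 2 * midpoint - start0
  list(start0 = start0, end0 = end0)
}

#' Construct a FeatureSet from chromosome/midpoint vectors
#'
#' @param chrom Character vector of chromosome names (must exist in
#'   \code{layout}).
#' @param midpoint Numeric midpoints on the 0-based scale (half-integral).
#' @param category A single category for all features, or a vector; one of
#'   \code{checked_origin}, \code{unchecked_origin}, \code{centromere},
#'   \code{cut_site}, \code{other}.
#' @param layout A \code{Seqinfo} from \code{\link{loadLayout}}.
#' @param name Optional feature names; autogenerated when missing.
#' @return A \code{\link{FeatureSet}}.
#' @export
FeatureSet <- function(chrom, midpoint, category, layout, name = NULL) {
  category <- rep_len(as.character(category), length(chrom))
  if (!all(chrom %in% seqnames(layout)))
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(chrom, seqnames(layout))), collapse = ", "))
  if (is.null(name))
    name <- sprintf("%s_%d", category, seq_along(chrom))
  iv <- .intervalForMidpoint(midpoint)
  gr <- GRanges(chrom, IRanges(start = iv$start0 + 1, end = iv$end0),
                seqinfo = layout)
  mcols(gr)$midpoint <- as.numeric(midpoint)
  mcols(gr)$category <- category
  mcols(gr)$name <- name
  new("FeatureSet", features = gr)
}

#' Load point features from a BED file
#'
#' Reads a BED3/BED6 file, checks every interval against the layout, and
#' reduces each interval to its midpoint \code{(start + end) / 2} on the
#' 0-based scale. Distances to features are always measured midpoint to
#' midpoint downstream.
#'
#' @param path Path to a BED3+ file.
#' @param layout A \code{Seqinfo} from \code{\link{loadLayout}}.
#' @param category Category assigned to all features in the file.
#' @return A \code{\link{FeatureSet}}.
#' @export
loadFeatures <- function(path, layout,
                         category = c("other", "checked_origin",
                                      "unchecked_origin", "centromere",
                                      "cut_site")) {
  category <- match.arg(category)
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(seqnames(gr))
  bad <- which(!chrom %in% seqnames(layout))
  if (length(bad))
    stop("feature on unknown chromosome '", chrom[bad[1L]], "' at line ",
         bad[1L], " of ", path)
  lim <- seqlengths(layout)[chrom]
  if (length(gr) && any(end(gr) > lim))
    stop("feature beyond chromosome end at line ",
         which(end(gr) > lim)[1L], " of ", path)
  midpoint <- (start(gr) - 1 + end(gr)) / 2
  nm <- mcols(gr)$name
  if (is.null(nm) || all(is.na(nm)))
    nm <- sprintf("%s_%d", category, seq_along(gr))
  out <- GRanges(chrom, IRanges(start(gr), end(gr)), seqinfo = layout)
  mcols(out)$midpoint <- midpoint
  mcols(out)$category <- rep(category, length(out))
  mcols(out)$name <- nm
  new("FeatureSet", features = out)
}

#' Write a FeatureSet back to BED
#'
#' The stored intervals are exported unchanged, so
#' \code{loadFeatures(writeFeatures(x))} reproduces midpoints exactly.
#'
#' @param x A \code{\link{FeatureSet}}.
#' @param path Output BED path.
#' @return \code{path}, invisibly.
#' @export
writeFeatures <- function(x, path) {
  gr <- x@features
  out <- granges(gr)
  mcols(out)$name <- mcols(gr)$name
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Subset a FeatureSet by category
#'
#' @param x A \code{\link{FeatureSet}}.
#' @param category Categories to keep.
#' @return A \code{\link{FeatureSet}}.
#' @export
subsetByCategory <- function(x, category) {
  keep <- mcols(x@features)$category %in% category
  new("FeatureSet", features = x@features[keep])
}

#' @rdname FeatureSet-class
#' @export
setMethod("featureMidpoints", "FeatureSet",
          function(x) mcols(x@features)$midpoint)

#' @rdname FeatureSet-class
#' @export
setMethod("featureCategories", "FeatureSet",
          function(x) mcols(x@features)$category)

#' @rdname FeatureSet-class
#' @export
setMethod("granges", "FeatureSet", function(x, ...) x@features)

#' @rdname FeatureSet-class
#' @export
setMethod("length", "FeatureSet", function(x) length(x@features))

setMethod("show", "FeatureSet", function(object) {
  tab <- table(featureCategories(object))
  cat("FeatureSet with", length(object), "features (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
})
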