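# Run expr under a given RNG seed, restoring the caller's RNG state after.
# Seeds are explicit everywhere; no function touches global random state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Probe midpoints on the 0-based coordinate scale
#'
#' Probes are stored as \code{GRanges} (1-based, closed); files use BED
#' conventions (0-based, half-open). The midpoint of a probe occupying
#' 0-based \code{[start0, end0)} is \code{(start0 + end0) / 2}, a real
#' number.
#'
#' @param gr A \code{GRanges}.
#' @return Numeric vector of midpoints in bp.
#' @export
probeMidpoints <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

# Internal: chromosome names as character.
.chromOf <- function(gr) as.character(GenomicRanges::seqnames(gr))
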