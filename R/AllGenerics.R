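#' @rdname FeatureSet-class
#' @param x,object A package object.
#' @export
setGeneric("featureMidpoints", function(x) standardGeneric("featureMidpoints"))

#' @rdname FeatureSet-class
#' @export
setGeneric("featureCategories",
           function(x) standardGeneric("featureCategories"))

#' @rdname ArraySample-class
#' @export
setGeneric("probes", function(x) standardGeneric("probes"))

#' @rdname RatioProfile-class
#' @export
setGeneric("rawRatio", function(x) standardGeneric("rawRatio"))

#' @rdname RatioProfile-class
#' @export
setGeneric("smoothedRatio", function(x) standardGeneric("smoothedRatio"))

#' @rdname RatioProfile-class
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' @rdname SiteSet-class
#' @export
setGeneric("siteMidpoints", function(x) standardGeneric("siteMidpoints"))

#' @rdname SiteSet-class
#' @export
setGeneric("siteRule", function(x) standardGeneric("siteRule"))

#' @rdname SiteSet-class
#' @export
setGeneric("siteThreshold", function(x) standardGeneric("siteThreshold"))

#' Count sites with a feature within a midpoint-to-midpoint cutoff
#'
#' @param sites A \code{\link{SiteSet}} or a \code{GRanges} of site positions.
#' @param features A \code{\link{FeatureSet}}.
#' @param cutoffBp Inclusive distance cutoff in bp (default 6000, matching
#'   the smoothing window).
#' @return Integer count of sites whose nearest same-chromosome feature
#'   midpoint lies within \code{cutoffBp}.
#' @export
setGeneric("countWithin",
           function(sites, features, cutoffBp = 6000)
             standardGeneric("countWithin"))

#' Randomization test for site/feature proximity
#'
#' @inheritParams countWithin
#' @param probeUniverse \code{GRanges} of array probes (with a
#'   \code{flagged} metadata column; flagged probes are excluded from the
#'   null universe).
#' @param nSims Number of random site placements (default 10000).
#' @param seed Integer seed for the simulation draws.
#' @return An \code{\link{AssociationResult}}.
#' @export
setGeneric("randomSimulationTest",
           function(sites, features, probeUniverse, cutoffBp = 6000,
                    nSims = 10000, seed)
             standardGeneric("randomSimulationTest"))
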