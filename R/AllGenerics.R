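#' Modal fragment length of a size profile
#'
#' The length (bp) attaining the maximum count; ties resolve to the
#' smallest length. \code{NA} for an empty profile.
#'
#' @param x a \linkS4class{SizeProfile}.
#' @return numeric scalar (bp), or \code{NA}.
#' @examples
#' p <- sizeHistogramFromLengths(c(rep(166, 100), rep(144, 80)))
#' modalLength(p)
#' @export
setGeneric("modalLength", function(x) standardGeneric("modalLength"))

#' Mean fragment length of a size profile
#'
#' Arithmetic mean of fragment lengths within a window, computed from the
#' profile's integer counts.
#'
#' @param x a \linkS4class{SizeProfile}.
#' @param window integer length-2 window (bp); defaults to the profile's
#'   own 30--1000 bp window.
#' @return numeric scalar (bp), or \code{NA} when the window is empty.
#' @examples
#' meanLength(sizeHistogramFromLengths(c(100, 200)))
#' @export
setGeneric("meanLength", function(x, window = NULL) standardGeneric("meanLength"))

#' Per-length counts of a size profile
#' @param x a \linkS4class{SizeProfile}.
#' @return named integer vector (names are lengths in bp).
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' Total fragments in a size profile
#' @param x a \linkS4class{SizeProfile}.
#' @return integer scalar.
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' ctDNA fraction of an estimate
#' @param x a \linkS4class{CtdnaEstimate}.
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("ctdnaFraction", function(x) standardGeneric("ctdnaFraction"))

#' Mean variant allele frequency of an estimate
#' @param x a \linkS4class{CtdnaEstimate}.
#' @return numeric scalar in [0, 1].
#' @export
setGeneric("meanVaf", function(x) standardGeneric("meanVaf"))

#' Bootstrap confidence interval of a ctDNA estimate
#' @param x a \linkS4class{CtdnaEstimate}.
#' @return named numeric vector \code{c(level, lo, hi)}.
#' @export
setGeneric("ctdnaCI", function(x) standardGeneric("ctdnaCI"))

#' p-value accessor
#' @param x a result object with a p-value
#'   (\linkS4class{RegionGainTest}, \linkS4class{GroupComparison},
#'   \linkS4class{CorrelationResult}).
#' @return numeric scalar in (0, 1], or \code{NA} when undefined.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
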