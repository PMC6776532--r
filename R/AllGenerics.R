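#' @include AllClasses.R
NULL

#' Accessors for pairHiC classes
#'
#' \code{bins} returns the bin grid as a \code{GRanges}; \code{binSize} the
#' bin width in bp; \code{nbins} the number of bins; \code{channel} the
#' haplotype channel; \code{pixels} the sparse upper-triangular pixel table;
#' \code{balancingWeights} the per-bin balancing weights (\code{NA} =
#' masked); \code{binMask} the logical masked indicator; \code{isBalanced}
#' whether weights are present; \code{values} a track's per-bin values;
#' \code{trackKind} its kind; \code{boundaryBins} and \code{prominences}
#' the boundary positions and prominences; \code{regions} the region
#' ranges; \code{curveTable} a scaling curve as a \code{data.frame}.
#'
#' @param x a pairHiC object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("balancingWeights", function(x) standardGeneric("balancingWeights"))
#' @rdname accessors
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))
#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))
#' @rdname accessors
#' @export
setGeneric("boundaryBins", function(x) standardGeneric("boundaryBins"))
#' @rdname accessors
#' @export
setGeneric("prominences", function(x) standardGeneric("prominences"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))
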