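#' @import methods
#' @importFrom GenomicRanges GRanges seqnames tileGenome granges
#' @importFrom IRanges IRanges ranges width
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels
NULL

#' BinnedGenome: a uniform bin grid over a genome assembly
#'
#' Tiles every chromosome contiguously with fixed-size bins (0-based,
#' half-open coordinates; the last bin of a chromosome may be shorter).
#' Every bin carries a unique global integer index in genomic order; all
#' tracks, contact maps, boundary sets and region sets in this package
#' refer to bins through this grid.
#'
#' @slot bins a \code{GRanges} with one range per bin, in genomic order.
#' @slot binSize bin width in base pairs.
#' @export
setClass("BinnedGenome",
    representation(bins = "GRanges", binSize = "integer"))

setValidity("BinnedGenome", function(object) {
    b <- object@bins
    if (length(b) == 0L) return("empty bin grid")
    if (object@binSize < 1L) return("binSize must be >= 1")
    sl <- GenomeInfoDb::seqlengths(b)
    if (any(is.na(sl))) return("seqlengths must be set")
    # per-chromosome contiguous tiling
    for (chr in GenomeInfoDb::seqlevels(b)) {
        r <- IRanges::ranges(b[GenomicRanges::seqnames(b) == chr])
        if (length(r) == 0L) next
        st <- BiocGenerics::start(r); en <- BiocGenerics::end(r)
        if (st[1] != 1L) return("bins must start at chromosome start")
        if (length(r) > 1L && any(st[-1] != en[-length(en)] + 1L))
            return(sprintf("bins do not tile chromosome %s contiguously", chr))
        w <- en - st + 1L
        if (any(w[-length(w)] != object@binSize))
            return("all but the last bin per chromosome must have width binSize")
        if (en[length(en)] != sl[chr])
            return(sprintf("bins do not reach the end of chromosome %s", chr))
    }
    TRUE
})

#' ContactMap: a haplotype-channel binned contact matrix
#'
#' Sparse symmetric contact matrix on a \linkS4class{BinnedGenome} grid.
#' Pixels are stored upper-triangular (\code{bin1 <= bin2}, global 1-based
#' bin indices) and interpreted symmetrically. After balancing, per-bin
#' multiplicative weights are stored; a bin is masked if and only if its
#' weight is \code{NA}. The balanced value of pixel (i,j) is
#' \code{count * weight[i] * weight[j]}, missing when either bin is masked.
#'
#' @slot binTable the \linkS4class{BinnedGenome} grid.
#' @slot channel one of \code{"cis_maternal"}, \code{"cis_paternal"},
#'   \code{"cis_pooled"}, \code{"thom"}, \code{"reference_pooled"}.
#' @slot pixels \code{data.frame} with integer columns \code{bin1},
#'   \code{bin2} and numeric \code{count}.
#' @slot weights numeric vector of balancing weights (\code{NA} = masked);
#'   length zero before balancing.
#' @slot metadata list of provenance notes.
#' @export
setClass("ContactMap",
    representation(binTable = "BinnedGenome", channel = "character",
                   pixels = "data.frame", weights = "numeric",
                   metadata = "list"))

.CHANNELS <- c("cis_maternal", "cis_paternal", "cis_pooled", "thom",
               "reference_pooled")

setValidity("ContactMap", function(object) {
    if (!(object@channel %in% .CHANNELS))
        return(sprintf("unknown channel '%s'", object@channel))
    px <- object@pixels
    if (!all(c("bin1", "bin2", "count") %in% names(px)))
        return("pixels must have columns bin1, bin2, count")
    nb <- length(object@binTable@bins)
    if (nrow(px)) {
        if (any(px$bin1 > px$bin2)) return("pixels must be upper-triangular (bin1 <= bin2)")
        if (any(px$bin1 < 1L | px$bin2 > nb)) return("pixel bin index off the grid")
        if (any(px$count < 0)) return("counts must be non-negative")
    }
    w <- object@weights
    if (length(w) && length(w) != nb)
        return("weights must have one entry per bin")
    TRUE
})

#' ScoreTrack: one value per genomic bin
#'
#' A genome-wide per-bin score on a \linkS4class{BinnedGenome} grid.
#' Pairing score (PS), cis score (CS) and insulation values are in log2
#' contact-frequency units; other kinds are in arbitrary units.
#'
#' @slot binTable the bin grid.
#' @slot values numeric, one per bin (\code{NA} = missing).
#' @slot kind one of \code{"PS"}, \code{"CS"}, \code{"insulation"},
#'   \code{"eigenvector"}, \code{"expression"}, \code{"chip_enrichment"},
#'   \code{"gene_count"}, \code{"other"}.
#' @slot window window half-width in bins where applicable, else \code{NA}.
#' @slot channel source contact-map channel, or \code{NA}.
#' @export
setClass("ScoreTrack",
    representation(binTable = "BinnedGenome", values = "numeric",
                   kind = "character", window = "integer",
                   channel = "character"))

setValidity("ScoreTrack", function(object) {
    if (length(object@values) != length(object@binTable@bins))
        return("values must have one entry per bin")
    kinds <- c("PS", "CS", "insulation", "eigenvector", "expression",
               "chip_enrichment", "gene_count", "other")
    if (!(object@kind %in% kinds))
        return(sprintf("unknown track kind '%s'", object@kind))
    TRUE
})

#' GaussianMixtureFit: two-Gaussian deconvolution of the PS distribution
#'
#' @slot weights mixture proportions (sum to 1), ordered (loose, tight).
#' @slot means component means in log2 units, mu_loose < mu_tight.
#' @slot sds component standard deviations.
#' @slot clipFloor values below this floor were winsorized before fitting.
#' @slot threshold density-intersection threshold between the components.
#' @slot logLik final log-likelihood.
#' @slot converged whether EM met its tolerance within the iteration cap.
#' @slot flagged TRUE when the fit is unreliable (near-degenerate
#'   components or no density crossing between the means).
#' @slot nobs number of values fitted.
#' @export
setClass("GaussianMixtureFit",
    representation(weights = "numeric", means = "numeric", sds = "numeric",
                   clipFloor = "numeric", threshold = "numeric",
                   logLik = "numeric", converged = "logical",
                   flagged = "logical", nobs = "integer"))

setValidity("GaussianMixtureFit", function(object) {
    if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-8)
        return("weights must be two proportions summing to 1")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (any(object@sds <= 0)) return("sds must be positive")
    if (object@means[1] > object@means[2])
        return("components must be ordered mu_loose < mu_tight")
    TRUE
})

#' BoundarySet: insulation-score boundaries
#'
#' @slot binTable the bin grid.
#' @slot bins sorted global bin indices of boundary bins.
#' @slot prominence per-boundary prominence (log2 units).
#' @slot cutoff prominence cutoff used for the calls.
#' @slot channel source channel of the insulation track.
#' @export
setClass("BoundarySet",
    representation(binTable = "BinnedGenome", bins = "integer",
                   prominence = "numeric", cutoff = "numeric",
                   channel = "character"))

setValidity("BoundarySet", function(object) {
    if (length(object@bins) != length(object@prominence))
        return("bins and prominence must align")
    if (is.unsorted(object@bins, strictly = TRUE))
        return("boundary bins must be strictly increasing")
    if (length(object@prominence) && any(object@prominence < object@cutoff - 1e-12))
        return("all prominences must be >= cutoff")
    TRUE
})

#' PairingRegionSet: boundary-delimited tight/loose regions
#'
#' Intervals between consecutive insulating boundaries (chromosome ends act
#' as implicit boundaries), each labeled tight or loose by the fraction of
#' loosely paired bins it contains, then merged across same-labeled
#' boundary bins.
#'
#' @slot binTable the bin grid.
#' @slot regions \code{GRanges}, sorted and non-overlapping, with metadata
#'   columns \code{label} (tight/loose/missing) and \code{looseFraction}.
#' @slot cutoff loose-bin fraction at or above which a region is loose.
#' @export
setClass("PairingRegionSet",
    representation(binTable = "BinnedGenome", regions = "GRanges",
                   cutoff = "numeric"))

setValidity("PairingRegionSet", function(object) {
    mc <- S4Vectors::mcols(object@regions)
    if (!all(c("label", "looseFraction") %in% names(mc)))
        return("regions need label and looseFraction columns")
    if (!all(mc$label %in% c("tight", "loose", "missing")))
        return("labels must be tight/loose/missing")
    TRUE
})

#' ScalingCurve: contact frequency vs genomic separation
#'
#' Log-binned average contact frequency P(s). Default edges span 10 bp to
#' 10 Mb with eight ranges per order of magnitude (48 ranges).
#'
#' @slot edges separation range edges in bp, strictly increasing.
#' @slot s representative separation per range (geometric mean of edges).
#' @slot P mean contact frequency per range (\code{NA} where no pairs).
#' @slot npairs number of contributing locus pairs per range.
#' @slot channel source channel.
#' @slot regionClass \code{"all"}, \code{"tight"} or \code{"loose"}.
#' @export
setClass("ScalingCurve",
    representation(edges = "numeric", s = "numeric", P = "numeric",
                   npairs = "numeric", channel = "character",
                   regionClass = "character"))

setValidity("ScalingCurve", function(object) {
    ne <- length(object@edges)
    if (is.unsorted(object@edges, strictly = TRUE))
        return("edges must be strictly increasing")
    if (length(object@P) != ne - 1L || length(object@s) != ne - 1L ||
        length(object@npairs) != ne - 1L)
        return("P, s and npairs must have one entry per range")
    if (any(object@P < 0, na.rm = TRUE)) return("P must be non-negative")
    TRUE
})
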