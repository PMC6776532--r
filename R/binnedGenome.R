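#' @include AllGenerics.R
NULL

#' Build a uniform bin grid over a genome
#'
#' Tiles each chromosome with fixed-size bins in the BED convention
#' (0-based, half-open intervals; internally stored as 1-based
#' \code{GRanges}). The last bin per chromosome may be shorter than
#' \code{binSize}.
#'
#' @param chromSizes named integer vector of chromosome lengths in bp, or
#'   the path to a two-column (chrom, length) tab-separated file.
#' @param binSize bin width in bp.
#' @return a \linkS4class{BinnedGenome}.
#' @examples
#' bg <- binnedGenome(c(chr1 = 20000), binSize = 4000)
#' nbins(bg)
#' @export
binnedGenome <- function(chromSizes, binSize) {
    if (is.character(chromSizes) && length(chromSizes) == 1L) {
        tab <- utils::read.table(chromSizes, sep = "\t", header = FALSE,
                                 col.names = c("chrom", "length"),
                                 stringsAsFactors = FALSE)
        chromSizes <- stats::setNames(as.integer(tab$length), tab$chrom)
    }
    if (is.null(names(chromSizes)) || any(!nzchar(names(chromSizes))))
        stop("chromSizes must be named by chromosome")
    binSize <- as.integer(binSize)
    si <- GenomeInfoDb::Seqinfo(seqnames = names(chromSizes),
                                seqlengths = as.integer(chromSizes))
    gr <- GenomicRanges::tileGenome(si, tilewidth = binSize,
                                    cut.last.tile.in.chrom = TRUE)
    new("BinnedGenome", bins = gr, binSize = binSize)
}

#' @rdname accessors
#' @export
setMethod("bins", "BinnedGenome", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("binSize", "BinnedGenome", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("nbins", "BinnedGenome", function(x) length(x@bins))

setMethod("show", "BinnedGenome", function(object) {
    sl <- GenomeInfoDb::seqlengths(object@bins)
    cat(sprintf("BinnedGenome: %d bins of %d bp over %d chromosome(s)\n",
                length(object@bins), object@binSize, length(sl)))
    cat("  ", paste(sprintf("%s (%d bp)", names(sl), sl), collapse = ", "),
        "\n", sep = "")
})

# Global-index span of every chromosome: data.frame(chrom, from, to, n).
.chromSpans <- function(bt) {
    rl <- S4Vectors::runLength(GenomicRanges::seqnames(bt@bins))
    rv <- as.character(S4Vectors::runValue(GenomicRanges::seqnames(bt@bins)))
    to <- cumsum(rl)
    data.frame(chrom = rv, from = to - rl + 1L, to = to, n = rl,
               stringsAsFactors = FALSE)
}

# Map (chrom, 0-based start) to global bin index; NA when off the grid.
.binIndexOf <- function(bt, chrom, start0) {
    sp <- .chromSpans(bt)
    m <- match(chrom, sp$chrom)
    local <- start0 %/% bt@binSize + 1L
    ok <- !is.na(m) & start0 >= 0L & (start0 %% bt@binSize == 0L) &
        local <= sp$n[m]
    out <- rep(NA_integer_, length(chrom))
    out[ok] <- sp$from[m[ok]] + local[ok] - 1L
    out
}

.sameGrid <- function(a, b) {
    identical(GenomeInfoDb::seqlengths(a@bins), GenomeInfoDb::seqlengths(b@bins)) &&
        a@binSize == b@binSize
}
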