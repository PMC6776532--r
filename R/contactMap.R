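#' @include binnedGenome.R
NULL

#' Construct a ContactMap from a pixel table
#'
#' Pixels may be given in any orientation; they are folded into the upper
#' triangle (\code{bin1 <= bin2}) and duplicate pixels are summed. For the
#' trans-homolog (thom) channel, maternal-to-paternal and
#' paternal-to-maternal contacts are experimentally indistinguishable in
#' aggregate, so the matrix is stored on the single reference bin grid and
#' symmetrized by folding.
#'
#' @param binTable a \linkS4class{BinnedGenome}.
#' @param pixels data.frame with columns \code{bin1}, \code{bin2} (global
#'   1-based bin indices) and \code{count}.
#' @param channel channel label (see \linkS4class{ContactMap}).
#' @param weights optional per-bin balancing weights.
#' @return a \linkS4class{ContactMap}.
#' @export
contactMap <- function(binTable, pixels, channel = "reference_pooled",
                       weights = numeric(0)) {
    stopifnot(is(binTable, "BinnedGenome"))
    pixels <- .foldPixels(pixels)
    new("ContactMap", binTable = binTable, channel = channel,
        pixels = pixels, weights = as.numeric(weights), metadata = list())
}

.foldPixels <- function(px) {
    b1 <- pmin.int(px$bin1, px$bin2)
    b2 <- pmax.int(px$bin1, px$bin2)
    key <- paste(b1, b2)
    if (anyDuplicated(key)) {
        cnt <- rowsum(as.numeric(px$count), key, reorder = FALSE)
        first <- !duplicated(key)
        out <- data.frame(bin1 = b1[first], bin2 = b2[first],
                          count = as.numeric(cnt[match(key[first], rownames(cnt)), 1L]))
    } else {
        out <- data.frame(bin1 = b1, bin2 = b2, count = as.numeric(px$count))
    }
    out <- out[order(out$bin1, out$bin2), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Read a contact map from a TSV triplet file
#'
#' Expects tab-separated columns \code{chrom1, start1, chrom2, start2,
#' count} with 0-based bin starts on the declared grid. Rows are folded
#' into the upper triangle; duplicate pixels are summed.
#'
#' @param path file location.
#' @param binTable the \linkS4class{BinnedGenome} the file must conform to.
#' @param channel channel label.
#' @return a \linkS4class{ContactMap}.
#' @export
readContactMap <- function(path, binTable, channel = "reference_pooled") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom1", "start1", "chrom2",
                                           "start2", "count"),
                             stringsAsFactors = FALSE)
    if (nrow(tab) && any(tab$count < 0))
        stop(sprintf("negative count in record %d of %s",
                     which(tab$count < 0)[1], path))
    b1 <- .binIndexOf(binTable, tab$chrom1, as.integer(tab$start1))
    b2 <- .binIndexOf(binTable, tab$chrom2, as.integer(tab$start2))
    bad <- which(is.na(b1) | is.na(b2))
    if (length(bad))
        stop(sprintf("record %d of %s is off the bin grid: %s:%d - %s:%d",
                     bad[1], path, tab$chrom1[bad[1]], tab$start1[bad[1]],
                     tab$chrom2[bad[1]], tab$start2[bad[1]]))
    contactMap(binTable,
               data.frame(bin1 = b1, bin2 = b2, count = tab$count),
               channel = channel)
}

#' Write a contact map as a TSV triplet file
#'
#' Inverse of \code{\link{readContactMap}}. Balancing weights, if present,
#' are written alongside as \code{<path>.weights.tsv} (chrom, start, end,
#' weight; \code{NA} for masked bins).
#'
#' @param map a \linkS4class{ContactMap}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeContactMap <- function(map, path) {
    bt <- map@binTable
    b <- bt@bins
    st0 <- BiocGenerics::start(b) - 1L
    chr <- as.character(GenomicRanges::seqnames(b))
    px <- map@pixels
    out <- data.frame(chrom1 = chr[px$bin1], start1 = st0[px$bin1],
                      chrom2 = chr[px$bin2], start2 = st0[px$bin2],
                      count = px$count)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (length(map@weights)) {
        wout <- data.frame(chrom = chr, start = st0,
                           end = BiocGenerics::end(b), weight = map@weights)
        utils::write.table(wout, paste0(path, ".weights.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    invisible(path)
}

#' @rdname accessors
#' @export
setMethod("bins", "ContactMap", function(x) x@binTable@bins)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMap", function(x) x@binTable@binSize)
#' @rdname accessors
#' @export
setMethod("nbins", "ContactMap", function(x) length(x@binTable@bins))
#' @rdname accessors
#' @export
setMethod("channel", "ContactMap", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("pixels", "ContactMap", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("balancingWeights", "ContactMap", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("isBalanced", "ContactMap", function(x) length(x@weights) > 0L)
#' @rdname accessors
#' @export
setMethod("binMask", "ContactMap", function(x) {
    if (!isBalanced(x)) rep(FALSE, nbins(x)) else is.na(x@weights)
})

setMethod("show", "ContactMap", function(object) {
    cat(sprintf("ContactMap [%s]: %d bins (%d bp), %d pixels, sum %.4g%s\n",
                object@channel, nbins(object), binSize(object),
                nrow(object@pixels), sum(object@pixels$count),
                if (isBalanced(object))
                    sprintf(", balanced (%d masked bins)",
                            sum(is.na(object@weights)))
                else ", unbalanced"))
})

#' Pool contact maps bin-wise
#'
#' Sums the raw counts of maps on the same grid, e.g. to form the
#' \code{cis_pooled} or \code{reference_pooled} channel. Weights are
#' dropped; re-balance the pooled map.
#'
#' @param maps list of \linkS4class{ContactMap}s on one grid.
#' @param channel channel label of the result.
#' @return a \linkS4class{ContactMap}.
#' @export
poolMaps <- function(maps, channel = "reference_pooled") {
    stopifnot(length(maps) >= 1L)
    bt <- maps[[1]]@binTable
    for (m in maps[-1]) {
        if (!.sameGrid(bt, m@binTable)) stop("maps are not on the same grid")
    }
    px <- do.call(rbind, lapply(maps, function(m) m@pixels))
    contactMap(bt, px, channel = channel)
}

#' Coarsen a contact map to a larger bin size
#'
#' Aggregates counts into bins of \code{factor} times the current size
#' (for, e.g., compartment analysis at a coarser scale). Weights are
#' dropped.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param factor integer coarsening factor.
#' @return a \linkS4class{ContactMap} on the coarser grid.
#' @export
coarsenMap <- function(map, factor) {
    factor <- as.integer(factor)
    stopifnot(factor >= 1L)
    if (factor == 1L) return(map)
    bt <- map@binTable
    sl <- GenomeInfoDb::seqlengths(bt@bins)
    bt2 <- binnedGenome(sl, bt@binSize * factor)
    b <- bt@bins
    chr <- as.character(GenomicRanges::seqnames(b))
    st0 <- BiocGenerics::start(b) - 1L
    coarse0 <- (st0 %/% (bt@binSize * factor)) * (bt@binSize * factor)
    newIdx <- .binIndexOf(bt2, chr, coarse0)
    px <- map@pixels
    contactMap(bt2, data.frame(bin1 = newIdx[px$bin1], bin2 = newIdx[px$bin2],
                               count = px$count), channel = map@channel)
}

# Dense per-chromosome matrix of raw or balanced values.
# Balanced: NA on masked rows/columns, zero elsewhere without a pixel.
.denseChromMatrix <- function(map, chrom, balanced = TRUE) {
    sp <- .chromSpans(map@binTable)
    row <- sp[sp$chrom == chrom, ]
    if (nrow(row) != 1L) stop(sprintf("unknown chromosome '%s'", chrom))
    n <- row$n
    px <- map@pixels
    keep <- px$bin1 >= row$from & px$bin2 <= row$to & px$bin2 >= row$from &
        px$bin1 <= row$to
    px <- px[keep, , drop = FALSE]
    i <- px$bin1 - row$from + 1L
    j <- px$bin2 - row$from + 1L
    A <- matrix(0, n, n)
    val <- px$count
    if (balanced) {
        if (!isBalanced(map)) stop("map is not balanced")
        w <- map@weights[row$from:row$to]
        val <- val * w[i] * w[j]
    }
    A[cbind(i, j)] <- val
    A[cbind(j, i)] <- val
    if (balanced) {
        bad <- which(is.na(map@weights[row$from:row$to]))
        A[bad, ] <- NA_real_
        A[, bad] <- NA_real_
    }
    A
}

# Per-chromosome diagonal vectors of the (optionally balanced) matrix:
# a list over lags 0..maxLag; element k+1 is the vector d_k with
# d_k[i] = A[i, i+k] (local indices), 0 where no pixel, NA never (mask is
# handled by the caller through the valid vector).
.chromDiagVals <- function(map, from, to, maxLag, balanced = TRUE) {
    n <- to - from + 1L
    px <- map@pixels
    keep <- px$bin1 >= from & px$bin1 <= to & px$bin2 <= to &
        (px$bin2 - px$bin1) <= maxLag
    px <- px[keep, , drop = FALSE]
    val <- px$count
    if (balanced) {
        w <- map@weights
        val <- val * w[px$bin1] * w[px$bin2]
        val[is.na(val)] <- 0
    }
    lag <- px$bin2 - px$bin1
    i <- px$bin1 - from + 1L
    out <- vector("list", maxLag + 1L)
    for (k in 0:maxLag) {
        v <- numeric(max(n - k, 0L))
        sel <- lag == k
        if (any(sel)) v[i[sel]] <- val[sel]
        out[[k + 1L]] <- v
    }
    out
}

# Per-chromosome per-diagonal sums of observed values and counts of
# unmasked pairs, for lags 1..(n-1). Returns list(sumVal, nPairs).
.diagSums <- function(map, from, to, balanced = TRUE, restrict = NULL) {
    n <- to - from + 1L
    px <- map@pixels
    keep <- px$bin1 >= from & px$bin2 <= to & px$bin1 < px$bin2
    px <- px[keep, , drop = FALSE]
    valid <- rep(TRUE, n)
    if (isBalanced(map)) valid <- !is.na(map@weights[from:to])
    if (!is.null(restrict)) valid <- valid & restrict
    val <- px$count
    if (balanced) {
        w <- map@weights
        val <- val * w[px$bin1] * w[px$bin2]
    }
    iloc <- px$bin1 - from + 1L
    jloc <- px$bin2 - from + 1L
    ok <- valid[iloc] & valid[jloc]
    if (!is.null(restrict)) ok <- ok   # restrict already folded into valid
    lag <- jloc[ok] - iloc[ok]
    sumVal <- numeric(n - 1L)
    if (length(lag)) {
        agg <- rowsum(val[ok], lag)
        sumVal[as.integer(rownames(agg))] <- agg[, 1L]
    }
    nPairs <- .lagPairCounts(valid)
    list(sumVal = sumVal, nPairs = nPairs)
}

# Number of unmasked bin pairs at each lag 1..(n-1), via FFT
# autocorrelation of the validity indicator.
.lagPairCounts <- function(valid) {
    n <- length(valid)
    if (n < 2L) return(numeric(0))
    if (all(valid)) return(as.numeric((n - 1L):1L))
    v <- as.numeric(valid)
    ac <- stats::convolve(v, rev(v), type = "open")
    round(ac[(n + 1L):(2L * n - 1L)])
}
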