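#' @include contactMap.R tracks.R
NULL

#' Diamond insulation score
#'
#' For every bin i, the raw score is the total balanced contact frequency
#' formed across that bin by pairs of bins on either side, up to \code{w}
#' bins away: pairs (a, b) with a in [i-w, i-1] and b in [i+1, i+w] (the
#' central bin itself is excluded). The track is
#' log2(raw / genome-wide median of raw). Values are missing within
#' \code{w} bins of a chromosome end and where the central bin or any flank
#' bin of the diamond is masked.
#'
#' @param map a balanced \linkS4class{ContactMap}.
#' @param w flank width in bins (default 5).
#' @return a \linkS4class{ScoreTrack} of kind \code{"insulation"}.
#' @export
insulationScore <- function(map, w = 5L) {
    if (!isBalanced(map)) stop("map must be balanced first")
    w <- as.integer(w)
    stopifnot(w >= 1L)
    sp <- .chromSpans(map@binTable)
    nb <- nbins(map)
    raw <- rep(NA_real_, nb)
    for (r in seq_len(nrow(sp))) {
        n <- sp$n[r]
        if (n < 2L * w + 1L) {
            warning(sprintf("chromosome %s shorter than the diamond; skipped",
                            sp$chrom[r]))
            next
        }
        validv <- !is.na(map@weights[sp$from[r]:sp$to[r]])
        dv <- .chromDiagVals(map, sp$from[r], sp$to[r], maxLag = 2L * w,
                             balanced = TRUE)
        S <- numeric(n)
        allValid <- rep(TRUE, n)
        for (p in 1:w) {
            for (q in 1:w) {
                k <- p + q                       # lag of pair (i-p, i+q)
                i <- (w + 1L):(n - w)
                S[i] <- S[i] + dv[[k + 1L]][i - p]
            }
        }
        for (off in (-w):w) {
            i <- (w + 1L):(n - w)
            allValid[i] <- allValid[i] & validv[i + off]
        }
        S[!allValid] <- NA_real_
        S[c(seq_len(w), (n - w + 1L):n)] <- NA_real_
        raw[sp$from[r]:sp$to[r]] <- S
    }
    med <- stats::median(raw, na.rm = TRUE)
    if (!is.finite(med) || med <= 0)
        stop("insulation median is not positive; cannot normalize")
    vals <- log2(raw / med)
    vals[!is.finite(vals)] <- NA_real_
    scoreTrack(map@binTable, vals, kind = "insulation", window = w,
               channel = map@channel)
}

# Alternating-extrema peak detection (peakdet-style): a minimum is
# registered when the series has risen by more than delta since the
# running minimum, symmetrically for maxima. Returns minima positions with
# prominence = the smaller rise to the flanking detected maxima (local
# maxima at the segment ends count as flanks).
.peakdetMinima <- function(v, delta) {
    n <- length(v)
    mins <- integer(0); maxs <- integer(0)
    mn <- Inf; mx <- -Inf; mnpos <- NA_integer_; mxpos <- NA_integer_
    lookForMax <- NA   # undecided until the first swing of size delta
    for (i in seq_len(n)) {
        if (v[i] > mx) { mx <- v[i]; mxpos <- i }
        if (v[i] < mn) { mn <- v[i]; mnpos <- i }
        if (is.na(lookForMax)) {
            if (v[i] < mx - delta) { lookForMax <- FALSE; mn <- v[i]; mnpos <- i }
            else if (v[i] > mn + delta) { lookForMax <- TRUE; mx <- v[i]; mxpos <- i }
        } else if (lookForMax) {
            if (v[i] < mx - delta) {
                maxs <- c(maxs, mxpos)
                mn <- v[i]; mnpos <- i; lookForMax <- FALSE
            }
        } else {
            if (v[i] > mn + delta) {
                mins <- c(mins, mnpos)
                mx <- v[i]; mxpos <- i; lookForMax <- TRUE
            }
        }
    }
    if (!length(mins)) return(data.frame(pos = integer(0), prom = numeric(0)))
    # flanking maxima for prominence; segment-edge maxima serve as flanks
    prom <- numeric(length(mins))
    for (k in seq_along(mins)) {
        m <- mins[k]
        left <- maxs[maxs < m]
        right <- maxs[maxs > m]
        leftVal <- if (length(left)) v[max(left)] else max(v[seq_len(m)])
        rightVal <- if (length(right)) v[min(right)] else max(v[m:n])
        prom[k] <- min(leftVal, rightVal) - v[m]
    }
    data.frame(pos = mins, prom = prom)
}

#' Detect insulating boundaries
#'
#' Local minima of the insulation track are found by alternating-extrema
#' peak detection (detection delta = \code{minProminence}/2) and kept when
#' their prominence - the smaller of the rises to the flanking detected
#' maxima - reaches \code{minProminence}. Boundaries whose bin or either
#' immediate neighbor is masked are removed. Default cutoffs: 0.3 for the
#' haplotype-resolved channels (cis and thom), 0.1 for the reference
#' channel.
#'
#' @param track an insulation \linkS4class{ScoreTrack}.
#' @param minProminence prominence cutoff in log2 units (\code{NULL}:
#'   channel default as above).
#' @param mask optional logical per-bin mask of excluded bins (defaults to
#'   the track's missing bins at chromosome interiors).
#' @return a \linkS4class{BoundarySet}.
#' @export
findBoundaries <- function(track, minProminence = NULL, mask = NULL) {
    if (track@kind != "insulation") stop("track must be an insulation track")
    if (is.null(minProminence))
        minProminence <- if (identical(track@channel, "reference_pooled"))
            0.1 else 0.3
    bt <- track@binTable
    sp <- .chromSpans(bt)
    v <- track@values
    if (is.null(mask)) mask <- rep(FALSE, length(v))
    pos <- integer(0); prom <- numeric(0)
    for (r in seq_len(nrow(sp))) {
        vv <- v[sp$from[r]:sp$to[r]]
        # scan maximal runs of defined values independently
        ok <- !is.na(vv)
        if (!any(ok)) next
        runs <- rle(ok)
        hi <- cumsum(runs$lengths); lo <- hi - runs$lengths + 1L
        for (seg in which(runs$values)) {
            idx <- lo[seg]:hi[seg]
            det <- .peakdetMinima(vv[idx], delta = minProminence / 2)
            keep <- det$prom >= minProminence
            pos <- c(pos, sp$from[r] + idx[det$pos[keep]] - 1L)
            prom <- c(prom, det$prom[keep])
        }
    }
    # remove boundaries adjacent to masked bins
    if (length(pos)) {
        nb <- length(v)
        bad <- mask[pos] |
            mask[pmax(pos - 1L, 1L)] | mask[pmin(pos + 1L, nb)]
        pos <- pos[!bad]; prom <- prom[!bad]
    }
    ord <- order(pos)
    new("BoundarySet", binTable = bt, bins = pos[ord],
        prominence = prom[ord], cutoff = minProminence,
        channel = track@channel)
}

#' @rdname accessors
#' @export
setMethod("boundaryBins", "BoundarySet", function(x) x@bins)
#' @rdname accessors
#' @export
setMethod("prominences", "BoundarySet", function(x) x@prominence)

setMethod("show", "BoundarySet", function(object) {
    cat(sprintf("BoundarySet [%s]: %d boundaries at prominence >= %.2f\n",
                object@channel, length(object@bins), object@cutoff))
})

#' Fraction of boundaries reproduced in another boundary set
#'
#' A boundary of set \code{a} is matched when a boundary of \code{b} on the
#' same chromosome lies within \code{tolerance} bins (inclusive); matching
#' is greedy nearest-first and one-to-one (no boundary is reused). The
#' default tolerance of 4 bins (16 kb at 4 kb resolution) absorbs the
#' positional drift caused by the stochasticity of contact maps.
#'
#' @param a,b \linkS4class{BoundarySet}s on the same grid.
#' @param tolerance positional tolerance in bins (default 4).
#' @return list with \code{fractionA} (fraction of a's boundaries matched
#'   in b), \code{fractionB} (the symmetric fraction), \code{nMatched},
#'   and a \code{flagged} marker when either set is empty (fractions then
#'   \code{NA}).
#' @export
boundaryOverlap <- function(a, b, tolerance = 4L) {
    if (!.sameGrid(a@binTable, b@binTable))
        stop("boundary sets are not on the same grid")
    na <- length(a@bins); nb <- length(b@bins)
    if (na == 0L || nb == 0L)
        return(list(fractionA = NA_real_, fractionB = NA_real_,
                    nMatched = 0L, flagged = TRUE))
    sp <- .chromSpans(a@binTable)
    chromOf <- function(x) findInterval(x, sp$from)
    ca <- chromOf(a@bins); cb <- chromOf(b@bins)
    pairs <- expand.grid(i = seq_len(na), j = seq_len(nb))
    pairs$d <- abs(a@bins[pairs$i] - b@bins[pairs$j])
    pairs <- pairs[ca[pairs$i] == cb[pairs$j] & pairs$d <= tolerance, ,
                   drop = FALSE]
    pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
    usedA <- logical(na); usedB <- logical(nb); nm <- 0L
    for (k in seq_len(nrow(pairs))) {
        i <- pairs$i[k]; j <- pairs$j[k]
        if (!usedA[i] && !usedB[j]) {
            usedA[i] <- TRUE; usedB[j] <- TRUE; nm <- nm + 1L
        }
    }
    list(fractionA = nm / na, fractionB = nm / nb, nMatched = nm,
         flagged = FALSE)
}

#' Fraction of boundaries overlapping an interval set
#'
#' A boundary overlaps when its bin interval [start, end) intersects at
#' least one interval (e.g. ChIP-seq peaks).
#'
#' @param boundarySet a \linkS4class{BoundarySet}.
#' @param peaks a \code{GRanges} of intervals on the same assembly.
#' @return the overlap fraction (\code{NA} for an empty boundary set).
#' @export
intervalOverlapFraction <- function(boundarySet, peaks) {
    if (!length(boundarySet@bins)) return(NA_real_)
    gr <- boundarySet@binTable@bins[boundarySet@bins]
    hits <- GenomicRanges::countOverlaps(gr, peaks)
    mean(hits > 0)
}

#' Write a BoundarySet as BED (prominence in the score column)
#'
#' @param boundarySet a \linkS4class{BoundarySet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeBoundariesBed <- function(boundarySet, path) {
    gr <- boundarySet@binTable@bins[boundarySet@bins]
    out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1L,
                      end = BiocGenerics::end(gr),
                      name = "boundary",
                      score = boundarySet@prominence)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
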