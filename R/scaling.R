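#' @include contactMap.R tracks.R
NULL

#' Default geometric separation bins: 10 bp to 10 Mb, eight per decade
#'
#' @return numeric vector of 49 edges delimiting 48 separation ranges.
#' @export
defaultScalingEdges <- function() 10^seq(1, 7, by = 1 / 8)

.curveS <- function(edges) sqrt(edges[-length(edges)] * edges[-1])

#' Contact frequency vs genomic separation
#'
#' For each separation range [lo, hi), P(s) is the sum of observed pixel
#' values at separations in the range divided by the number of unmasked
#' locus pairs at those separations. Separations are computed on the bin
#' grid as the distance between bin starts; the main diagonal (s = 0)
#' contributes to no range.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param edges separation range edges in bp
#'   (default \code{\link{defaultScalingEdges}}).
#' @param use \code{"balanced"} (default; requires weights) or \code{"raw"}.
#' @return a \linkS4class{ScalingCurve}.
#' @export
contactFrequencyCurve <- function(map, edges = defaultScalingEdges(),
                                  use = c("balanced", "raw")) {
    use <- match.arg(use)
    if (use == "balanced" && !isBalanced(map))
        stop("map must be balanced (or pass use = 'raw')")
    agg <- .aggregateDiagSums(map, edges, use, restrictClass = NULL)
    new("ScalingCurve", edges = edges, s = .curveS(edges),
        P = agg$P, npairs = agg$npairs, channel = map@channel,
        regionClass = "all")
}

# Shared kernel: per-chromosome per-diagonal sums aggregated into ranges.
# restrictClass: NULL, or list(regions = <list of local index vectors keyed
# by chrom>, spans handled by caller).
.aggregateDiagSums <- function(map, edges, use, restrictClass = NULL) {
    sp <- .chromSpans(map@binTable)
    nr <- length(edges) - 1L
    sumV <- numeric(nr); nP <- numeric(nr)
    bs <- binSize(map)
    for (r in seq_len(nrow(sp))) {
        n <- sp$n[r]
        if (n < 2L) next
        addSegment <- function(from, to, restrict = NULL) {
            ds <- .diagSums(map, from, to, balanced = (use == "balanced"),
                            restrict = restrict)
            nd <- length(ds$nPairs)
            if (!nd) return()
            sbp <- seq_len(nd) * bs
            rng <- findInterval(sbp, edges, left.open = FALSE)
            ok <- rng >= 1L & rng <= nr & sbp < edges[nr + 1L]
            if (!any(ok)) return()
            sv <- rowsum(ds$sumVal[ok], rng[ok])
            np <- rowsum(ds$nPairs[ok], rng[ok])
            idx <- as.integer(rownames(sv))
            sumV[idx] <<- sumV[idx] + sv[, 1L]
            nP[idx] <<- nP[idx] + np[, 1L]
        }
        if (is.null(restrictClass)) {
            addSegment(sp$from[r], sp$to[r])
        } else {
            regs <- restrictClass[[sp$chrom[r]]]
            for (reg in regs)  # pairs must lie within the same region
                addSegment(sp$from[r] + reg[1L] - 1L,
                           sp$from[r] + reg[2L] - 1L)
        }
    }
    list(P = ifelse(nP > 0, sumV / nP, NA_real_), npairs = nP)
}

#' Normalize a scaling curve to a reference value
#'
#' Divides all P values by the reference curve's value at the range
#' containing the reference separation (e.g. to normalize cis and thom
#' curves jointly to the cis frequency at the smallest separation).
#'
#' @param curve the \linkS4class{ScalingCurve} to normalize.
#' @param reference the curve supplying the reference value (defaults to
#'   \code{curve} itself).
#' @param separation reference separation in bp (default: the smallest
#'   range with a value).
#' @return the normalized \linkS4class{ScalingCurve}.
#' @export
normalizeCurve <- function(curve, reference = curve, separation = NULL) {
    if (!identical(curve@edges, reference@edges))
        stop("curve and reference must share edges")
    P <- reference@P
    if (is.null(separation)) {
        k <- which(!is.na(P))[1]
    } else {
        k <- findInterval(separation, reference@edges, left.open = FALSE)
    }
    if (is.na(k) || k < 1L || k > length(P) || is.na(P[k]))
        stop("reference range has no value")
    out <- curve
    out@P <- curve@P / P[k]
    out
}

#' Ratio of two scaling curves (e.g. P_thom(s) / P_cis(s))
#'
#' @param num,den \linkS4class{ScalingCurve}s with identical edges.
#' @return a \linkS4class{ScalingCurve} of element-wise ratios; missing
#'   where either input is missing.
#' @export
ratioCurve <- function(num, den) {
    if (!identical(num@edges, den@edges)) stop("curves must share edges")
    out <- num
    out@P <- ifelse(!is.na(num@P) & !is.na(den@P) & den@P > 0,
                    num@P / den@P, NA_real_)
    out@channel <- paste0(num@channel, "/", den@channel)
    out@npairs <- pmin(num@npairs, den@npairs)
    out
}

#' Region-restricted scaling curves
#'
#' Computes P(s) separately within tightly and loosely paired regions;
#' pairs contribute only when both bins fall in the same region of the
#' given class.
#'
#' @param map a \linkS4class{ContactMap}.
#' @param regionSet a \linkS4class{PairingRegionSet} on the same grid.
#' @param edges separation range edges in bp.
#' @param use \code{"balanced"} or \code{"raw"}.
#' @return named list of \linkS4class{ScalingCurve}s for classes
#'   \code{tight} and \code{loose} (\code{NULL} with a warning for an
#'   empty class).
#' @export
regionRestrictedCurves <- function(map, regionSet,
                                   edges = defaultScalingEdges(),
                                   use = c("balanced", "raw")) {
    use <- match.arg(use)
    if (!.sameGrid(map@binTable, regionSet@binTable))
        stop("regions are not on the map's bin grid")
    sp <- .chromSpans(map@binTable)
    out <- list()
    for (cls in c("tight", "loose")) {
        gr <- regionSet@regions[S4Vectors::mcols(regionSet@regions)$label == cls]
        if (!length(gr)) {
            warning(sprintf("no regions of class '%s'", cls))
            out[cls] <- list(NULL)
            next
        }
        byChrom <- list()
        for (r in seq_len(nrow(sp))) {
            sel <- gr[as.character(GenomicRanges::seqnames(gr)) == sp$chrom[r]]
            if (!length(sel)) next
            bs <- binSize(map)
            lo <- (BiocGenerics::start(sel) - 1L) %/% bs + 1L
            hi <- (BiocGenerics::end(sel) - 1L) %/% bs + 1L
            byChrom[[sp$chrom[r]]] <- lapply(seq_along(sel),
                                             function(k) c(lo[k], hi[k]))
        }
        agg <- .aggregateDiagSums(map, edges, use, restrictClass = byChrom)
        out[[cls]] <- new("ScalingCurve", edges = edges, s = .curveS(edges),
                          P = agg$P, npairs = agg$npairs,
                          channel = map@channel, regionClass = cls)
    }
    out
}

#' Log-log slope of a scaling curve
#'
#' Centered finite differences of log10 P against log10 s; one-sided at
#' the first and last defined ranges, missing where neighbors are missing.
#'
#' @param curve a \linkS4class{ScalingCurve}.
#' @return data.frame with columns \code{s} and \code{slope}.
#' @export
logSlope <- function(curve) {
    ok <- which(!is.na(curve@P) & curve@P > 0)
    if (length(ok) < 2L) stop("need at least two defined adjacent ranges")
    ls <- log10(curve@s); lp <- log10(curve@P)
    slope <- rep(NA_real_, length(curve@s))
    for (idx in seq_along(ok)) {
        k <- ok[idx]
        lo <- if (idx > 1L && ok[idx - 1L] == k - 1L) k - 1L else k
        hi <- if (idx < length(ok) && ok[idx + 1L] == k + 1L) k + 1L else k
        if (lo < hi) slope[k] <- (lp[hi] - lp[lo]) / (ls[hi] - ls[lo])
    }
    data.frame(s = curve@s, slope = slope)
}

#' @rdname accessors
#' @export
setMethod("curveTable", "ScalingCurve", function(x) {
    data.frame(edge_lo = x@edges[-length(x@edges)], edge_hi = x@edges[-1],
               s = x@s, P = x@P, n_pairs = x@npairs, channel = x@channel,
               region_class = x@regionClass)
})

setMethod("show", "ScalingCurve", function(object) {
    cat(sprintf("ScalingCurve [%s, %s]: %d ranges (%d with data), s in [%g, %g] bp\n",
                object@channel, object@regionClass, length(object@P),
                sum(!is.na(object@P)), min(object@edges), max(object@edges)))
})

#' Write a scaling curve as TSV
#'
#' @param curve a \linkS4class{ScalingCurve}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path) {
    utils::write.table(curveTable(curve), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
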