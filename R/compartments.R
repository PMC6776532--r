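#' @include balancing.R tracks.R
NULL

#' Compartment eigenvector
#'
#' Per chromosome, eigendecomposition of the observed/expected matrix with
#' 1.0 subtracted from each pixel and masked rows/columns removed. The
#' first \code{nEigs} eigenvectors (largest absolute eigenvalue first),
#' each scaled by the square root of its absolute eigenvalue, are
#' correlated (Pearson) with the per-bin gene-count track; the one with the
#' highest absolute correlation is reported, sign-oriented so the
#' correlation is positive. Positive values then mark the gene-dense
#' A-type compartment.
#'
#' @param map a balanced \linkS4class{ContactMap}.
#' @param geneCountTrack \linkS4class{ScoreTrack} of gene counts per bin on
#'   the same grid.
#' @param nEigs number of leading eigenvectors to screen (default 3).
#' @return list with \code{track} (the selected eigenvector as a
#'   \linkS4class{ScoreTrack}, NA at masked bins) and per-chromosome
#'   \code{eigenvalues}, \code{selected} index and \code{correlation}.
#' @export
compartmentEigenvector <- function(map, geneCountTrack, nEigs = 3L) {
    if (!isBalanced(map)) stop("map must be balanced first")
    if (!.sameGrid(map@binTable, geneCountTrack@binTable))
        stop("gene-count track is not on the map's grid")
    oe <- observedOverExpected(map)
    sp <- .chromSpans(map@binTable)
    out <- rep(NA_real_, nbins(map))
    info <- list()
    for (chrom in names(oe)) {
        r <- which(sp$chrom == chrom)
        idx <- sp$from[r]:sp$to[r]
        valid <- !is.na(map@weights[idx])
        if (sum(valid) < nEigs + 1L) next
        M <- oe[[chrom]][valid, valid, drop = FALSE] - 1
        M[!is.finite(M)] <- 0
        eg <- eigen(M, symmetric = TRUE)
        ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(nEigs)]
        g <- geneCountTrack@values[idx][valid]
        best <- NULL
        for (k in ord) {
            v <- eg$vectors[, k] * sqrt(abs(eg$values[k]))
            cr <- suppressWarnings(stats::cor(v, g))
            if (is.na(cr)) next
            if (is.null(best) || abs(cr) > abs(best$cr))
                best <- list(k = k, v = v, cr = cr)
        }
        if (is.null(best)) next
        v <- if (best$cr < 0) -best$v else best$v
        out[idx[valid]] <- v
        info[[chrom]] <- list(eigenvalues = eg$values[ord],
                              selected = match(best$k, ord),
                              correlation = abs(best$cr))
    }
    list(track = scoreTrack(map@binTable, out, kind = "eigenvector",
                            channel = map@channel),
         info = info)
}

#' Spearman correlation between two tracks
#'
#' Rank correlation over bins where both tracks are defined.
#'
#' @param a,b \linkS4class{ScoreTrack}s on one grid.
#' @return list with \code{rho}, \code{pValue}, \code{n} and a
#'   \code{flagged} marker when a track is constant (correlation then
#'   \code{NA}).
#' @export
trackCorrelation <- function(a, b) {
    if (!.sameGrid(a@binTable, b@binTable))
        stop("tracks are not on the same grid")
    ok <- is.finite(a@values) & is.finite(b@values)
    if (sum(ok) < 10L) stop("need >= 10 jointly defined bins")
    x <- a@values[ok]; y <- b@values[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, pValue = NA_real_, n = sum(ok),
                    flagged = TRUE))
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), pValue = ct$p.value, n = sum(ok),
         flagged = FALSE)
}

#' Genome fractions of pairing/annotation quadrants
#'
#' Splits jointly defined bins into four classes by pairing (tight: PS at
#' or above the threshold) and a second track (high: at or above its
#' threshold; default threshold: the track median), e.g. PS against the
#' compartment eigenvector or expression.
#'
#' @param ps a PS \linkS4class{ScoreTrack}.
#' @param psThreshold PS tight/loose threshold.
#' @param other the second \linkS4class{ScoreTrack}.
#' @param otherThreshold high/low threshold for \code{other} (default:
#'   median over jointly defined bins).
#' @return named numeric vector of fractions (tight_high, tight_low,
#'   loose_high, loose_low) summing to 1.
#' @export
quadrantFractions <- function(ps, psThreshold, other, otherThreshold = NULL) {
    if (!.sameGrid(ps@binTable, other@binTable))
        stop("tracks are not on the same grid")
    ok <- is.finite(ps@values) & is.finite(other@values)
    if (!any(ok)) stop("no jointly defined bins")
    p <- ps@values[ok]; o <- other@values[ok]
    if (is.null(otherThreshold)) otherThreshold <- stats::median(o)
    tight <- p >= psThreshold
    high <- o >= otherThreshold
    n <- length(p)
    c(tight_high = sum(tight & high) / n,
      tight_low = sum(tight & !high) / n,
      loose_high = sum(!tight & high) / n,
      loose_low = sum(!tight & !high) / n)
}

#' Mood's median test of PS by chromatin state
#'
#' Collects the PS values of bins overlapping each chromatin state and,
#' for every non-reference state, performs Mood's median test against the
#' reference state: a 2x2 chi-square (1 df, no continuity correction) of
#' counts above/at-or-below the pooled median of the two samples.
#'
#' @param ps a PS \linkS4class{ScoreTrack}.
#' @param states \code{GRanges} with a \code{state} metadata column.
#' @param referenceState label of the reference state (e.g. active
#'   chromatin).
#' @param minBins states with fewer overlapping scored bins are excluded
#'   with a warning (default 10).
#' @return list with \code{values} (named list of per-state PS vectors) and
#'   \code{tests} (data.frame: state, n, median, chisq, pValue).
#' @export
chromatinStateAssociation <- function(ps, states, referenceState,
                                      minBins = 10L) {
    stopifnot("state" %in% names(S4Vectors::mcols(states)))
    binsGr <- ps@binTable@bins
    scored <- which(is.finite(ps@values))
    hits <- GenomicRanges::findOverlaps(binsGr[scored], states)
    stateOf <- S4Vectors::mcols(states)$state[S4Vectors::subjectHits(hits)]
    psOf <- ps@values[scored[S4Vectors::queryHits(hits)]]
    vals <- split(psOf, stateOf)
    sizes <- lengths(vals)
    small <- names(vals)[sizes < minBins]
    if (length(small)) {
        warning(sprintf("excluding states with < %d bins: %s", minBins,
                        paste(small, collapse = ", ")))
        vals <- vals[sizes >= minBins]
    }
    if (!referenceState %in% names(vals))
        stop(sprintf("reference state '%s' absent (or too small)",
                     referenceState))
    ref <- vals[[referenceState]]
    others <- setdiff(names(vals), referenceState)
    tests <- data.frame(state = others, n = NA_integer_, median = NA_real_,
                        chisq = NA_real_, pValue = NA_real_)
    for (k in seq_along(others)) {
        x <- vals[[others[k]]]
        mt <- moodMedianTest(x, ref)
        tests$n[k] <- length(x)
        tests$median[k] <- stats::median(x)
        tests$chisq[k] <- mt$chisq
        tests$pValue[k] <- mt$pValue
    }
    list(values = vals, tests = tests, referenceState = referenceState)
}

#' Mood's median test for two samples
#'
#' 2x2 chi-square (1 df, no continuity correction) of counts above vs at
#' or below the pooled median:
#' chisq = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @param x,y numeric samples.
#' @return list with \code{chisq}, \code{pValue} and the 2x2 \code{table}.
#' @export
moodMedianTest <- function(x, y) {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    med <- stats::median(c(x, y))
    a <- sum(x > med); b <- sum(y > med)
    cc <- sum(x <= med); d <- sum(y <= med)
    N <- a + b + cc + d
    denom <- as.numeric(a + b) * (cc + d) * (a + cc) * (b + d)
    chisq <- if (denom == 0) 0 else N * (a * d - b * cc)^2 / denom
    list(chisq = chisq,
         pValue = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         table = matrix(c(a, cc, b, d), 2L, 2L,
                        dimnames = list(c("above", "below"), c("x", "y"))))
}

#' Loop quantitation
#'
#' The contact frequency at each loop is the sum of the balanced contact
#' frequency in a square window (side \code{window} bp, default 120 kb)
#' centered on the loop-anchor pixel. Masked pixels contribute 0; windows
#' reaching past a chromosome end are truncated and flagged.
#'
#' @param map a balanced \linkS4class{ContactMap}.
#' @param loops data.frame with columns \code{chrom1}, \code{pos1},
#'   \code{chrom2}, \code{pos2} (anchor midpoints in bp, 0-based).
#' @param window window side in bp (multiple of the bin size).
#' @return the input with columns \code{signal} and \code{truncated} added.
#' @export
loopQuantitation <- function(map, loops, window = 120e3) {
    if (!isBalanced(map)) stop("map must be balanced first")
    bs <- binSize(map)
    if (window %% bs != 0) stop("window must be a multiple of the bin size")
    nbWin <- as.integer(window %/% bs)
    offs <- seq_len(nbWin) - 1L - (nbWin - 1L) %/% 2L
    sp <- .chromSpans(map@binTable)
    w <- map@weights
    loops$signal <- NA_real_
    loops$truncated <- FALSE
    for (k in seq_len(nrow(loops))) {
        r1 <- which(sp$chrom == loops$chrom1[k])
        r2 <- which(sp$chrom == loops$chrom2[k])
        if (!length(r1) || !length(r2))
            stop(sprintf("loop %d anchor off the assembly (%s / %s)",
                         k, loops$chrom1[k], loops$chrom2[k]))
        a1 <- sp$from[r1] + as.integer(loops$pos1[k] %/% bs)
        a2 <- sp$from[r2] + as.integer(loops$pos2[k] %/% bs)
        if (a1 > sp$to[r1] || a2 > sp$to[r2])
            stop(sprintf("loop %d anchor off the assembly", k))
        rows <- a1 + offs; cols <- a2 + offs
        okR <- rows >= sp$from[r1] & rows <= sp$to[r1]
        okC <- cols >= sp$from[r2] & cols <= sp$to[r2]
        if (!all(okR) || !all(okC)) loops$truncated[k] <- TRUE
        rows <- rows[okR]; cols <- cols[okC]
        px <- map@pixels
        sel <- (px$bin1 %in% rows & px$bin2 %in% cols) |
            (px$bin1 %in% cols & px$bin2 %in% rows)
        px <- px[sel, , drop = FALSE]
        if (!nrow(px)) { loops$signal[k] <- 0; next }
        # symmetric-matrix window sum: count a pixel once per covered cell
        inWin <- function(b1, b2) (b1 %in% rows & b2 %in% cols)
        val <- px$count * w[px$bin1] * w[px$bin2]
        val[is.na(val)] <- 0
        hits <- inWin(px$bin1, px$bin2) + inWin(px$bin2, px$bin1)
        same <- px$bin1 == px$bin2
        hits[same] <- pmin(hits[same], 1L)
        loops$signal[k] <- sum(val * hits)
    }
    loops
}

#' Disomy fraction from homolog coverage
#'
#' A disomy of one homolog in a fraction x of cells raises its sequencing
#' coverage by r = (1 + x)/(1 - x) relative to the other homolog;
#' conversely x = (r - 1)/(r + 1). \code{r} is the ratio of mean coverages
#' over the queried region; when r < 1 the homolog roles are swapped and
#' recorded.
#'
#' @param coverageHigh,coverageLow per-bin coverage of the two homologs
#'   over the region of interest.
#' @return a list of class \code{DisomyEstimate}: \code{r}, \code{x},
#'   \code{swapped}.
#' @export
disomyFraction <- function(coverageHigh, coverageLow) {
    mh <- mean(coverageHigh); ml <- mean(coverageLow)
    if (!is.finite(mh) || !is.finite(ml) || mh <= 0 || ml <= 0)
        stop("coverages must be positive over the region")
    swapped <- mh < ml
    r <- if (swapped) ml / mh else mh / ml
    structure(list(r = r, x = (r - 1) / (r + 1), swapped = swapped),
              class = "DisomyEstimate")
}

#' @export
print.DisomyEstimate <- function(x, ...) {
    cat(sprintf("DisomyEstimate: r = %.4f, disomic cell fraction x = %.4f%s\n",
                x$r, x$x, if (x$swapped) " (homolog roles swapped)" else ""))
    invisible(x)
}

#' Coverage ratio implied by a disomy fraction (inverse of
#' \code{\link{disomyFraction}})
#'
#' @param x disomic cell fraction in [0, 1).
#' @return r = (1 + x)/(1 - x).
#' @export
disomyRatio <- function(x) {
    stopifnot(all(x >= 0), all(x < 1))
    (1 + x) / (1 - x)
}
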