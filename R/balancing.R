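#' @include contactMap.R
NULL

#' Iterative correction (matrix balancing)
#'
#' Equalizes the marginal sums of a contact map by iterative correction,
#' yielding per-bin multiplicative weights so that every unmasked bin's
#' balanced marginal (main diagonal excluded) equals the same constant.
#' Weights are scaled so that the total balanced signal over unmasked
#' pixels equals the total raw signal, preserving the count scale; the
#' pairing score and cis score are therefore in (log2) corrected-count
#' units.
#'
#' Bins with zero coverage, and bins whose coverage deviates from the
#' median by more than \code{madMax} median absolute deviations, are masked
#' (weight \code{NA}) before balancing and excluded downstream.
#'
#' @param map a \linkS4class{ContactMap} with raw counts.
#' @param madMax coverage filter width in MADs (default 5).
#' @param tol relative convergence tolerance on the marginal spread
#'   (default 1e-6).
#' @param maxIter iteration cap (default 1000).
#' @return the map with \code{balancingWeights} set.
#' @export
iterativeCorrection <- function(map, madMax = 5, tol = 1e-6, maxIter = 1000L) {
    stopifnot(tol > 0)
    nb <- nbins(map)
    px <- map@pixels
    offdiag <- px$bin1 != px$bin2
    # raw coverage excluding the main diagonal
    cov <- numeric(nb)
    od <- px[offdiag, , drop = FALSE]
    if (nrow(od)) {
        t1 <- rowsum(od$count, od$bin1)
        t2 <- rowsum(od$count, od$bin2)
        cov[as.integer(rownames(t1))] <- cov[as.integer(rownames(t1))] + t1[, 1L]
        cov[as.integer(rownames(t2))] <- cov[as.integer(rownames(t2))] + t2[, 1L]
    }
    masked <- cov == 0
    nzcov <- cov[!masked]
    if (length(nzcov) > 1L && is.finite(madMax)) {
        med <- stats::median(nzcov)
        madv <- stats::mad(nzcov)
        if (madv > 0) masked <- masked | abs(cov - med) > madMax * madv
    }
    keep <- which(!masked)
    if (!length(keep)) stop("all bins masked by the coverage filter")
    # sparse symmetric off-diagonal matrix restricted to unmasked bins
    sel <- offdiag & !masked[px$bin1] & !masked[px$bin2]
    spx <- px[sel, , drop = FALSE]
    loc <- integer(nb); loc[keep] <- seq_along(keep)
    A <- Matrix::sparseMatrix(i = c(loc[spx$bin1], loc[spx$bin2]),
                              j = c(loc[spx$bin2], loc[spx$bin1]),
                              x = c(spx$count, spx$count),
                              dims = c(length(keep), length(keep)))
    b <- rep(1, length(keep))
    spread <- Inf
    for (it in seq_len(maxIter)) {
        s <- b * as.numeric(A %*% b)
        ms <- mean(s)
        if (ms == 0) stop("balancing degenerate: zero marginals")
        spread <- max(abs(s / ms - 1))
        if (spread < tol) break
        b <- b / sqrt(s / ms)
    }
    if (spread >= tol)
        stop(sprintf(paste0("iterative correction did not converge in %d ",
                            "iterations; final relative marginal spread %.3g"),
                     maxIter, spread))
    # preserve the raw count scale: total balanced == total raw (unmasked)
    w <- rep(NA_real_, nb)
    w[keep] <- b
    allsel <- !masked[px$bin1] & !masked[px$bin2]
    rawTot <- sum(px$count[allsel])
    balTot <- sum(px$count[allsel] * w[px$bin1[allsel]] * w[px$bin2[allsel]])
    if (balTot > 0) w <- w * sqrt(rawTot / balTot)
    out <- map
    out@weights <- w
    out@metadata$balancing <- list(madMax = madMax, tol = tol, iterations = it,
                                   spread = spread)
    out
}

#' Observed/expected matrices
#'
#' For each chromosome, divides the balanced contact matrix by its
#' per-diagonal mean (the expected value at that genomic separation,
#' averaged over all unmasked bin pairs). Masked pixels are missing.
#'
#' @param map a balanced \linkS4class{ContactMap}.
#' @return named list of dense per-chromosome matrices of ratios.
#' @export
observedOverExpected <- function(map) {
    if (!isBalanced(map)) stop("map must be balanced first")
    sp <- .chromSpans(map@binTable)
    out <- list()
    for (r in seq_len(nrow(sp))) {
        chrom <- sp$chrom[r]
        valid <- !is.na(map@weights[sp$from[r]:sp$to[r]])
        if (sum(valid) < 2L) {
            warning(sprintf("chromosome %s has < 2 unmasked bins; skipped", chrom))
            next
        }
        A <- .denseChromMatrix(map, chrom, balanced = TRUE)
        n <- nrow(A)
        ds <- .diagSums(map, sp$from[r], sp$to[r], balanced = TRUE)
        npairs <- ds$nPairs
        expected <- ifelse(npairs > 0, ds$sumVal / npairs, NA_real_)
        # main diagonal expected: mean over unmasked diagonal entries
        d0 <- diag(A)
        e0 <- mean(d0[valid])
        E <- matrix(NA_real_, n, n)
        lag <- abs(.row(c(n, n)) - .col(c(n, n)))
        E[] <- c(e0, expected)[lag + 1L]
        out[[chrom]] <- A / E
    }
    out
}

#' Pick the map resolution supported by sequencing depth
#'
#' Given the same data binned at several candidate bin sizes, computes for
#' each candidate the fraction of non-zero pixels on each diagonal, and
#' chooses the finest candidate whose fraction of non-zero pixels at the
#' diagonal containing \code{referenceSeparation} exceeds
#' \code{minFraction}. Defaults follow the rule of selecting the finest
#' resolution with more than 50\% non-zero pixels at 100 kb separation.
#'
#' @param maps named list of \linkS4class{ContactMap}s, one per candidate
#'   bin size (names are ignored; bin sizes are read from the maps).
#' @param referenceSeparation reference genomic separation in bp
#'   (default 1e5); must be a multiple of every candidate bin size.
#' @param minFraction required fraction of non-zero pixels (default 0.5).
#' @return a list of class \code{ResolutionReport} with elements
#'   \code{candidates} (bp), \code{curves} (per candidate, data.frame of
#'   separation and fraction non-zero), \code{fractionAtReference},
#'   \code{chosen} (bp) and \code{qualified} (logical flag; when no
#'   candidate qualifies, \code{chosen} is the coarsest candidate and
#'   \code{qualified} is \code{FALSE}).
#' @export
pickResolution <- function(maps, referenceSeparation = 1e5, minFraction = 0.5) {
    stopifnot(length(maps) >= 1L)
    sizes <- vapply(maps, binSize, integer(1))
    if (any(referenceSeparation %% sizes != 0))
        stop("referenceSeparation must be a multiple of every candidate bin size")
    ord <- order(sizes)
    maps <- maps[ord]; sizes <- sizes[ord]
    curves <- vector("list", length(maps))
    fracRef <- numeric(length(maps))
    for (k in seq_along(maps)) {
        m <- maps[[k]]
        sp <- .chromSpans(m@binTable)
        maxlag <- max(sp$n) - 1L
        nz <- numeric(maxlag); tot <- numeric(maxlag)
        for (r in seq_len(nrow(sp))) {
            n <- sp$n[r]
            if (n < 2L) next
            px <- m@pixels
            keep <- px$bin1 >= sp$from[r] & px$bin2 <= sp$to[r] &
                px$bin1 < px$bin2 & px$count > 0
            lag <- px$bin2[keep] - px$bin1[keep]
            if (length(lag)) {
                tb <- table(lag)
                nz[as.integer(names(tb))] <- nz[as.integer(names(tb))] + tb
            }
            tot[seq_len(n - 1L)] <- tot[seq_len(n - 1L)] + (n - 1L):1L
        }
        frac <- ifelse(tot > 0, nz / tot, NA_real_)
        curves[[k]] <- data.frame(separation = seq_len(maxlag) * sizes[k],
                                  fraction = frac)
        dref <- referenceSeparation %/% sizes[k]
        fracRef[k] <- if (dref >= 1 && dref <= maxlag) frac[dref] else NA_real_
    }
    ok <- which(!is.na(fracRef) & fracRef > minFraction)
    qualified <- length(ok) > 0L
    chosen <- if (qualified) sizes[min(ok)] else sizes[length(sizes)]
    structure(list(candidates = sizes, curves = curves,
                   fractionAtReference = fracRef, chosen = chosen,
                   qualified = qualified,
                   referenceSeparation = referenceSeparation,
                   minFraction = minFraction),
              class = "ResolutionReport")
}

#' @export
print.ResolutionReport <- function(x, ...) {
    cat("ResolutionReport\n")
    for (k in seq_along(x$candidates))
        cat(sprintf("  %6d bp: %.1f%% non-zero at %g bp%s\n", x$candidates[k],
                    100 * x$fractionAtReference[k], x$referenceSeparation,
                    if (x$candidates[k] == x$chosen) "  <- chosen" else ""))
    if (!x$qualified)
        cat("  (no candidate met the threshold; coarsest reported)\n")
    invisible(x)
}
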