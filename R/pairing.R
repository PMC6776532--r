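#' @include contactMap.R tracks.R
NULL

#' Pairing score / cis score track
#'
#' The pairing score of bin i is log2 of the mean balanced contact
#' frequency over all (m, n) pairs with m, n in [i-W, i+W] - the
#' (2W+1) x (2W+1) pixel window centered on the diagonal, main diagonal
#' included. Computed on the trans-homolog channel it is the PS; on a cis
#' channel the same statistic is the cis score (CS), a control for local
#' visibility. The default W = 3 gives a 7 x 7 = 49-pixel window.
#'
#' A bin's value is missing when more than half of the full window's pixels
#' are unavailable (masked bins, or the window truncated at a chromosome
#' end) or when the window mean is zero.
#'
#' @param map a balanced \linkS4class{ContactMap}.
#' @param W window half-width in bins (default 3).
#' @return a \linkS4class{ScoreTrack} of kind \code{"PS"} (thom channel) or
#'   \code{"CS"} (otherwise), in log2 corrected-count units.
#' @export
pairingScore <- function(map, W = 3L) {
    if (!isBalanced(map)) stop("map must be balanced first")
    W <- as.integer(W)
    stopifnot(W >= 0L)
    sp <- .chromSpans(map@binTable)
    nb <- nbins(map)
    out <- rep(NA_real_, nb)
    totalPix <- (2L * W + 1L)^2
    for (r in seq_len(nrow(sp))) {
        n <- sp$n[r]
        valid <- as.numeric(!is.na(map@weights[sp$from[r]:sp$to[r]]))
        dv <- .chromDiagVals(map, sp$from[r], sp$to[r], maxLag = 2L * W,
                             balanced = TRUE)
        S <- numeric(n); C <- numeric(n)
        for (a in (-W):W) {
            for (b in (-W):W) {
                k <- abs(a - b)
                off <- min(a, b)          # diagonal element index i + off
                lo <- max(1L, 1L - off, 1L - off - k)
                hi <- min(n, n - off, n - off - k)
                if (lo > hi) next
                i <- lo:hi
                S[i] <- S[i] + dv[[k + 1L]][i + off]
                C[i] <- C[i] + valid[i + off] * valid[i + off + k]
            }
        }
        m <- ifelse(C > 0, S / C, NA_real_)
        m[C < totalPix / 2] <- NA_real_
        m[!is.na(m) & m <= 0] <- NA_real_
        out[sp$from[r]:sp$to[r]] <- log2(m)
    }
    out[binMask(map)] <- NA_real_
    scoreTrack(map@binTable, out,
               kind = if (map@channel == "thom") "PS" else "CS",
               window = W, channel = map@channel)
}

#' Mode of a sample by fixed-bandwidth kernel density
#'
#' Gaussian kernel density with fixed bandwidth evaluated on a regular
#' grid spanning the sample range (grid step at most \code{step}); the
#' argmax is the mode. The fixed bandwidth makes the estimate
#' deterministic and comparable across samples.
#'
#' @param x numeric sample (NAs dropped).
#' @param bw kernel bandwidth (default 0.05, log2 units).
#' @param step maximum grid step (default 0.001).
#' @return the estimated mode.
#' @export
modeEstimate <- function(x, bw = 0.05, step = 0.001) {
    x <- x[is.finite(x)]
    if (!length(x)) stop("no finite values")
    rng <- range(x)
    if (diff(rng) < step) return(mean(rng))
    npts <- max(512L, 2L^as.integer(ceiling(log2(diff(rng) / step + 1))))
    d <- stats::density(x, bw = bw, from = rng[1], to = rng[2], n = npts)
    d$x[which.max(d$y)]
}

#' Aggregated pairing score (APS)
#'
#' The APS is the mode of the genome-wide per-bin (PS - CS) distribution:
#' the most probable log2 ratio of short-distance trans-homolog to
#' short-distance cis contact frequency. The mode makes the summary robust
#' to the heavy loose-pairing tail.
#'
#' @param ps PS \linkS4class{ScoreTrack} (or a numeric vector of per-bin
#'   PS - CS differences, with \code{cs} omitted).
#' @param cs CS \linkS4class{ScoreTrack} on the same grid.
#' @param minBins minimum number of jointly defined bins (default 100).
#' @param bw,step mode-estimator settings (see \code{\link{modeEstimate}}).
#' @return the APS in log2 units.
#' @export
aggregatedPairingScore <- function(ps, cs = NULL, minBins = 100L, bw = 0.05,
                                   step = 0.001) {
    d <- psCsDifference(ps, cs)
    d <- d[is.finite(d)]
    if (length(d) < minBins)
        stop(sprintf("only %d bins with both PS and CS defined (need >= %d)",
                     length(d), minBins))
    modeEstimate(d, bw = bw, step = step)
}

#' Per-bin PS - CS differences
#'
#' @param ps PS \linkS4class{ScoreTrack} or numeric vector of differences.
#' @param cs CS \linkS4class{ScoreTrack}, or \code{NULL} when \code{ps}
#'   already holds differences.
#' @return numeric vector of per-bin differences (NA where either missing).
#' @export
psCsDifference <- function(ps, cs = NULL) {
    if (is.numeric(ps) && is.null(cs)) return(ps)
    stopifnot(is(ps, "ScoreTrack"), is(cs, "ScoreTrack"))
    if (!.sameGrid(ps@binTable, cs@binTable))
        stop("PS and CS tracks must share a bin table")
    ps@values - cs@values
}

#' Bootstrap test for an APS difference between two conditions
#'
#' Tests the null hypothesis that the per-bin (PS - CS) values of two
#' conditions come from one distribution. The two samples are merged; each
#' replicate redraws, with replacement, two samples of the original sizes
#' from the merged pool and records the absolute difference of their APS.
#' The p-value is the fraction of replicates at least as extreme as the
#' observed |delta APS|, with add-one smoothing (k+1)/(R+1) so that 0 is
#' never reported.
#'
#' @param diffA,diffB numeric vectors of per-bin (PS - CS) values for the
#'   two conditions.
#' @param replicates bootstrap replicate count (default 1000).
#' @param seed integer seed.
#' @param bw,step mode-estimator settings.
#' @return a list of class \code{APSComparison}: \code{apsA}, \code{apsB},
#'   \code{difference} (APS_A - APS_B), \code{pValue}, \code{replicates},
#'   \code{seed}.
#' @export
apsBootstrapTest <- function(diffA, diffB, replicates = 1000L, seed = NULL,
                             bw = 0.05, step = 0.001) {
    diffA <- diffA[is.finite(diffA)]
    diffB <- diffB[is.finite(diffB)]
    if (!length(diffA) || !length(diffB)) stop("both samples must be non-empty")
    stopifnot(replicates >= 1L)
    apsA <- modeEstimate(diffA, bw = bw, step = step)
    apsB <- modeEstimate(diffB, bw = bw, step = step)
    obs <- apsA - apsB
    merged <- c(diffA, diffB)
    na <- length(diffA); nb <- length(diffB)
    dnull <- .withSeed(seed, vapply(seq_len(replicates), function(r) {
        sa <- sample(merged, na, replace = TRUE)
        sb <- sample(merged, nb, replace = TRUE)
        abs(modeEstimate(sa, bw = bw, step = step) -
            modeEstimate(sb, bw = bw, step = step))
    }, numeric(1)))
    p <- (sum(dnull >= abs(obs)) + 1) / (replicates + 1)
    structure(list(apsA = apsA, apsB = apsB, difference = obs, pValue = p,
                   replicates = replicates, seed = seed),
              class = "APSComparison")
}

#' @export
print.APSComparison <- function(x, ...) {
    cat(sprintf(paste0("APSComparison: APS_A = %.4f, APS_B = %.4f, ",
                       "delta = %.4f, p = %.4g (%d bootstrap replicates)\n"),
                x$apsA, x$apsB, x$difference, x$pValue, x$replicates))
    invisible(x)
}
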