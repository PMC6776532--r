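#' @include tracks.R
NULL

#' Fit a two-Gaussian mixture to the pairing-score distribution
#'
#' The genome-wide PS distribution shows a well-pronounced high-PS peak
#' (tightly paired bins) with a tail into low values (loosely paired bins).
#' The two populations are separated by fitting a sum of two Gaussians by
#' maximum-likelihood EM. To stabilize the fit, values below
#' \code{clipFloor} are winsorized (set to the floor, preserving the
#' loose-tail mass). Initialization is deterministic: means at the 25th and
#' 75th percentiles, equal weights, both sds at half the sample sd.
#'
#' @param psValues numeric PS sample (a \linkS4class{ScoreTrack} is also
#'   accepted); needs >= 500 finite values.
#' @param clipFloor winsorization floor in log2 units (default -3).
#' @param tol relative log-likelihood tolerance (default 1e-8).
#' @param maxIter EM iteration cap (default 1000).
#' @return a \linkS4class{GaussianMixtureFit} with components ordered
#'   mu_loose < mu_tight and the density-intersection threshold set.
#' @export
fitTwoGaussians <- function(psValues, clipFloor = -3, tol = 1e-8,
                            maxIter = 1000L) {
    if (is(psValues, "ScoreTrack")) psValues <- psValues@values
    x <- psValues[is.finite(psValues)]
    if (length(x) < 500L)
        stop(sprintf("need >= 500 finite PS values, got %d", length(x)))
    x[x < clipFloor] <- clipFloor
    fit <- .emTwoGaussians(x, tol, maxIter, varFloor = 0)
    if (fit$degenerate)
        fit <- .emTwoGaussians(x, tol, maxIter, varFloor = 1e-4)
    if (fit$degenerate)
        stop("EM degenerate (a component variance collapsed) even with a variance floor")
    ord <- order(fit$mu)
    # reliability: the two-component fit must beat a single Gaussian by BIC
    # (3 extra parameters), otherwise the split is not identifiable
    ll1 <- sum(stats::dnorm(x, mean(x),
                            stats::sd(x) * sqrt((length(x) - 1) / length(x)),
                            log = TRUE))
    flagged <- abs(diff(fit$mu)) < 1e-3 ||
        2 * (fit$ll - ll1) < 3 * log(length(x))
    out <- new("GaussianMixtureFit", weights = fit$pi[ord],
               means = fit$mu[ord], sds = fit$sigma[ord],
               clipFloor = clipFloor, threshold = NA_real_,
               logLik = fit$ll, converged = fit$converged,
               flagged = flagged, nobs = length(x))
    th <- tryCatch(intersectionThreshold(out), error = function(e) NA_real_)
    if (is.na(th)) out@flagged <- TRUE
    out@threshold <- th
    out
}

.emTwoGaussians <- function(x, tol, maxIter, varFloor = 0) {
    n <- length(x)
    mu <- as.numeric(stats::quantile(x, c(0.25, 0.75), names = FALSE))
    if (mu[1] == mu[2]) mu <- mu + c(-1, 1) * max(stats::sd(x), 1e-3) / 4
    sigma <- rep(max(stats::sd(x) / 2, sqrt(varFloor), 1e-6), 2L)
    pi_ <- c(0.5, 0.5)
    ll <- -Inf; converged <- FALSE; degenerate <- FALSE
    for (it in seq_len(maxIter)) {
        d1 <- pi_[1] * stats::dnorm(x, mu[1], sigma[1])
        d2 <- pi_[2] * stats::dnorm(x, mu[2], sigma[2])
        tot <- d1 + d2
        if (any(tot == 0) || any(!is.finite(tot))) { degenerate <- TRUE; break }
        g <- d1 / tot
        llNew <- sum(log(tot))
        if (is.finite(ll) && abs(llNew - ll) <= tol * abs(ll)) {
            ll <- llNew; converged <- TRUE; break
        }
        ll <- llNew
        n1 <- sum(g); n2 <- n - n1
        if (n1 < 1e-8 || n2 < 1e-8) { degenerate <- TRUE; break }
        mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
        v1 <- sum(g * (x - mu[1])^2) / n1
        v2 <- sum((1 - g) * (x - mu[2])^2) / n2
        v1 <- max(v1, varFloor); v2 <- max(v2, varFloor)
        if (v1 <= 0 || v2 <= 0) { degenerate <- TRUE; break }
        sigma <- sqrt(c(v1, v2))
        pi_ <- c(n1, n2) / n
    }
    list(pi = pi_, mu = mu, sigma = sigma, ll = ll, converged = converged,
         degenerate = degenerate)
}

#' Density-intersection threshold of a two-Gaussian fit
#'
#' Solves pi_1 phi(x; mu_1, sigma_1) = pi_2 phi(x; mu_2, sigma_2) for the
#' root between the two means (the equation is quadratic in x via the log
#' densities). Bins below the threshold are more likely to belong to the
#' low-PS (loose) component.
#'
#' @param fit a \linkS4class{GaussianMixtureFit}.
#' @return the threshold theta, strictly between mu_loose and mu_tight.
#' @export
intersectionThreshold <- function(fit) {
    p <- fit@weights; m <- fit@means; s <- fit@sds
    # log p1 - log s1 - (x-m1)^2/(2 s1^2) = log p2 - log s2 - (x-m2)^2/(2 s2^2)
    A <- 1 / (2 * s[2]^2) - 1 / (2 * s[1]^2)
    B <- m[1] / s[1]^2 - m[2] / s[2]^2
    Cc <- m[2]^2 / (2 * s[2]^2) - m[1]^2 / (2 * s[1]^2) +
        log(p[1]) - log(p[2]) + log(s[2]) - log(s[1])
    if (abs(A) < 1e-14) {
        if (abs(B) < 1e-14) stop(.noRootMsg(fit))
        roots <- -Cc / B
    } else {
        disc <- B^2 - 4 * A * Cc
        if (disc < 0) stop(.noRootMsg(fit))
        roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
    }
    inside <- roots[roots > m[1] & roots < m[2]]
    if (!length(inside)) stop(.noRootMsg(fit))
    inside[1]
}

.noRootMsg <- function(fit) {
    sprintf(paste0("no density crossing between the means: pi = (%.3f, %.3f), ",
                   "mu = (%.3f, %.3f), sigma = (%.3f, %.3f)"),
            fit@weights[1], fit@weights[2], fit@means[1], fit@means[2],
            fit@sds[1], fit@sds[2])
}

setMethod("show", "GaussianMixtureFit", function(object) {
    cat(sprintf(paste0("GaussianMixtureFit (n = %d, clip floor %.3g):\n",
                       "  loose: pi = %.3f, mu = %.3f, sd = %.3f\n",
                       "  tight: pi = %.3f, mu = %.3f, sd = %.3f\n",
                       "  threshold = %.4f%s\n"),
                object@nobs, object@clipFloor,
                object@weights[1], object@means[1], object@sds[1],
                object@weights[2], object@means[2], object@sds[2],
                object@threshold,
                if (object@flagged) "  [FLAGGED: unreliable]" else ""))
})

#' Classify bins as tightly or loosely paired
#'
#' Bins with PS strictly below the threshold are loose; bins at or above it
#' are tight; bins with missing PS stay missing.
#'
#' @param ps a PS \linkS4class{ScoreTrack}.
#' @param threshold PS threshold (a \linkS4class{GaussianMixtureFit} is
#'   also accepted).
#' @return character vector of per-bin labels
#'   \code{"tight"/"loose"/NA}.
#' @export
classifyBins <- function(ps, threshold) {
    if (is(threshold, "GaussianMixtureFit")) threshold <- threshold@threshold
    stopifnot(is.finite(threshold))
    v <- if (is(ps, "ScoreTrack")) ps@values else as.numeric(ps)
    ifelse(is.na(v), NA_character_, ifelse(v < threshold, "loose", "tight"))
}

#' Classify boundary-delimited regions as tightly or loosely paired
#'
#' The genome is divided into regions between consecutive insulating
#' boundaries (chromosome ends act as implicit boundaries). A region is
#' loose when its fraction of loosely paired bins (missing bins excluded
#' from the denominator) is at least \code{looseCutoff}, else tight;
#' regions whose bins are all missing are labeled missing. Adjacent
#' regions with the same label are then merged when the boundary bin
#' between them carries that same bin-level label, repeating until stable
#' (false-positive boundary calls otherwise split single regions).
#'
#' @param labels per-bin labels from \code{\link{classifyBins}}.
#' @param boundarySet a \linkS4class{BoundarySet} on the same grid.
#' @param looseCutoff loose-bin fraction cutoff (default 0.25).
#' @return a \linkS4class{PairingRegionSet}.
#' @export
classifyRegions <- function(labels, boundarySet, looseCutoff = 0.25) {
    bt <- boundarySet@binTable
    stopifnot(length(labels) == length(bt@bins))
    sp <- .chromSpans(bt)
    allRegions <- list()
    for (r in seq_len(nrow(sp))) {
        bb <- boundarySet@bins[boundarySet@bins >= sp$from[r] &
                               boundarySet@bins <= sp$to[r]]
        # regions: [from, b1-1], [b1, b2-1], ..., [bk, to]
        starts <- c(sp$from[r], bb)
        ends <- c(bb - 1L, sp$to[r])
        keep <- starts <= ends
        starts <- starts[keep]; ends <- ends[keep]
        regLab <- character(length(starts))
        looseFrac <- rep(NA_real_, length(starts))
        for (k in seq_along(starts)) {
            lab <- labels[starts[k]:ends[k]]
            nlab <- sum(!is.na(lab))
            if (nlab == 0L) { regLab[k] <- "missing"; next }
            looseFrac[k] <- sum(lab == "loose", na.rm = TRUE) / nlab
            regLab[k] <- if (looseFrac[k] >= looseCutoff) "loose" else "tight"
        }
        # merge across boundary bins carrying the shared label, to fixpoint
        repeat {
            merged <- FALSE
            k <- 1L
            while (k < length(starts)) {
                bbin <- starts[k + 1L]   # boundary bin between k and k+1
                if (regLab[k] != "missing" && regLab[k] == regLab[k + 1L] &&
                    !is.na(labels[bbin]) && labels[bbin] == regLab[k]) {
                    lab <- labels[starts[k]:ends[k + 1L]]
                    nlab <- sum(!is.na(lab))
                    looseFrac[k] <- sum(lab == "loose", na.rm = TRUE) / nlab
                    ends[k] <- ends[k + 1L]
                    starts <- starts[-(k + 1L)]; ends <- ends[-(k + 1L)]
                    regLab <- regLab[-(k + 1L)]
                    looseFrac <- looseFrac[-(k + 1L)]
                    merged <- TRUE
                } else k <- k + 1L
            }
            if (!merged) break
        }
        b <- bt@bins
        gr <- GenomicRanges::GRanges(
            sp$chrom[r],
            IRanges::IRanges(start = BiocGenerics::start(b)[starts],
                             end = BiocGenerics::end(b)[ends]),
            seqinfo = GenomeInfoDb::seqinfo(b))
        S4Vectors::mcols(gr)$label <- regLab
        S4Vectors::mcols(gr)$looseFraction <- looseFrac
        allRegions[[r]] <- gr
    }
    regions <- suppressWarnings(do.call(c, allRegions))
    new("PairingRegionSet", binTable = bt, regions = regions,
        cutoff = looseCutoff)
}

#' @rdname accessors
#' @export
setMethod("regions", "PairingRegionSet", function(x) x@regions)

setMethod("show", "PairingRegionSet", function(object) {
    lab <- S4Vectors::mcols(object@regions)$label
    w <- IRanges::width(object@regions)
    cat(sprintf(paste0("PairingRegionSet: %d regions (cutoff %.2f): ",
                       "%d tight (%.1f Mb), %d loose (%.1f Mb), %d missing\n"),
                length(lab), object@cutoff,
                sum(lab == "tight"), sum(w[lab == "tight"]) / 1e6,
                sum(lab == "loose"), sum(w[lab == "loose"]) / 1e6,
                sum(lab == "missing")))
})

#' Keep regions within a size class
#'
#' @param regionSet a \linkS4class{PairingRegionSet}.
#' @param sizeRange c(lo, hi) in bp; regions with lo <= length < hi are
#'   kept. The analyses of region-internal organization use the classes
#'   100-200 kb and 200-400 kb.
#' @return the filtered \linkS4class{PairingRegionSet} (possibly empty).
#' @export
selectRegionsBySize <- function(regionSet, sizeRange) {
    stopifnot(length(sizeRange) == 2L, sizeRange[1] < sizeRange[2])
    w <- IRanges::width(regionSet@regions)
    out <- regionSet
    out@regions <- regionSet@regions[w >= sizeRange[1] & w < sizeRange[2]]
    out
}

#' Write a PairingRegionSet (or per-bin labels) as BED
#'
#' The name field carries the label and the score column the loose-bin
#' fraction scaled to 0-1000.
#'
#' @param regionSet a \linkS4class{PairingRegionSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regionSet, path) {
    gr <- regionSet@regions
    mc <- S4Vectors::mcols(gr)
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        start = BiocGenerics::start(gr) - 1L,
        end = BiocGenerics::end(gr),
        name = mc$label,
        score = ifelse(is.na(mc$looseFraction), 0L,
                       as.integer(round(1000 * mc$looseFraction))))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
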