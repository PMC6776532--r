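# Shared fixtures and independent brute-force oracles. Oracles work on
# dense matrices by direct enumeration and never call the package paths
# they are used to check.

# A small single-chromosome grid.
toyGenome <- function(nbins, binSize = 4000L, chrom = "chr1") {
    binnedGenome(stats::setNames(nbins * binSize, chrom), binSize)
}

# Deterministic random sparse symmetric map on a toy grid.
randomToyMap <- function(nbins, density = 0.3, seed = 1, channel = "cis_pooled",
                         maxCount = 20L) {
    set.seed(seed)
    ij <- which(upper.tri(matrix(0, nbins, nbins), diag = TRUE), arr.ind = TRUE)
    keep <- runif(nrow(ij)) < density
    ij <- ij[keep, , drop = FALSE]
    px <- data.frame(bin1 = ij[, 1], bin2 = ij[, 2],
                     count = sample.int(maxCount, nrow(ij), replace = TRUE))
    contactMap(toyGenome(nbins), px, channel = channel)
}

# Dense symmetric matrix from a ContactMap (raw or balanced; balanced has
# NA at masked bins).
denseFromMap <- function(map, balanced = FALSE) {
    n <- nbins(map)
    A <- matrix(0, n, n)
    px <- pixels(map)
    A[cbind(px$bin1, px$bin2)] <- px$count
    A[cbind(px$bin2, px$bin1)] <- px$count
    if (balanced) {
        w <- balancingWeights(map)
        A <- A * outer(w, w)
    }
    A
}

# Brute-force fixed-point balancing oracle on a dense matrix: iterates
# b <- b / (marginals/mean) on the off-diagonal part until the marginals
# are flat to `tol`, then rescales so the balanced total matches the raw
# total. Returns the weight vector (NA for zero-coverage bins).
bruteForceIC <- function(A, tol = 1e-12, maxIter = 100000L) {
    n <- nrow(A)
    Aoff <- A; diag(Aoff) <- 0
    cov <- rowSums(Aoff)
    keep <- cov > 0
    b <- rep(1, n); b[!keep] <- NA
    for (it in seq_len(maxIter)) {
        s <- b[keep] * (Aoff[keep, keep, drop = FALSE] %*% b[keep])[, 1]
        if (max(abs(s / mean(s) - 1)) < tol) break
        b[keep] <- b[keep] / sqrt(s / mean(s))
    }
    W <- outer(b, b)
    rawTot <- sum(A[keep, keep]) / 2 + sum(diag(A)[keep]) / 2
    balTot <- sum((A * W)[keep, keep]) / 2 + sum((diag(A) * diag(W))[keep]) / 2
    b * sqrt(rawTot / balTot)
}

# Brute-force P(s) oracle: average value over enumerated unmasked pairs
# per separation range [lo, hi) in bp.
brutePs <- function(A, binSizeBp, edges, valid = rep(TRUE, nrow(A))) {
    n <- nrow(A)
    nr <- length(edges) - 1L
    sumV <- numeric(nr); nP <- numeric(nr)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (!valid[i] || !valid[j]) next
        s <- (j - i) * binSizeBp
        k <- findInterval(s, edges)
        if (k >= 1 && k <= nr && s < edges[nr + 1]) {
            sumV[k] <- sumV[k] + A[i, j]
            nP[k] <- nP[k] + 1
        }
    }
    ifelse(nP > 0, sumV / nP, NA_real_)
}

# Brute-force windowed pairing-score oracle: log2 mean of the
# (2W+1)^2 window of the dense balanced matrix at each bin; NA when more
# than half the full window is unavailable.
brutePairingScore <- function(A, W, valid = rep(TRUE, nrow(A))) {
    n <- nrow(A)
    out <- rep(NA_real_, n)
    total <- (2 * W + 1)^2
    for (i in 1:n) {
        if (!valid[i]) next
        idx <- (i - W):(i + W)
        idx <- idx[idx >= 1 & idx <= n]
        idx <- idx[valid[idx]]
        cnt <- length(idx)^2
        if (cnt < total / 2) next
        m <- mean(A[idx, idx, drop = FALSE])
        if (is.na(m) || m <= 0) next
        out[i] <- log2(m)
    }
    out
}

# Brute-force diamond insulation raw sums.
bruteDiamond <- function(A, w) {
    n <- nrow(A)
    out <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
        out[i] <- sum(A[(i - w):(i - 1), (i + 1):(i + w)])
    }
    out
}

# Exhaustive maximum bipartite matching size for boundary sets within a
# tolerance (small instances only).
bruteMatch <- function(a, b, tol) {
    if (!length(a) || !length(b)) return(0L)
    best <- 0L
    recurse <- function(ai, usedB, acc) {
        if (ai > length(a)) { best <<- max(best, acc); return() }
        recurse(ai + 1L, usedB, acc)
        for (j in seq_along(b)) {
            if (!usedB[j] && abs(a[ai] - b[j]) <= tol) {
                usedB[j] <- TRUE
                recurse(ai + 1L, usedB, acc + 1L)
                usedB[j] <- FALSE
            }
        }
    }
    recurse(1L, logical(length(b)), 0L)
    best
}

# Balanced toy map: random map balanced with no MAD filtering.
balancedToyMap <- function(nbins, density = 0.6, seed = 1,
                           channel = "cis_pooled") {
    m <- randomToyMap(nbins, density = density, seed = seed,
                      channel = channel)
    iterativeCorrection(m, madMax = Inf)
}

# Closed-form density-intersection root of a two-Gaussian mixture,
# independent of the package implementation: dense grid crossing search.
gridIntersection <- function(p, m, s, lo, hi, n = 2e6) {
    x <- seq(lo, hi, length.out = n)
    d <- p[1] * dnorm(x, m[1], s[1]) - p[2] * dnorm(x, m[2], s[2])
    k <- which(diff(sign(d)) != 0)
    x[k[1]] + (x[2] - x[1]) / 2
}

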