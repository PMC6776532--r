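test_that("bin grids tile chromosomes and map coordinates to indices", {
    bg <- binnedGenome(c(chr1 = 10000, chr2 = 7000), binSize = 4000)
    expect_equal(nbins(bg), 3L + 2L)
    w <- IRanges::width(bins(bg))
    expect_equal(w, c(4000, 4000, 2000, 4000, 3000))
    expect_equal(pairHiC:::.binIndexOf(bg, c("chr1", "chr2", "chr1"),
                                       c(4000L, 0L, 8000L)),
                 c(2L, 4L, 3L))
    expect_true(is.na(pairHiC:::.binIndexOf(bg, "chr1", 3999L)))
    expect_true(is.na(pairHiC:::.binIndexOf(bg, "chrX", 0L)))
})

test_that("TSV pixels are folded to the upper triangle regardless of orientation", {
    bg <- binnedGenome(c(chr1 = 8000), binSize = 4000)
    f1 <- tempfile(); f2 <- tempfile()
    writeLines("chr1\t0\tchr1\t4000\t5", f1)
    writeLines("chr1\t4000\tchr1\t0\t5", f2)
    m1 <- readContactMap(f1, bg)
    m2 <- readContactMap(f2, bg)
    expect_equal(pixels(m1), data.frame(bin1 = 1L, bin2 = 2L, count = 5))
    expect_identical(pixels(m1), pixels(m2))
})

test_that("malformed records are rejected with the offending record named", {
    bg <- binnedGenome(c(chr1 = 8000), binSize = 4000)
    f <- tempfile()
    writeLines("chr1\t0\tchr1\t4000\t-2", f)
    expect_error(readContactMap(f, bg), "negative")
    writeLines("chr1\t0\tchr1\t1234\t2", f)
    expect_error(readContactMap(f, bg), "off the bin grid")
})

test_that("write/read round trip preserves pixels and weights", {
    m <- randomToyMap(50, density = 0.2, seed = 42)
    m <- iterativeCorrection(m, madMax = Inf)
    f <- tempfile(fileext = ".tsv")
    writeContactMap(m, f)
    m2 <- readContactMap(f, m@binTable, channel = channel(m))
    expect_equal(pixels(m2), pixels(m))
    w <- utils::read.table(paste0(f, ".weights.tsv"), sep = "\t")
    expect_equal(w$V4, balancingWeights(m), tolerance = 1e-12)
})

test_that("balancing a constant matrix gives equal weights and flat marginals", {
    n <- 12L
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- contactMap(toyGenome(n),
                    data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = 7))
    b <- iterativeCorrection(m, madMax = Inf, tol = 1e-10)
    w <- balancingWeights(b)
    expect_true(all(!is.na(w)))
    expect_lt(diff(range(w)), 1e-9)
    A <- denseFromMap(b, balanced = TRUE)
    diag(A) <- 0
    marg <- rowSums(A)
    expect_lt(max(abs(marg / mean(marg) - 1)), 1e-9)
})

test_that("balancing weights match an independent fixed-point oracle", {
    m <- contactMap(toyGenome(3),
                    data.frame(bin1 = c(1, 1, 2), bin2 = c(2, 3, 3),
                               count = c(2, 1, 4)))
    b <- iterativeCorrection(m, madMax = Inf, tol = 1e-12)
    oracle <- bruteForceIC(denseFromMap(m), tol = 1e-14)
    expect_equal(balancingWeights(b), oracle, tolerance = 1e-8)

    m2 <- randomToyMap(20, density = 0.7, seed = 9)
    b2 <- iterativeCorrection(m2, madMax = Inf, tol = 1e-12)
    expect_equal(balancingWeights(b2), bruteForceIC(denseFromMap(m2)),
                 tolerance = 1e-8)
})

test_that("zero-coverage bins are masked and re-balancing is idempotent", {
    n <- 10L
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    px <- data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = 5)
    px <- px[px$bin1 != 4L & px$bin2 != 4L, ]      # bin 4 has zero coverage
    m <- iterativeCorrection(contactMap(toyGenome(n), px), madMax = Inf)
    expect_true(is.na(balancingWeights(m)[4]))
    expect_identical(binMask(m), seq_len(n) == 4L)
    # idempotence: weights change by less than tol under re-balancing
    m2 <- iterativeCorrection(m, madMax = Inf, tol = 1e-8)
    ok <- !is.na(balancingWeights(m))
    expect_equal(balancingWeights(m2)[ok], balancingWeights(m)[ok],
                 tolerance = 1e-6)
})

test_that("observed/expected is 1 for translation-invariant matrices", {
    n <- 15L
    A <- outer(1:n, 1:n, function(i, j) 10 / (abs(i - j) + 1))
    ij <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    m <- contactMap(toyGenome(n),
                    data.frame(bin1 = ij[, 1], bin2 = ij[, 2],
                               count = A[ij]))
    m@weights <- rep(1, n)     # unit weights: balanced values stay Toeplitz
    oe <- observedOverExpected(m)[[1]]
    expect_equal(max(abs(oe - 1), na.rm = TRUE), 0, tolerance = 1e-6)
})

test_that("observed/expected matches per-diagonal enumeration and propagates masks", {
    m <- balancedToyMap(5, density = 0.9, seed = 3)
    A <- denseFromMap(m, balanced = TRUE)
    oe <- observedOverExpected(m)[[1]]
    for (d in 1:4) {
        idx <- cbind(1:(5 - d), (1 + d):5)
        expected <- mean(A[idx])
        expect_equal(oe[idx], A[idx] / expected, tolerance = 1e-12)
    }
    # per-diagonal mean of O/E is 1
    for (d in 1:4) {
        idx <- cbind(1:(5 - d), (1 + d):5)
        expect_equal(mean(oe[idx], na.rm = TRUE), 1, tolerance = 1e-10)
    }
    # masked row/column fully missing
    n <- 10L
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    px <- data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = 5)
    px <- px[px$bin1 != 4L & px$bin2 != 4L, ]
    mm <- iterativeCorrection(contactMap(toyGenome(n), px), madMax = Inf)
    oe2 <- observedOverExpected(mm)[[1]]
    expect_true(all(is.na(oe2[4, ])))
    expect_true(all(is.na(oe2[, 4])))
})

test_that("resolution picking selects the finest qualifying bin size", {
    mkmap <- function(nbins, binSizeBp, refLag, fracNonzero, seed) {
        set.seed(seed)
        d <- refLag
        i <- seq_len(nbins - d)
        nz <- sample(i, round(fracNonzero * length(i)))
        px <- data.frame(bin1 = c(nz, seq_len(nbins - 1L)),
                         bin2 = c(nz + d, seq_len(nbins - 1L) + 1L),
                         count = 1)
        contactMap(binnedGenome(c(chr1 = nbins * binSizeBp), binSizeBp), px)
    }
    # 100 kb diagonal: 40% non-zero at 2 kb, 80% at 4 kb
    m2k <- mkmap(500, 2000, 50, 0.4, 1)
    m4k <- mkmap(250, 4000, 25, 0.8, 2)
    rep1 <- pickResolution(list(m2k, m4k))
    expect_equal(rep1$chosen, 4000L)
    expect_true(rep1$qualified)
    expect_equal(rep1$fractionAtReference, c(0.4, 0.8), tolerance = 0.01)
    # fully dense maps: the finest candidate wins
    dense <- lapply(c(1000, 2000, 4000, 10000), function(bs) {
        nb <- 200000 %/% bs
        ij <- which(upper.tri(matrix(0, nb, nb), diag = TRUE), arr.ind = TRUE)
        contactMap(binnedGenome(c(chr1 = 200000), bs),
                   data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = 1))
    })
    expect_equal(pickResolution(dense)$chosen, 1000L)
    # nothing qualifies: coarsest, flagged
    sparse <- mkmap(250, 4000, 25, 0.1, 3)
    rep2 <- pickResolution(list(sparse))
    expect_false(rep2$qualified)
    expect_equal(rep2$chosen, 4000L)
})
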