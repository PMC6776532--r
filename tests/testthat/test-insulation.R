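# Balanced two-block map: independent blocks meeting between bins k and
# k+1, with weak cross-block contact.
twoBlockMap <- function(n, k, within = 10, across = 0.5) {
    A <- matrix(across, n, n)
    A[1:k, 1:k] <- within
    A[(k + 1):n, (k + 1):n] <- within
    ij <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    m <- contactMap(toyGenome(n),
                    data.frame(bin1 = ij[, 1], bin2 = ij[, 2],
                               count = A[ij]))
    m@weights <- rep(1, n)
    m
}

test_that("insulation is flat on translation-invariant maps and matches the diamond oracle", {
    n <- 30L
    A <- outer(1:n, 1:n, function(i, j) 5 / (abs(i - j) + 1))
    ij <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    m <- contactMap(toyGenome(n),
                    data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = A[ij]))
    m@weights <- rep(1, n)
    tr <- insulationScore(m, w = 5)
    v <- values(tr)
    expect_equal(v[6:25], rep(0, 20), tolerance = 1e-12)
    expect_true(all(is.na(v[c(1:5, 26:30)])))

    mb <- twoBlockMap(30, 15)
    tr2 <- insulationScore(mb, w = 3)
    raws <- bruteDiamond(denseFromMap(mb, balanced = TRUE), 3)
    med <- median(raws, na.rm = TRUE)
    expect_equal(values(tr2), log2(raws / med), tolerance = 1e-12)
    # minimum sits where the blocks meet
    expect_equal(which.min(values(tr2)), 15L)
})

test_that("insulation is invariant to uniform map rescaling", {
    m <- balancedToyMap(40, density = 0.8, seed = 6)
    m10 <- m
    m10@pixels$count <- m10@pixels$count * 10
    expect_equal(values(insulationScore(m)), values(insulationScore(m10)),
                 tolerance = 1e-12)
})

test_that("boundary detection filters by prominence and handles monotone tracks", {
    bt <- toyGenome(60)
    # constructed track: deep minimum (prominence 0.5) at 20, shallow
    # dimple (0.05) at 40
    v <- rep(0.6, 60)
    v[14:26] <- 0.6 - 0.5 * (1 - abs(seq(-6, 6) / 6))
    v[38:42] <- 0.6 - 0.05 * (1 - abs(seq(-2, 2) / 2))
    tr <- scoreTrack(bt, v, kind = "insulation", channel = "cis_pooled")
    b <- findBoundaries(tr, minProminence = 0.3)
    expect_equal(boundaryBins(b), 20L)
    expect_equal(prominences(b), 0.5, tolerance = 1e-12)
    # monotone track: no boundaries, not an error
    mono <- scoreTrack(bt, seq(0, 3, length.out = 60), kind = "insulation",
                       channel = "cis_pooled")
    expect_length(boundaryBins(findBoundaries(mono, 0.1)), 0L)
    # boundary count is monotone non-increasing in the cutoff
    set.seed(5)
    noisy <- scoreTrack(bt, cumsum(rnorm(60, 0, 0.3)), kind = "insulation",
                        channel = "cis_pooled")
    counts <- vapply(c(0.05, 0.2, 0.5, 1),
                     function(p) length(boundaryBins(findBoundaries(noisy, p))),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("default cutoffs depend on the source channel", {
    bt <- toyGenome(40)
    v <- rep(1, 40); v[18:22] <- c(0.9, 0.85, 0.8, 0.85, 0.9)
    mkTrack <- function(ch) scoreTrack(bt, v, kind = "insulation",
                                       channel = ch)
    # prominence 0.2: kept at the reference default (0.1), dropped at the
    # allele-resolved default (0.3)
    expect_length(boundaryBins(findBoundaries(mkTrack("reference_pooled"))), 1L)
    expect_length(boundaryBins(findBoundaries(mkTrack("thom"))), 0L)
    expect_length(boundaryBins(findBoundaries(mkTrack("cis_maternal"))), 0L)
})

test_that("boundaries adjacent to masked bins are removed", {
    bt <- toyGenome(40)
    v <- rep(1, 40); v[20] <- 0.2
    tr <- scoreTrack(bt, v, kind = "insulation", channel = "cis_pooled")
    mask <- rep(FALSE, 40)
    expect_equal(boundaryBins(findBoundaries(tr, 0.3, mask = mask)), 20L)
    mask[21] <- TRUE
    expect_length(boundaryBins(findBoundaries(tr, 0.3, mask = mask)), 0L)
})

test_that("boundary overlap matches a brute-force matching oracle", {
    bt <- toyGenome(200)
    mkSet <- function(bins) new("BoundarySet", binTable = bt,
                                bins = as.integer(sort(bins)),
                                prominence = rep(1, length(bins)),
                                cutoff = 0.3, channel = "cis_pooled")
    a <- mkSet(c(10L)); b4 <- mkSet(c(14L)); b5 <- mkSet(c(15L))
    expect_equal(boundaryOverlap(a, b4, 4)$fractionA, 1)
    expect_equal(boundaryOverlap(a, b5, 4)$fractionA, 0)
    idSet <- mkSet(c(5, 50, 100))
    ov <- boundaryOverlap(idSet, idSet, 4)
    expect_equal(ov$fractionA, 1); expect_equal(ov$fractionB, 1)
    # tolerance 0 equals exact intersection
    s1 <- mkSet(c(5, 50, 100, 150)); s2 <- mkSet(c(5, 51, 100, 170))
    expect_equal(boundaryOverlap(s1, s2, 0)$fractionA, 0.5)
    # random sets vs exhaustive maximum matching
    for (seed in 1:5) {
        set.seed(seed)
        x <- sort(sample(1:200, 8)); y <- sort(sample(1:200, 6))
        ov <- boundaryOverlap(mkSet(x), mkSet(y), 4)
        expect_equal(ov$nMatched, bruteMatch(x, y, 4),
                     label = sprintf("seed %d", seed))
    }
    # empty set: undefined fractions, flagged
    empty <- new("BoundarySet", binTable = bt, bins = integer(0),
                 prominence = numeric(0), cutoff = 0.3,
                 channel = "cis_pooled")
    ovE <- boundaryOverlap(empty, idSet, 4)
    expect_true(is.na(ovE$fractionA) && ovE$flagged)
})

test_that("boundaries are not matched across chromosomes", {
    bt <- binnedGenome(c(chr1 = 40000, chr2 = 40000), 4000)
    a <- new("BoundarySet", binTable = bt, bins = 10L, prominence = 1,
             cutoff = 0.3, channel = "cis_pooled")
    b <- new("BoundarySet", binTable = bt, bins = 11L, prominence = 1,
             cutoff = 0.3, channel = "cis_pooled")
    # bin 10 is the last bin of chr1, bin 11 the first of chr2
    expect_equal(boundaryOverlap(a, b, 4)$fractionA, 0)
})

test_that("interval overlap fraction counts boundary bins touching peaks", {
    bt <- toyGenome(100)
    bset <- new("BoundarySet", binTable = bt,
                bins = c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L, 95L),
                prominence = rep(1, 10), cutoff = 0.3,
                channel = "cis_pooled")
    si <- GenomeInfoDb::seqinfo(bins(bt))
    genome <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 400000),
                                     seqinfo = si)
    expect_equal(intervalOverlapFraction(bset, genome), 1)
    none <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10),
                                   seqinfo = si)
    expect_equal(intervalOverlapFraction(bset, none), 0)
    # hand-placed peaks over bins 10, 20 and 95 -> 3/10
    peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(37000, 77000, 377000), end = c(38000, 78500, 380000)),
        seqinfo = si)
    expect_equal(intervalOverlapFraction(bset, peaks), 0.3)
})
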