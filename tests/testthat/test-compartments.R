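test_that("checkerboard maps yield the block-label eigenvector, sign-oriented", {
    n <- 40L
    labels <- rep(c(1, -1), each = 4, length.out = n)
    # balanced checkerboard: matched labels interact more
    A <- 2 + 0.8 * outer(labels, labels)
    ij <- which(upper.tri(A, diag = TRUE), arr.ind = TRUE)
    m <- contactMap(toyGenome(n),
                    data.frame(bin1 = ij[, 1], bin2 = ij[, 2], count = A[ij]))
    m@weights <- rep(1, n)
    genes <- scoreTrack(m@binTable, ifelse(labels > 0, 5, 0),
                        kind = "gene_count")
    ev <- compartmentEigenvector(m, genes)
    v <- values(ev$track)
    expect_equal(sign(v), labels)
    expect_gt(ev$info$chr1$correlation, 0.95)
    # anti-correlated gene track flips the orientation
    genesFlip <- scoreTrack(m@binTable, ifelse(labels > 0, 0, 5),
                            kind = "gene_count")
    v2 <- values(compartmentEigenvector(m, genesFlip)$track)
    expect_equal(sign(v2), -labels)
    # selection invariant under positive rescaling of the gene track
    genes10 <- scoreTrack(m@binTable, 10 * values(genes), kind = "gene_count")
    expect_equal(values(compartmentEigenvector(m, genes10)$track), v,
                 tolerance = 1e-12)
})

test_that("synthetic compartment labels are recovered by the eigenvector", {
    cfg <- simulationConfig(chromLength = 4e6, binSize = 8000, depth = 4e6,
                            plaidStrength = 1.6, looseProb = 0, seed = 12)
    sim <- simulateDiploidMaps(cfg)
    ref <- iterativeCorrection(poolMaps(list(sim$cis_maternal,
                                             sim$cis_paternal)))
    truthLab <- ifelse(sim$truth$compartments == "A", 1, -1)
    genes <- scoreTrack(ref@binTable,
                        ifelse(truthLab > 0, 4, 0.5), kind = "gene_count")
    ev <- compartmentEigenvector(ref, genes)
    v <- values(ev$track)
    ok <- !is.na(v)
    expect_gt(abs(cor(v[ok], truthLab[ok])), 0.95)
})

test_that("track correlation reproduces the rank formula and flags constants", {
    bt <- toyGenome(20)
    set.seed(2)
    x <- rnorm(20); y <- x + rnorm(20, 0, 0.5)
    ta <- scoreTrack(bt, x); tb <- scoreTrack(bt, y)
    res <- trackCorrelation(ta, tb)
    # Spearman rho by the rank formula, no ties: 1 - 6*sum(d^2)/(n(n^2-1))
    d <- rank(x) - rank(y)
    expect_equal(res$rho, 1 - 6 * sum(d^2) / (20 * 399), tolerance = 1e-12)
    expect_equal(trackCorrelation(ta, ta)$rho, 1)
    tneg <- scoreTrack(bt, -x)
    expect_equal(trackCorrelation(ta, tneg)$rho, -1)
    const <- scoreTrack(bt, rep(1, 20))
    expect_true(trackCorrelation(ta, const)$flagged)
})

test_that("quadrant fractions sum to one and match hand counts", {
    bt <- toyGenome(10)
    ps <- scoreTrack(bt, c(1, 1, 1, -2, -2, 1, -2, 1, 1, -2), kind = "PS")
    ex <- scoreTrack(bt, c(5, 0, 5, 5, 0, 0, 0, 5, 0, 5), kind = "expression")
    q <- quadrantFractions(ps, 0, ex, 1)
    expect_equal(unname(q), c(3, 3, 2, 2) / 10)
    expect_equal(sum(q), 1)
    allTight <- quadrantFractions(scoreTrack(bt, rep(1, 10)), 0,
                                  scoreTrack(bt, rep(9, 10)), 1)
    expect_equal(unname(allTight), c(1, 0, 0, 0))
})

test_that("Mood's median test matches the closed form and a chi-square oracle", {
    # counts [[30,10],[10,30]] -> chisq = 20 by N(ad-bc)^2/prod(margins)
    x <- c(rep(1, 30), rep(-1, 10))
    y <- c(rep(1, 10), rep(-1, 30))
    mt <- moodMedianTest(x, y)
    expect_equal(mt$chisq, 20)
    expect_equal(unname(mt$table), matrix(c(30, 10, 10, 30), 2))
    expect_equal(mt$pValue, stats::pchisq(20, 1, lower.tail = FALSE))
    # identical samples: chi-square 0, p ~ 1
    mt0 <- moodMedianTest(x, x)
    expect_equal(mt0$chisq, 0)
    expect_equal(mt0$pValue, 1)
    # agreement with the standard chi-square implementation, and power
    set.seed(7)
    a <- rnorm(500); b <- rnorm(500, 1)
    mt2 <- moodMedianTest(a, b)
    med <- median(c(a, b))
    tab <- rbind(c(sum(a > med), sum(b > med)),
                 c(sum(a <= med), sum(b <= med)))
    or <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mt2$chisq, unname(or$statistic), tolerance = 1e-12)
    expect_equal(mt2$pValue, or$p.value, tolerance = 1e-12)
    expect_lt(mt2$pValue, 1e-6)
})

test_that("chromatin-state association tests states against the reference", {
    bt <- toyGenome(600)
    set.seed(3)
    v <- rnorm(600)
    v[1:200] <- v[1:200] - 1.5          # "black" chromatin: low PS
    ps <- scoreTrack(bt, v, kind = "PS")
    si <- GenomeInfoDb::seqinfo(bins(bt))
    states <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(1, 800001, 1600001) , end = c(800000, 1600000, 2400000)),
        seqinfo = si)
    S4Vectors::mcols(states)$state <- c("black", "yellow", "yellow2")
    res <- chromatinStateAssociation(ps, states, "yellow")
    expect_setequal(res$tests$state, c("black", "yellow2"))
    expect_lt(res$tests$pValue[res$tests$state == "black"], 1e-6)
    expect_gt(res$tests$pValue[res$tests$state == "yellow2"], 0.01)
    # small states are excluded with a warning
    S4Vectors::mcols(states)$state <- c("black", "yellow", "tiny")
    states2 <- c(states[1:2],
                 GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(1600001, 1604000),
                                        seqinfo = si))
    S4Vectors::mcols(states2)$state <- c("black", "yellow", "tiny")
    expect_warning(chromatinStateAssociation(ps, states2, "yellow"), "tiny")
})

test_that("loop quantitation equals brute-force window sums", {
    m <- balancedToyMap(60, density = 0.7, seed = 17)
    A <- denseFromMap(m, balanced = TRUE)
    A[is.na(A)] <- 0
    # 5-bin window (20 kb at 4 kb bins), offsets -2..+2 around the anchor
    loops <- data.frame(chrom1 = "chr1", pos1 = c(10, 30) * 4000,
                        chrom2 = "chr1", pos2 = c(40, 50) * 4000)
    out <- loopQuantitation(m, loops, window = 20000)
    for (k in 1:2) {
        rows <- (loops$pos1[k] / 4000 + 1) + (-2:2)
        cols <- (loops$pos2[k] / 4000 + 1) + (-2:2)
        expect_equal(out$signal[k], sum(A[rows, cols]), tolerance = 1e-12)
    }
    expect_false(any(out$truncated))
    # zero matrix gives zero; single pixel gives its balanced value
    z <- contactMap(m@binTable, data.frame(bin1 = 31L, bin2 = 51L, count = 2))
    z@weights <- rep(0.5, 60)
    outz <- loopQuantitation(z, loops, window = 20000)
    expect_equal(outz$signal, c(0, 2 * 0.5 * 0.5))
    # window truncation at the chromosome end is flagged
    edge <- data.frame(chrom1 = "chr1", pos1 = 4000, chrom2 = "chr1",
                       pos2 = 59 * 4000)
    expect_true(loopQuantitation(m, edge, window = 20000)$truncated)
    bad <- data.frame(chrom1 = "chrX", pos1 = 0, chrom2 = "chr1", pos2 = 0)
    expect_error(loopQuantitation(m, bad, window = 20000), "off the assembly")
})

test_that("disomy closed form round-trips exactly", {
    expect_equal(disomyFraction(c(1, 1), c(1, 1))$x, 0)
    est <- disomyFraction(rep(1.5, 10), rep(1, 10))
    expect_equal(est$r, 1.5); expect_equal(est$x, 0.2)
    # x -> r -> x round trip exact over [0, 0.99]
    x <- seq(0, 0.99, by = 0.01)
    r <- disomyRatio(x)
    expect_equal((r - 1) / (r + 1), x, tolerance = 1e-12)
    # swapped homolog roles are detected and recorded
    sw <- disomyFraction(rep(1, 5), rep(2, 5))
    expect_true(sw$swapped)
    expect_equal(sw$r, 2)
})
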