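test_that("EM recovers a known mixture and agrees with the grid threshold oracle", {
    x <- simulatePsSample(c(0.3, 0.7), c(-2, 0), c(0.6, 0.5), 1e5, seed = 42)
    fit <- fitTwoGaussians(x, clipFloor = -30)
    expect_equal(fit@weights, c(0.3, 0.7), tolerance = 0.05)
    expect_equal(fit@means, c(-2, 0), tolerance = 0.05)
    expect_equal(fit@sds, c(0.6, 0.5), tolerance = 0.05)
    expect_false(fit@flagged)
    # quadratic-root threshold equals a dense-grid density-crossing oracle
    th <- intersectionThreshold(fit)
    thGrid <- gridIntersection(fit@weights, fit@means, fit@sds,
                               fit@means[1], fit@means[2])
    expect_equal(th, thGrid, tolerance = 1e-5)
    expect_gt(th, fit@means[1]); expect_lt(th, fit@means[2])
    # and against the analytic root of the construction itself
    thTrue <- gridIntersection(c(0.3, 0.7), c(-2, 0), c(0.6, 0.5), -2, 0)
    expect_equal(th, thTrue, tolerance = 0.05)
})

test_that("EM agrees with an independent mixture implementation (mclust)", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))   # Mclust needs its namespace attached
    x <- simulatePsSample(c(0.4, 0.6), c(-1.5, 0.2), c(0.4, 0.3), 2e4,
                          seed = 9)
    fit <- fitTwoGaussians(x, clipFloor = -30)
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    ord <- order(mc$parameters$mean)
    expect_equal(fit@means, unname(mc$parameters$mean[ord]), tolerance = 0.02)
    expect_equal(fit@weights, mc$parameters$pro[ord], tolerance = 0.02)
    expect_equal(fit@sds,
                 unname(sqrt(mc$parameters$variance$sigmasq[ord])),
                 tolerance = 0.02)
})

test_that("equal weights and sds give the midpoint threshold exactly", {
    fit <- new("GaussianMixtureFit", weights = c(0.5, 0.5),
               means = c(-1.2, 0.4), sds = c(0.3, 0.3), clipFloor = -3,
               threshold = NA_real_, logLik = 0, converged = TRUE,
               flagged = FALSE, nobs = 1000L)
    expect_equal(intersectionThreshold(fit), (-1.2 + 0.4) / 2)
})

test_that("values below the clip floor are winsorized before fitting", {
    set.seed(8)
    x <- c(rnorm(3000, 0, 0.3), rnorm(1000, -2, 0.3), rnorm(200, -40, 1))
    fit <- fitTwoGaussians(x, clipFloor = -3)
    expect_gte(fit@means[1], -3)     # outliers pulled to the floor
    f2 <- fitTwoGaussians(x)         # the default floor is -3
    expect_equal(fit@means, f2@means)
})

test_that("a single-Gaussian sample yields a flagged near-degenerate fit", {
    set.seed(1)
    x <- rnorm(5000, 0, 0.4)
    fit <- tryCatch(fitTwoGaussians(x, clipFloor = -30),
                    error = function(e) NULL)
    if (!is.null(fit)) expect_true(fit@flagged)
})

test_that("bin classification applies a strict-below rule at the threshold", {
    bt <- toyGenome(5)
    ps <- scoreTrack(bt, c(-1, -0.71, -0.7099, NA, 2), kind = "PS")
    lab <- classifyBins(ps, -0.71)
    expect_identical(lab, c("loose", "tight", "tight", NA, "tight"))
    expect_identical(unique(classifyBins(ps, -5)[c(1:3, 5)]), "tight")
})

test_that("region classification follows the 25% rule and merges across boundary bins", {
    # 50-bin chromosome, boundaries at 11, 21, 31, 41: five 10-bin regions
    bt <- toyGenome(50)
    bnd <- new("BoundarySet", binTable = bt,
               bins = c(11L, 21L, 31L, 41L), prominence = rep(1, 4),
               cutoff = 0.3, channel = "reference_pooled")
    lab <- rep("tight", 50)
    lab[12:20] <- "loose"            # region 2: 9/10 loose
    lab[23:25] <- "loose"            # region 3: 3/10 loose -> loose (0.3)
    lab[44] <- "loose"               # region 5: 1/10 -> tight
    # boundary bin 21 is tight -> regions 2 and 3 both loose but NOT merged
    rs <- classifyRegions(lab, bnd, looseCutoff = 0.25)
    mc <- S4Vectors::mcols(regions(rs))
    expect_identical(mc$label, c("tight", "loose", "loose", "tight"))
    # regions 4 and 5 are tight with tight boundary bin 41: merged
    expect_equal(BiocGenerics::start(regions(rs)),
                 (c(1, 11, 21, 31) - 1) * 4000 + 1)
    # now make boundary bin 21 loose: regions 2+3 merge into one
    lab[21] <- "loose"
    rs2 <- classifyRegions(lab, bnd, looseCutoff = 0.25)
    expect_identical(S4Vectors::mcols(regions(rs2))$label,
                     c("tight", "loose", "tight"))
    # direct rule: 0 loose -> tight, 3/10 loose -> loose
    expect_identical(S4Vectors::mcols(regions(rs))$label[1], "tight")
    expect_equal(S4Vectors::mcols(regions(rs))$looseFraction[3], 0.3)
})

test_that("region classification is idempotent and tiles the genome", {
    set.seed(14)
    bt <- toyGenome(200)
    bnd <- new("BoundarySet", binTable = bt,
               bins = sort(sample(5:195, 12)), prominence = rep(1, 12),
               cutoff = 0.3, channel = "reference_pooled")
    lab <- sample(c("tight", "loose", NA), 200, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
    rs <- classifyRegions(lab, bnd)
    expect_equal(sum(IRanges::width(regions(rs))), 200 * 4000)
    expect_true(all(diff(BiocGenerics::start(regions(rs))) > 0))
    # re-deriving boundaries from the merged regions and re-classifying
    # changes nothing (merge fixpoint)
    starts <- BiocGenerics::start(regions(rs))
    bnd2 <- new("BoundarySet", binTable = bt,
                bins = as.integer((starts[-1] - 1L) %/% 4000 + 1L),
                prominence = rep(1, length(starts) - 1L), cutoff = 0.3,
                channel = "reference_pooled")
    rs2 <- classifyRegions(lab, bnd2)
    expect_identical(S4Vectors::mcols(regions(rs2))$label,
                     S4Vectors::mcols(regions(rs))$label)
    expect_equal(BiocGenerics::start(regions(rs2)),
                 BiocGenerics::start(regions(rs)))
})

test_that("size-class selection keeps half-open [lo, hi) lengths", {
    bt <- toyGenome(200)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(1, 300001, 700001),
        end = c(300000, 700000, 800000)),
        seqinfo = GenomeInfoDb::seqinfo(bins(bt)))
    S4Vectors::mcols(gr)$label <- c("tight", "loose", "tight")
    S4Vectors::mcols(gr)$looseFraction <- c(0, 1, 0)
    rs <- new("PairingRegionSet", binTable = bt, regions = gr, cutoff = 0.25)
    kept <- selectRegionsBySize(rs, c(200e3, 400e3))
    # the 400 kb region is excluded by the half-open upper limit
    expect_equal(IRanges::width(regions(kept)), 300000)
    expect_length(regions(selectRegionsBySize(rs, c(1e6, 2e6))), 0L)
})

test_that("threshold recovery is stable across seeded replicates", {
    thTrue <- gridIntersection(c(0.3, 0.7), c(-2, 0), c(0.6, 0.5), -2, 0)
    err <- vapply(1:5, function(s) {
        x <- simulatePsSample(c(0.3, 0.7), c(-2, 0), c(0.6, 0.5), 2e4,
                              seed = s)
        abs(fitTwoGaussians(x, clipFloor = -30)@threshold - thTrue)
    }, numeric(1))
    expect_true(all(err <= 0.08))
})
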