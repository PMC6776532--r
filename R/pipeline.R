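#' @include simulate.R balancing.R pairing.R classify.R insulation.R
#' @include scaling.R compartments.R
NULL

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end analysis. All
#' randomness flows from the single root \code{seed}.
#'
#' @param sim a \code{\link{simulationConfig}} describing the synthetic
#'   input (its seed is overridden by the root seed).
#' @param window PS/CS window half-width in bins (default 3).
#' @param insulationW insulation flank width in bins (default 5).
#' @param prominenceRef boundary prominence cutoff for the reference
#'   channel (default 0.1).
#' @param prominenceAllele cutoff for haplotype-resolved channels
#'   (default 0.3).
#' @param clipFloor PS winsorization floor for the mixture fit
#'   (default -3).
#' @param looseCutoff loose-bin fraction for region classification
#'   (default 0.25).
#' @param replicates bootstrap replicates for APS tests (default 1000).
#' @param coarsenFactor bin coarsening factor for the compartment
#'   eigendecomposition (default 8).
#' @param madMax,tol balancing parameters (see
#'   \code{\link{iterativeCorrection}}).
#' @param boundaryTolerance bin tolerance for boundary matching
#'   (default 4).
#' @param seed root integer seed.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simulationConfig(), window = 3L,
                           insulationW = 5L, prominenceRef = 0.1,
                           prominenceAllele = 0.3, clipFloor = -3,
                           looseCutoff = 0.25, replicates = 1000L,
                           coarsenFactor = 8L, madMax = 5, tol = 1e-6,
                           boundaryTolerance = 4L, seed = 1L) {
    stopifnot(window >= 0L, insulationW >= 1L, prominenceRef >= 0,
              prominenceAllele >= 0, looseCutoff >= 0, looseCutoff <= 1,
              replicates >= 1L, coarsenFactor >= 1L)
    structure(as.list(environment()), class = "PipelineConfig")
}

# Expand a coarse-grid track back onto the fine grid.
.expandTrack <- function(coarseTrack, fineBt, factor) {
    cb <- coarseTrack@binTable
    b <- fineBt@bins
    idx <- .binIndexOf(cb, as.character(GenomicRanges::seqnames(b)),
                       ((BiocGenerics::start(b) - 1L) %/%
                        (cb@binSize)) * cb@binSize)
    scoreTrack(fineBt, coarseTrack@values[idx], kind = coarseTrack@kind)
}

#' Run the full homolog-pairing analysis on synthetic diploid maps
#'
#' Chains simulate, balance, pairing/cis scores, two-Gaussian
#' classification, insulation and boundaries, region classification,
#' scaling curves, compartment eigenvector and the pairing summaries, and
#' (optionally) writes all stage outputs plus a machine-readable summary.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (\code{NULL}: nothing is written).
#' @return list with \code{summary} (named list of headline quantities) and
#'   the intermediate objects (\code{maps}, \code{tracks}, \code{fit},
#'   \code{regions}, \code{boundaries}, \code{curves}, \code{truth}).
#' @export
runPairingPipeline <- function(config = pipelineConfig(), outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    simcfg <- config$sim
    simcfg$seed <- config$seed
    sim <- stage("simulate", simulateDiploidMaps(simcfg))
    truth <- sim$truth
    bt <- truth$binTable

    cisPooled <- poolMaps(list(sim$cis_maternal, sim$cis_paternal),
                          "cis_pooled")
    reference <- poolMaps(list(sim$cis_maternal, sim$cis_paternal, sim$thom),
                          "reference_pooled")
    bal <- function(m) iterativeCorrection(m, madMax = config$madMax,
                                           tol = config$tol)
    thom <- stage("balance", bal(sim$thom))
    cisPooled <- stage("balance", bal(cisPooled))
    reference <- stage("balance", bal(reference))

    ps <- stage("ps", pairingScore(thom, W = config$window))
    cs <- stage("cs", pairingScore(cisPooled, W = config$window))
    fit <- stage("classify", fitTwoGaussians(ps, clipFloor = config$clipFloor))
    binLabels <- classifyBins(ps, fit@threshold)

    insRef <- stage("insulation", insulationScore(reference,
                                                  w = config$insulationW))
    bndRef <- findBoundaries(insRef, minProminence = config$prominenceRef,
                             mask = binMask(reference))
    insCis <- insulationScore(cisPooled, w = config$insulationW)
    bndCis <- findBoundaries(insCis, minProminence = config$prominenceAllele,
                             mask = binMask(cisPooled))
    insThom <- insulationScore(thom, w = config$insulationW)
    bndThom <- findBoundaries(insThom, minProminence = config$prominenceAllele,
                              mask = binMask(thom))
    ovl <- boundaryOverlap(bndCis, bndThom,
                           tolerance = config$boundaryTolerance)

    regionSet <- stage("regions", classifyRegions(binLabels, bndRef,
                                                  looseCutoff = config$looseCutoff))

    curveCis <- stage("scaling", contactFrequencyCurve(cisPooled))
    curveThom <- contactFrequencyCurve(thom)
    curveRatio <- ratioCurve(curveThom, curveCis)
    regionCurves <- suppressWarnings(
        regionRestrictedCurves(cisPooled, regionSet))

    coarse <- stage("compartments", {
        cm <- coarsenMap(reference, config$coarsenFactor)
        iterativeCorrection(cm, madMax = config$madMax, tol = config$tol)
    })
    geneTrack <- .withSeed(config$seed + 1L, {
        f <- config$coarsenFactor
        nFine <- length(truth$compartments)
        grp <- (seq_len(nFine) - 1L) %/% f
        fracA <- tapply(truth$compartments == "A", grp, mean)
        lam <- ifelse(fracA >= 0.5, 4, 0.5)
        scoreTrack(coarse@binTable, stats::rpois(length(lam), lam),
                   kind = "gene_count")
    })
    ev <- compartmentEigenvector(coarse, geneTrack)
    evFine <- .expandTrack(ev$track, bt, config$coarsenFactor)
    psEvCor <- tryCatch(trackCorrelation(ps, evFine),
                        error = function(e) list(rho = NA, pValue = NA))
    quad <- tryCatch(quadrantFractions(ps, fit@threshold, evFine, 0),
                     error = function(e) rep(NA_real_, 4))

    aps <- stage("aps", aggregatedPairingScore(ps, cs))

    # truth-based recovery metrics
    okBins <- !is.na(binLabels) & !is.na(truth$binLabels)
    labelAccuracy <- mean(binLabels[okBins] == truth$binLabels[okBins])
    truthBnd <- new("BoundarySet", binTable = bt,
                    bins = as.integer(truth$boundaries),
                    prominence = rep(Inf, length(truth$boundaries)),
                    cutoff = 0, channel = "reference_pooled")
    rec <- boundaryOverlap(truthBnd, bndRef, tolerance = 1L)
    regionTruth <- .regionAgreement(regionSet, truth)

    covM <- .rawCoverage(sim$cis_maternal)
    covP <- .rawCoverage(sim$cis_paternal)
    disomy <- disomyFraction(covM, covP)

    labTab <- table(factor(binLabels, levels = c("tight", "loose")),
                    useNA = "always")
    nb <- length(binLabels)
    summary <- list(
        seed = config$seed,
        n_bins = nb,
        bin_size = simcfg$binSize,
        aps = aps,
        threshold = fit@threshold,
        mixture = list(weights = fit@weights, means = fit@means,
                       sds = fit@sds),
        fraction_tight_bins = unname(labTab["tight"]) / nb,
        fraction_loose_bins = unname(labTab["loose"]) / nb,
        fraction_missing_bins =
            unname(labTab[is.na(names(labTab))]) / nb,
        label_accuracy = labelAccuracy,
        region_agreement = regionTruth,
        n_boundaries_reference = length(bndRef@bins),
        boundary_recall = rec$fractionA,
        boundary_precision = rec$fractionB,
        boundary_overlap_cis_in_thom = ovl$fractionA,
        boundary_overlap_thom_in_cis = ovl$fractionB,
        ps_eigenvector_spearman = psEvCor$rho,
        quadrant_fractions = as.list(quad),
        disomy_r = disomy$r,
        disomy_x = disomy$x,
        parameters = list(window = config$window,
                          insulationW = config$insulationW,
                          prominenceRef = config$prominenceRef,
                          prominenceAllele = config$prominenceAllele,
                          clipFloor = config$clipFloor,
                          looseCutoff = config$looseCutoff,
                          madMax = config$madMax, tol = config$tol))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeTrackBedGraph(ps, file.path(outDir, "ps.bedGraph"))
        writeTrackBedGraph(cs, file.path(outDir, "cs.bedGraph"))
        writeTrackBedGraph(insRef, file.path(outDir, "insulation.bedGraph"))
        writeBoundariesBed(bndRef, file.path(outDir, "boundaries.bed"))
        writeRegionsBed(regionSet, file.path(outDir, "regions.bed"))
        writeCurve(curveCis, file.path(outDir, "scaling_cis.tsv"))
        writeCurve(curveThom, file.path(outDir, "scaling_thom.tsv"))
        writeCurve(curveRatio, file.path(outDir, "scaling_ratio.tsv"))
        writeContactMap(sim$thom, file.path(outDir, "thom.tsv"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE)
    }
    list(summary = summary, maps = list(thom = thom, cis_pooled = cisPooled,
                                        reference = reference),
         tracks = list(ps = ps, cs = cs, insulation = insRef,
                       eigenvector = evFine),
         fit = fit, binLabels = binLabels, regions = regionSet,
         boundaries = list(reference = bndRef, cis = bndCis, thom = bndThom),
         curves = list(cis = curveCis, thom = curveThom, ratio = curveRatio,
                       byRegion = regionCurves),
         truth = truth)
}

# Fraction of bins whose region-level label agrees with the planted
# domain pairing label.
.regionAgreement <- function(regionSet, truth) {
    n <- length(truth$binLabels)
    dom <- findInterval(seq_len(n), truth$domainStarts)
    truthLab <- truth$regionLabels[dom]
    gr <- regionSet@regions
    lab <- S4Vectors::mcols(gr)$label
    bs <- regionSet@binTable@binSize
    predLab <- rep(NA_character_, n)
    for (k in seq_along(gr)) {
        lo <- (BiocGenerics::start(gr)[k] - 1L) %/% bs + 1L
        hi <- (BiocGenerics::end(gr)[k] - 1L) %/% bs + 1L
        predLab[lo:hi] <- lab[k]
    }
    ok <- !is.na(predLab) & predLab != "missing"
    mean(predLab[ok] == truthLab[ok])
}

# Raw per-bin coverage (marginals including diagonal) of a map.
.rawCoverage <- function(map) {
    px <- map@pixels
    nb <- nbins(map)
    cov <- numeric(nb)
    t1 <- rowsum(px$count, px$bin1)
    t2 <- rowsum(px$count[px$bin1 != px$bin2], px$bin2[px$bin1 != px$bin2])
    cov[as.integer(rownames(t1))] <- cov[as.integer(rownames(t1))] + t1[, 1L]
    if (nrow(t2))
        cov[as.integer(rownames(t2))] <- cov[as.integer(rownames(t2))] + t2[, 1L]
    cov
}
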