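#' @include contactMap.R
NULL

# Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Configuration for the synthetic diploid contact-map generator
#'
#' The generator emulates the hallmarks of a haplotype-resolved fly Hi-C
#' map: power-law distance decay, domains with insulating boundaries, an
#' A/B compartment plaid, and a trans-homolog (thom) channel whose
#' near-diagonal signal is enriched in tightly paired regions and depleted
#' inside loosely paired regions while preserved at region boundaries.
#'
#' Cis expected counts are
#' \code{lambda_cis(i,j) = C * max(s,1)^(-alpha) * domain * plaid}, where
#' \code{s} is the separation in bins, the domain factor is
#' \code{insulationDepletion} for pairs crossing a boundary (1 within a
#' domain) and the plaid factor is \code{plaidStrength} when the two bins'
#' compartment labels match. When \code{alphaShallow} is set, within-domain
#' decay is two-regime: inside tight domains the exponent is
#' \code{alphaShallow} up to \code{tightDomainScale} and \code{alpha}
#' beyond (continuous at the change point), while loose domains decay with
#' the shallow exponent throughout their span (a single larger domain
#' lacking internal structure). The thom channel is
#' \code{lambda_cis * tightEnrichment}, additionally multiplied by
#' \code{looseDepletion} when both bins are loosely paired and
#' \code{s < looseScale}; boundary-adjacent bins keep the tight factor.
#' Both cis channels share \code{lambda_cis} (homologs are structurally
#' concordant) but are sampled independently; counts are Poisson.
#'
#' @param chromLength chromosome length in bp (default 20 Mb).
#' @param binSize bin size in bp (default 4 kb).
#' @param alpha power-law decay exponent (default 1).
#' @param alphaShallow optional shallow within-domain exponent
#'   (default \code{NA}: single-regime decay).
#' @param tightDomainScale change-point scale in bp for the shallow mode
#'   inside tight domains (default 30 kb; used only with
#'   \code{alphaShallow}).
#' @param boundaries integer bin indices of domain starts (excluding bin 1),
#'   or \code{NULL} to draw domain sizes uniformly between
#'   \code{minDomainBins} and \code{maxDomainBins}.
#' @param minDomainBins,maxDomainBins domain-size range in bins when
#'   boundaries are generated (defaults 40 and 100, i.e. 160-400 kb at
#'   4 kb bins).
#' @param insulationDepletion cross-boundary contact multiplier in (0,1]
#'   (default 0.3).
#' @param compartmentLabels per-domain labels in \{"A","B"\} or \code{NULL}
#'   to draw them (P(A) = 0.5).
#' @param plaidStrength matched-compartment contact multiplier >= 1
#'   (default 1.6).
#' @param pairingLabels per-domain labels in \{"tight","loose"\} or
#'   \code{NULL} to draw them.
#' @param looseProb overall probability that a generated domain is loose
#'   (default 0.35). Pairing is compartment-linked: B-type domains are
#'   five times more likely to be loose than A-type domains (active
#'   compartments pair almost exclusively tightly), with the overall rate
#'   kept at \code{looseProb}.
#' @param tightEnrichment thom/cis ratio where both bins are tightly paired
#'   (default 0.7).
#' @param looseDepletion additional thom multiplier in [0,1) inside loose
#'   regions below \code{looseScale} (default 0.15).
#' @param looseScale separation below which the loose depletion applies, in
#'   bp (default 100 kb).
#' @param depth expected total cis read count per channel (default 1e7).
#' @param seed integer seed.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(chromLength = 20e6, binSize = 4000, alpha = 1,
                             alphaShallow = NA_real_, tightDomainScale = 30e3,
                             boundaries = NULL, minDomainBins = 40L,
                             maxDomainBins = 100L, insulationDepletion = 0.3,
                             compartmentLabels = NULL, plaidStrength = 1.6,
                             pairingLabels = NULL, looseProb = 0.35,
                             tightEnrichment = 0.7, looseDepletion = 0.15,
                             looseScale = 1e5, depth = 1e7, seed = 1L) {
    stopifnot(chromLength >= binSize, binSize >= 1,
              insulationDepletion > 0, insulationDepletion <= 1,
              plaidStrength >= 1, tightEnrichment > 0,
              looseDepletion >= 0, looseDepletion < 1, depth > 0)
    if (!is.null(boundaries)) {
        boundaries <- as.integer(boundaries)
        if (is.unsorted(boundaries, strictly = TRUE) ||
            any(boundaries < 2L |
                boundaries > ceiling(chromLength / binSize)))
            stop("boundaries must be sorted bin indices inside the chromosome")
    }
    structure(as.list(environment()), class = "SimulationConfig")
}

# Resolve generated layout pieces (boundaries, labels) under the seed.
.resolveLayout <- function(config) {
    n <- as.integer(ceiling(config$chromLength / config$binSize))
    .withSeed(config$seed, {
        b <- config$boundaries
        if (is.null(b)) {
            pos <- 1L; b <- integer(0)
            repeat {
                step <- sample(config$minDomainBins:config$maxDomainBins, 1L)
                pos <- pos + step
                if (pos > n - config$minDomainBins %/% 2L) break
                b <- c(b, pos)
            }
        }
        starts <- c(1L, b)
        ndom <- length(starts)
        comp <- config$compartmentLabels
        if (is.null(comp)) comp <- sample(c("A", "B"), ndom, replace = TRUE)
        pair <- config$pairingLabels
        if (is.null(pair)) {
            # pairing is compartment-linked: inactive B-type domains are
            # five times more likely to pair loosely than active A-type
            # ones; the overall loose probability stays looseProb
            pLoose <- pmin(1, ifelse(comp == "A", config$looseProb / 3,
                                     5 * config$looseProb / 3))
            pair <- ifelse(stats::runif(ndom) < pLoose, "loose", "tight")
        }
        if (length(comp) != ndom || length(pair) != ndom)
            stop("per-domain labels must match the number of domains")
        list(n = n, boundaries = b, domainStarts = starts,
             compartments = comp, pairing = pair)
    })
}

# Per-bin layout vectors from a resolved layout.
.binLayout <- function(layout) {
    n <- layout$n
    dom <- findInterval(seq_len(n), layout$domainStarts)
    comp <- layout$compartments[dom]
    regionLoose <- layout$pairing[dom] == "loose"
    # boundary-adjacent bins (both flanks of each boundary, plus the
    # chromosome ends) stay tightly paired
    anchor <- rep(FALSE, n)
    anchor[c(1L, n, layout$boundaries, layout$boundaries - 1L)] <- TRUE
    binLoose <- regionLoose & !anchor
    list(dom = dom, comp = comp, binLoose = binLoose)
}

# Expected (pre-Poisson) cis and thom matrices for a config; dense, for
# small instances and oracle checks.
#' Expected-value matrices of the generator
#'
#' Returns the dense expected (pre-Poisson) cis and thom count matrices
#' for a configuration, mainly for inspection and testing on small
#' instances.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with matrices \code{cis} and \code{thom}, and the resolved
#'   layout (\code{boundaries}, per-bin labels).
#' @export
expectedDiploidMatrices <- function(config) {
    layout <- .resolveLayout(config)
    bl <- .binLayout(layout)
    n <- layout$n
    lam <- .lambdaByDiagonal(config, layout, bl)
    cis <- matrix(0, n, n); thom <- matrix(0, n, n)
    for (d in 0:(n - 1L)) {
        i <- seq_len(n - d)
        cis[cbind(i, i + d)] <- lam$cis[[d + 1L]]
        cis[cbind(i + d, i)] <- lam$cis[[d + 1L]]
        thom[cbind(i, i + d)] <- lam$thom[[d + 1L]]
        thom[cbind(i + d, i)] <- lam$thom[[d + 1L]]
    }
    list(cis = cis, thom = thom, layout = layout, binLoose = bl$binLoose)
}

# lambda vectors per diagonal d = 0..n-1 (list index d+1), scaled so that
# the cis upper triangle (incl. diagonal) sums to depth.
.lambdaByDiagonal <- function(config, layout, bl) {
    n <- layout$n
    a <- config$alpha
    ash <- config$alphaShallow
    s0bins <- config$tightDomainScale / config$binSize
    cis <- vector("list", n); thom <- vector("list", n)
    tot <- 0
    looseLagMax <- config$looseScale / config$binSize
    for (d in 0:(n - 1L)) {
        i <- seq_len(n - d); j <- i + d
        s <- max(d, 1L)
        sameDom <- bl$dom[i] == bl$dom[j]
        if (!is.na(ash)) {
            domLoose <- layout$pairing[bl$dom[i]] == "loose"
            base <- numeric(n - d)
            steep <- if (s <= s0bins) s^(-ash) else s0bins^(a - ash) * s^(-a)
            base[sameDom & !domLoose] <- steep
            base[sameDom & domLoose] <- s^(-ash)
            base[!sameDom] <- s^(-a) * config$insulationDepletion
        } else {
            base <- rep(s^(-a), n - d)
            base[!sameDom] <- base[!sameDom] * config$insulationDepletion
        }
        base[bl$comp[i] == bl$comp[j]] <-
            base[bl$comp[i] == bl$comp[j]] * config$plaidStrength
        cis[[d + 1L]] <- base
        tf <- rep(config$tightEnrichment, n - d)
        if (d < looseLagMax) {
            both <- bl$binLoose[i] & bl$binLoose[j]
            tf[both] <- tf[both] * config$looseDepletion
        }
        thom[[d + 1L]] <- base * tf
        tot <- tot + sum(base)
    }
    scale <- config$depth / tot
    list(cis = lapply(cis, `*`, scale), thom = lapply(thom, `*`, scale))
}

#' Simulate haplotype-tagged diploid contact maps with known ground truth
#'
#' Draws Poisson counts from the expected-value model described in
#' \code{\link{simulationConfig}} and returns the two cis channels, the
#' trans-homolog channel and the ground truth (per-bin pairing labels,
#' planted boundaries, compartment labels and the decay exponent).
#' Identical configurations (including the seed) give identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{cis_maternal}, \code{cis_paternal}, \code{thom}
#'   (\linkS4class{ContactMap}s) and \code{truth} (class
#'   \code{GroundTruth}: \code{binLabels}, \code{boundaries},
#'   \code{compartments}, \code{regionLabels}, \code{domainStarts},
#'   \code{alpha}, \code{lowDepth}, \code{config}).
#' @export
simulateDiploidMaps <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    layout <- .resolveLayout(config)
    bl <- .binLayout(layout)
    n <- layout$n
    lam <- .lambdaByDiagonal(config, layout, bl)
    bt <- binnedGenome(stats::setNames(config$chromLength, "chrS"),
                       config$binSize)
    lowDepth <- min(lam$cis[[2L]]) < 1
    if (lowDepth)
        warning("depth too low to populate the first diagonal (expected < 1 per pixel)")
    sampleChannel <- function(lamlist, channelName) {
        b1 <- vector("list", n); b2 <- vector("list", n); ct <- vector("list", n)
        for (d in 0:(n - 1L)) {
            cnt <- stats::rpois(n - d, lamlist[[d + 1L]])
            nz <- which(cnt > 0L)
            if (length(nz)) {
                b1[[d + 1L]] <- nz
                b2[[d + 1L]] <- nz + d
                ct[[d + 1L]] <- cnt[nz]
            }
        }
        contactMap(bt, data.frame(bin1 = unlist(b1), bin2 = unlist(b2),
                                  count = unlist(ct)),
                   channel = channelName)
    }
    maps <- .withSeed(config$seed, list(
        cis_maternal = sampleChannel(lam$cis, "cis_maternal"),
        cis_paternal = sampleChannel(lam$cis, "cis_paternal"),
        thom = sampleChannel(lam$thom, "thom")))
    truth <- structure(list(
        binLabels = ifelse(bl$binLoose, "loose", "tight"),
        boundaries = layout$boundaries,
        domainStarts = layout$domainStarts,
        compartments = bl$comp,
        regionLabels = layout$pairing,
        alpha = config$alpha,
        lowDepth = lowDepth,
        binTable = bt,
        config = config), class = "GroundTruth")
    c(maps, list(truth = truth))
}

#' @export
print.GroundTruth <- function(x, ...) {
    cat(sprintf(paste0("GroundTruth: %d bins, %d planted boundaries, ",
                       "%d domains (%d loose), alpha = %g\n"),
                length(x$binLabels), length(x$boundaries),
                length(x$regionLabels), sum(x$regionLabels == "loose"),
                x$alpha))
    invisible(x)
}

#' Draw a PS-like sample from a two-Gaussian mixture
#'
#' @param weights two mixture proportions summing to 1.
#' @param means,sds component means and standard deviations.
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric vector of \code{n} i.i.d. mixture draws.
#' @export
simulatePsSample <- function(weights, means, sds, n, seed = NULL) {
    if (n <= 0) stop("n must be positive")
    stopifnot(length(weights) == 2L, abs(sum(weights) - 1) < 1e-8,
              all(sds > 0))
    .withSeed(seed, {
        z <- stats::rbinom(n, 1L, weights[2L]) + 1L
        stats::rnorm(n, mean = means[z], sd = sds[z])
    })
}
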