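# Heavier shared fixtures for the acceptance-level checks: one default-condition
# simulation (4 kb bins, 20 Mb chromosome) per seed, balanced
# channels and score tracks, computed once and cached across test blocks.
.simCache <- new.env(parent = emptyenv())

defaultSimBundle <- function(seed = 1L) {
    key <- paste0("seed", seed)
    if (!exists(key, envir = .simCache)) {
        cfg <- simulationConfig(seed = seed)
        sim <- simulateDiploidMaps(cfg)
        thom <- iterativeCorrection(sim$thom)
        cisP <- iterativeCorrection(poolMaps(list(sim$cis_maternal,
                                                  sim$cis_paternal),
                                             "cis_pooled"))
        ps <- pairingScore(thom)
        cs <- pairingScore(cisP)
        truthBnd <- new("BoundarySet", binTable = sim$truth$binTable,
                        bins = as.integer(sim$truth$boundaries),
                        prominence = rep(Inf, length(sim$truth$boundaries)),
                        cutoff = 0, channel = "reference_pooled")
        assign(key, list(cfg = cfg, sim = sim, thom = thom, cisP = cisP,
                         ps = ps, cs = cs, truthBnd = truthBnd),
               envir = .simCache)
    }
    get(key, envir = .simCache)
}
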