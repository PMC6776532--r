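---
title: "Quantifying homolog pairing from haplotype-resolved Hi-C: models and methods"
author: "pairHiC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying homolog pairing from haplotype-resolved Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairHiC)
```

# The problem

In *Drosophila* somatic cells the two homologous chromosomes pair along
their length. When Hi-C reads can be assigned to the maternal or paternal
homolog through parental SNVs, the contact map splits into channels:
*cis*-maternal and *cis*-paternal contacts (both reads on the same
homolog), and *trans*-homolog (*thom*) contacts between the two homologs.
If homologs are paired in precise register ("railroad-track" pairing), a
locus contacts the homologous locus on the other chromosome almost as often
as nearby loci on its own chromosome, and the thom map acquires a strong
main diagonal mirroring the cis structure. Where pairing is loose, the
thom diagonal fades inside domains while persisting at domain boundaries.

pairHiC quantifies this structure: per-bin pairing scores, a genome-wide
aggregated pairing score with a bootstrap test, a two-Gaussian
classification of bins into tightly and loosely paired, boundary-anchored
pairing regions, plus the surrounding Hi-C toolbox (iterative correction,
contact-probability scaling curves, insulation scores and boundaries,
compartment eigenvectors, loop quantitation, map-resolution selection and
a disomy estimator).

# Data model

All objects live on a `BinnedGenome`: a fixed-size bin grid (BED
convention, 0-based half-open; the stored `GRanges` is 1-based) with a
unique global index per bin. A `ContactMap` stores one channel's pixels
upper-triangular with raw counts; the thom channel is stored on the single
reference grid and symmetrized by folding, since maternal-to-paternal and
paternal-to-maternal contacts are indistinguishable in aggregate. Genomic
separation between bins is the distance between bin starts.

# Iterative correction

`iterativeCorrection()` equalizes marginals (main diagonal excluded) by
the usual multiplicative fixed-point iteration, after masking bins with
zero coverage or coverage more than 5 MADs from the median (both
configurable; cap 1000 iterations, relative tolerance 1e-6). Two
conventions exist for the final scale of the weights: normalizing
marginals to 1, or preserving the total count scale. pairHiC rescales the
converged weights so that the total balanced signal equals the total raw
signal. This keeps balanced values in corrected-count units, which makes
the pairing score comparable to published log2 thresholds of order -3..0
and mirrors the caveat that scores depend on sequencing depth, so
cross-condition comparisons should be depth-matched. Each channel is
balanced independently.

# Pairing score and cis score

The pairing score of bin *i* is

PS^W(i) = log2 of the mean balanced thom contact frequency over the
(2W+1) x (2W+1) pixel window centered on the diagonal at *i*,

with default W = 3 (a 7 x 7 = 49-pixel window at 4 kb bins, i.e. +-12 kb),
the balance between specificity and sensitivity at this resolution. The
cis score (CS) is the same statistic on a cis map and controls for local
visibility: a dip in PS alone indicates a change in pairing, a dip in both
indicates a visibility artifact. The main diagonal is included in the
window. A bin's score is missing when more than half of the full window's
pixels are unavailable (masked, or truncated at a chromosome end) - a
validity rule guarding boundary and mask artifacts - or when the window
mean is zero.

# Aggregated pairing score and bootstrap

APS = mode of the genome-wide per-bin (PS - CS) distribution: the most
probable log2 ratio of short-range thom to cis contact frequency, robust
to the heavy loose-pairing tail. The mode is estimated by a Gaussian
kernel density with fixed bandwidth 0.05 log2 units evaluated on a regular
grid with step at most 0.001 spanning the sample range; the fixed
bandwidth makes APS deterministic and comparable across conditions.

To compare two conditions, `apsBootstrapTest()` merges the two (PS - CS)
samples, redraws pairs of samples of the original sizes with replacement
(default 1000 replicates), and reports the fraction of replicates whose
absolute APS difference reaches the observed one, with add-one smoothing
(k+1)/(R+1). The two-sided form is used. Under the null the test is
slightly conservative by construction. Note a genuine limitation: when
the merged pool is strongly bimodal (two very different conditions), the
resampled mode alternates between the modes and the test loses power; its
intended regime is the small mode shifts seen in knockdowns.

# Tight/loose classification

The genome-wide PS distribution shows a pronounced high-PS peak with a low
tail. `fitTwoGaussians()` winsorizes values below a clip floor (default
-3; winsorizing rather than discarding preserves the loose-tail mass that
defines the loose weight), then fits a two-component Gaussian mixture by
EM with deterministic initialization (means at the 25th/75th percentiles,
equal weights, sds at half the sample sd; relative log-likelihood
tolerance 1e-8, cap 1000; on degeneracy a restart with variance floor
1e-4). The fit is flagged unreliable when the split does not beat a
single Gaussian by BIC. The tight/loose threshold is the density
intersection between the two means, solved in closed form from the
quadratic in the log densities and cross-checked against a dense-grid
oracle in the tests. Bins strictly below the threshold are loose; missing
PS stays missing. A single genome-wide threshold is used.

`classifyRegions()` cuts the genome between consecutive insulating
boundaries (chromosome ends are implicit boundaries), labels a region
loose when at least 25% of its scored bins are loose (PS dips are gradual,
so a quarter of loose bins suffices to call the region), and merges
adjacent same-labeled regions when the boundary bin between them carries
that same bin-level label, iterating to a fixpoint; a boundary bin with a
missing label never licenses a merge. Size classes (100-200 kb and
200-400 kb) can then be selected for region-internal analyses.

# Insulation and boundaries

The raw insulation score at bin *i* is the sum of balanced contacts
crossing *i* within a flank of w = 5 bins (pairs strictly straddling the
bin; sum, not mean); the track is log2(raw / genome-wide median), missing
within w bins of chromosome ends and where the diamond touches a masked
bin. Uniform rescaling of the map cancels in the normalization.

Boundaries are local minima found by alternating-extrema peak detection
with detection delta equal to half the prominence cutoff; a minimum's
prominence is the smaller of the rises to its flanking detected maxima,
and minima with prominence at or above the cutoff are kept, minus any
whose bin or immediate neighbor is masked. Default cutoffs follow the
published empirical choices: 0.3 for haplotype-resolved channels, 0.1 for
the reference map. The cutoffs are configuration, not automatically
derived from the prominence distribution. `boundaryOverlap()` matches two
boundary sets greedily nearest-first, one-to-one, within a tolerance of 4
bins (16 kb at 4 kb resolution) to absorb stochastic drift.

# Compartments, associations, loops, disomy, resolution

* `observedOverExpected()` divides each chromosome's balanced matrix by
  its per-diagonal mean. `compartmentEigenvector()` decomposes (O/E - 1)
  with masked rows removed, scales eigenvectors by the square root of the
  absolute eigenvalue, screens the first three against a per-bin
  gene-count track (Pearson; the selection is invariant to positive
  rescaling of that track) and orients the best so the correlation is
  positive - positive values mark the gene-dense A compartment.
* PS-annotation associations use Spearman correlation
  (`trackCorrelation()`), quadrant genome fractions
  (`quadrantFractions()`, second-track threshold defaulting to its
  median), and Mood's median test per chromatin state against a reference
  state (`chromatinStateAssociation()`; 2 x 2 chi-square on the pooled
  median, 1 df, no continuity correction).
* `loopQuantitation()` sums balanced values in a 120 kb x 120 kb window
  centered on each loop-anchor pixel; masked pixels contribute zero,
  truncated windows are flagged.
* `disomyFraction()` inverts r = (1+x)/(1-x): a coverage ratio r between
  homologs over a region implies a disomic cell fraction x = (r-1)/(r+1).
* `pickResolution()` chooses the finest candidate bin size with more than
  50% non-zero pixels on the diagonal at 100 kb separation.

# The synthetic diploid generator

`simulateDiploidMaps()` draws Poisson counts from an explicit
expected-value model so every stage is testable against a known truth.
For bins i, j at separation s (bins):

* cis: lambda = C * max(s,1)^-alpha, times `insulationDepletion` (default
  0.3) when the pair crosses a domain boundary, times `plaidStrength`
  (default 1.6) when the two bins' compartment labels match. C scales the
  expected cis total to `depth`.
* thom: lambda_cis * `tightEnrichment` (default 0.7), additionally times
  `looseDepletion` (default 0.15) when both bins are loosely paired and
  s < `looseScale` (default 100 kb). Boundary-adjacent bins are tight
  anchors, so loose regions keep pairing at their edges.
* optionally a two-regime within-domain decay (`alphaShallow`, change
  point `tightDomainScale` = 30 kb, continuous): tight domains are shallow
  then steep - the signature of a series of small domains - while loose
  domains decay with the shallow exponent throughout, emulating single
  larger domains.

Defaults are the study conditions exercised by the tests: one 20 Mb
chromosome at 4 kb bins (5000 bins), alpha = 1, domain sizes uniform
160-400 kb, overall loose probability 0.35 with pairing compartment-linked
(B-type domains five times more likely loose than A-type, matching the
observation that active compartments pair almost exclusively tightly), and
`depth` = 1e7 expected cis counts per channel - the same order as ~75M
mappable pairs over a ~120 Mb genome. Both cis channels share one lambda
(structurally concordant homologs) but are sampled independently; noise is
Poisson, not negative binomial - overdispersion, mappability structure,
SNV-density variation and homolog misassignment are deliberately not
emulated, so passing tests demonstrate correctness of the estimators under
the stated model, not robustness to every artifact of real data.

# What the tests show, and known limitations

The test suite checks each operation against independent brute-force
enumerations on small instances (exact to 1e-10 or better), and the whole
pipeline against the generator's planted truth: bin- and region-label
recovery at or above 90%, boundary recall/precision against planted
boundaries, APS shifts of exactly log2 f under thom-diagonal depletion at
fixed weights (re-balancing after a depletion partially absorbs the shift
into the weights, so the check holds visibility fixed - the same reason
knockdown comparisons should be depth-matched), decay-exponent recovery by
log-log regression of P(s) over 10-300 kb (per-range finite-difference
slopes carry bin-grid discretization jitter at small lags and are verified
on exact closed-form inputs instead), a null-calibrated bootstrap
(rejection rate at alpha = 0.05 within the binomial band over 200 null
pairs), and byte-identical pipeline summaries under identical seeds.

Two results deserve honesty:

* Under these conditions the planted boundaries are strong, and iterative
  correction produces elevated insulation "rims" flanking each boundary
  valley. Shallow interior dimples measured against those rims reach
  prominences of ~0.3-0.55, at or above the 0.3 default cutoff, which caps
  cis-channel boundary precision near 0.9 and - because the thom channel
  is the shallowest and loose interiors the noisiest - leaves roughly a
  third of thom boundary calls unmatched in the cis calls. The cis-in-thom
  direction reaches ~0.96, while thom-in-cis sits near 0.55-0.8 across
  seeds; the corresponding real-data concordance reported for this assay
  is 81.5%/89.1%. The acceptance test states the stricter 0.9 bound in
  both directions and is expected to stay red on that clause rather than
  having the generator, cutoffs or seeds adjusted to meet it.
* The compartment eigendecomposition in the pipeline runs on a map
  coarsened 8-fold (4 kb to 32 kb, 625 bins per 20 Mb chromosome): the
  full dense eigendecomposition is cubic in bin count and compartments are
  large-scale structure; at 32 kb the planted labels are recovered with
  correlation above 0.95.

Numerical conventions collected in one place: coordinates 0-based
half-open; separations from bin starts; curve ranges half-open [lo, hi)
with eight per decade from 10 bp to 10 Mb and the geometric mean of the
edges as the plotted s; empty separation ranges are missing, not zero;
PS threshold ties go to tight (strict-below is loose); bootstrap p-values
use (k+1)/(R+1); EM is deterministically initialized; the mode grid step
is 0.001.

# A worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(sim = simulationConfig(chromLength = 6e6,
                                             binSize = 8000, depth = 3e6),
                      coarsenFactor = 4, seed = 1)
res <- runPairingPipeline(cfg, outDir = "pairing-out")
res$fit                      # two-Gaussian fit and threshold
res$summary$aps              # aggregated pairing score
res$summary$label_accuracy   # recovery of the planted labels
```

The pipeline writes PS/CS and insulation tracks as bedGraph, boundaries
and regions as BED, scaling curves as TSV and a machine-readable
`summary.json`; identical seeds reproduce it byte for byte.
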