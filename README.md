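# pairHiC

Quantitative analysis of somatic homolog pairing from haplotype-resolved
Hi-C contact maps.

In organisms with somatic pairing (classically *Drosophila*), parental
SNVs let Hi-C read pairs be assigned to the maternal or paternal homolog,
splitting a contact map into *cis* channels (both reads on one homolog)
and a *trans*-homolog (*thom*) channel (one read on each). When homologs
are paired in register, the thom map carries a main diagonal mirroring the
cis structure; where pairing is loose, that diagonal fades inside domains
but persists at their boundaries. pairHiC turns these signatures into
numbers:

- **Pairing score (PS)** of bin *i*: `log2` mean iteratively corrected
  thom contact frequency over the `(2W+1) x (2W+1)` pixel window centered
  on the diagonal (default `W = 3`, a 7 x 7 window at 4 kb bins), with the
  analogous **cis score (CS)** as a visibility control.
- **Aggregated pairing score** `APS = mode(PS - CS)` (fixed-bandwidth
  kernel density estimate), with a merged-pool bootstrap test for APS
  differences between conditions, `p = (k+1)/(R+1)`.
- **Tight/loose classification**: a two-Gaussian EM fit of the PS
  distribution (values clipped below -3), thresholded at the density
  intersection between the component means; regions between insulation
  boundaries are called loose at >= 25% loose bins and merged across
  same-labeled boundary bins.
- **Hi-C toolbox** around it: iterative correction (matrix balancing with
  MAD-based bin masking), contact-probability curves P(s) in geometric
  separation ranges (8 per decade, 10 bp-10 Mb) with ratio, normalized,
  region-restricted and slope views, diamond insulation scores with
  prominence-filtered boundary detection and tolerance-aware boundary
  matching, O/E compartment eigenvectors selected by gene-density
  correlation, 120 kb loop quantitation, map-resolution selection
  (finest bin size with >50% non-zero pixels at 100 kb), and a disomy
  estimator `x = (r-1)/(r+1)` from homolog coverage ratios.
- A **synthetic diploid map generator** with planted truth (decay
  exponent, boundaries, compartments, tight/loose regions) so the entire
  pipeline is testable offline.

Input contact maps are TSV triplets (`chrom1 start1 chrom2 start2 count`)
on a declared chrom-sizes + bin-size grid; tracks and intervals are
bedGraph/BED via rtracklayer.

## Worked example

```r
library(pairHiC)

cfg <- pipelineConfig(sim = simulationConfig(chromLength = 6e6,
                                             binSize = 8000, depth = 3e6),
                      coarsenFactor = 4, seed = 1)
res <- runPairingPipeline(cfg, outDir = "pairing-out")

res$fit
#> GaussianMixtureFit (n = 748, clip floor -3):
#>   loose: pi = 0.335, mu = 6.476, sd = 0.249
#>   tight: pi = 0.665, mu = 7.967, sd = 0.130
#>   threshold = 7.4276
round(res$summary$aps, 3)
#> [1] -1.812
round(res$summary$label_accuracy, 3)
#> [1] 0.997
```

Read: the fit separates a tight mode (`mu = 7.97` log2 corrected counts)
from a loose mode (`mu = 6.48`); bins below the density-intersection
threshold `7.43` are loosely paired. The APS of `-1.81` is the most
probable log2 ratio of short-range thom to cis contact frequency on this
synthetic sample, and 99.7% of bins get their planted tight/loose label
back. `pairing-out/` holds PS/CS/insulation bedGraphs, boundary and
region BEDs, scaling-curve TSVs and `summary.json`.

Per-stage functions (`iterativeCorrection`, `pairingScore`,
`fitTwoGaussians`, `classifyRegions`, `insulationScore`,
`findBoundaries`, `contactFrequencyCurve`, `compartmentEigenvector`,
`loopQuantitation`, `disomyFraction`, ...) expose every step separately;
see the methods vignette (`vignettes/homolog-pairing-methods.Rmd`) for
the models, parameter meanings and numerical conventions.

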