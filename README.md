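# ocmod — overlapping co-expressed gene module detection

Most co-expression tools (WGCNA-style clustering among them) partition
genes into disjoint modules. Real transcriptional programs overlap: a gene
can serve several programs, and some programs act only in a subset of
samples. `ocmod` detects modules that are **allowed to overlap** by
factoring a normalized gene-expression matrix *X* (genes × samples) into

```
X ≈ S · A
```

where the columns of *S* are gene-space **signatures** (one weight per
gene per latent program) and the rows of *A* the paired sample-space
**patterns**. It is aimed at anyone analyzing bulk or single-cell
expression matrices who wants modules with membership overlap, hub-gene
reports, and module–trait associations from one seeded, reproducible
pipeline.

The pipeline:

1. **Pre-processing** — outlier samples removed by standardized
   sample-network connectivity (*z* < −2.5), then each gene centred and
   standardized across samples.
2. **Component count** — permutation parallel analysis
   (`select_components`): the variance fraction of each singular value is
   compared against *B* within-gene-row permutations; the chosen *k* is
   the initial run of candidates with p < α (p-values +1-corrected, never
   zero). The same report recommends ICA or IPCA by counting
   kurtosis-passing signatures.
3. **Decomposition** — symmetric FastICA (logcosh negentropy, α = 1) or
   IPCA (deflation FastICA on the top-*k* principal gene loadings), both
   seeded, with restarts guarding against spurious fixed points.
4. **Non-Gaussianity filter** — only signatures with Pearson kurtosis
   m₄/m₂² ≥ 3 (the Gaussian reference value) are kept.
5. **Module assignment** — per signature, genes in the tails are
   assigned either by a tail-area FDR from a two-component mixture with a
   Gaussian null fitted around the median (default FDR < 0.001) or by a
   z-score rule (default |z| > 3σ). A gene may land in several modules.
6. **Hub genes** — the members with the largest |weight| in either tail
   (top 10 by default).
7. **Association** — Pearson correlation of each module's pattern with
   each numeric clinical feature, with two-sided t p-values and a
   Benjamini–Hochberg column; plus utilities to cross-correlate patterns
   with module eigengenes of an external clustering.

A seeded synthetic-data generator (`simulate_expression`) plants
overlapping modules with Laplace (heavy-tailed) weights and Gaussian
patterns, so the whole pipeline is benchmarkable without any downloads.

## Worked example

```r
library(ocmod)

sim <- simulate_expression(seed = 1)                  # 2000 genes x 100 samples, 3 planted modules
cli <- simulate_clinical(sim$truth, effect = 5, seed = 1)
run <- run_pipeline(sim$x, clinical = cli, method = "ICA", k = "auto", seed = 1)
print(run)
```

```
Overlapping-module run
  method = ICA, k = 3, assigner = FDR (threshold 0.001), seed = 1
Module set (ICA-FDR, threshold 0.001): 3 modules over 2000 genes
  sizes: oM1=88, oM2=85, oM3=90
  genes in >= 2 modules: 12
```

The permutation analysis chose k = 3 (the planted count: the first three
variance fractions beat all 50 permutations, p ≈ 0.02, while candidate 4
is indistinguishable from noise, p = 1). Three modules of 85–90 genes were
detected out of 100 planted members each — the stringent FDR < 0.001 cut
deliberately leaves out members whose planted weight is near zero — and 12
genes were recovered in more than one module, reflecting the planted 10%
overlap.

```r
head(run$hubs, 5)            # strongest drivers of oM1, both tails eligible
#>   module rank  gene    weight
#> 1    oM1    1 g1895  4.589237
#> 2    oM1    2 g1395 -4.583396
#> 3    oM1    3 g1749 -4.581053
#> 4    oM1    4 g1701 -4.578794
#> 5    oM1    5 g0039 -4.575637

round(run$association$r, 3)  # module patterns vs clinical features
#>     trait_M1 trait_M2 trait_M3 noise
#> oM1   -0.987    0.024    0.109 0.008
#> oM2    0.056   -0.981    0.065 0.062
#> oM3    0.119    0.013   -0.979 0.067
```

Each module's pattern correlates near-perfectly (|r| ≈ 0.98, BH-adjusted
p < 1e-60) with exactly the clinical feature built from its planted
pattern, and shows nothing against the pure-noise feature. Signs are
arbitrary, as in any ICA.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/ocmod.R simulate --out data --seed 1
Rscript inst/cli/ocmod.R run --input data/expression.tsv --clinical data/clinical.tsv \
        --out results --method auto --k auto --seed 1
```

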