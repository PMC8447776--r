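# chromhier

Hierarchical chromatin-architecture analysis from binned Hi-C contact
counts, for genomes with a macro/micro chromosome split (snakes, birds
and other sauropsids). Starting from sparse triplet contact counts,
chromhier normalizes (library size, ICE, observed/expected), calls A/B
compartments, detects TAD boundaries by insulation score, calls focal
chromatin loops with a HICCUPS-style donut filter, and integrates the
three layers with gene expression and histone-mark peaks (H3ac,
H3K27me3). A planted-truth synthetic-data generator makes every stage
verifiable end-to-end without external data.

## The models at the core

* **Compartments.** Per chromosome, the leading eigenvector of the
  Pearson correlation matrix of the observed/expected map at 100 kb;
  sign oriented so the eigenvector correlates positively with gene
  density, labels A (positive, gene-dense) and B (negative). Bins that
  switch label between conditions (A→B, B→A) are tested against the
  stable group with a Wilcoxon rank-sum test on per-gene log2 fold
  changes.
* **TAD boundaries.** Insulation score
  `log2( mean contact in a sliding w×w square / chromosomal geometric mean )`
  at 10 kb with a 100 kb window; boundaries at negative-to-positive zero
  crossings of the delta vector, then padded 40 kb per side so each
  final boundary spans exactly 90 kb (10 kb bin + 80 kb).
* **Loops.** For each pixel within 1 Mb, observed signal versus four
  local-background expectations (donut, lower-left, horizontal,
  vertical), Poisson upper-tail p-values with Benjamini–Hochberg
  correction at FDR 0.1, called at 10 kb and 25 kb and merged with
  fine-resolution precedence.
* **Integration.** Peak-in-feature enrichment (permutation z, bp odds
  ratio, Fisher p), strand-aware promoter statistics and TSS
  meta-profiles, mark–expression Pearson correlation, and a simple
  median-of-ratios + Welch-t differential-expression stand-in at
  |lfc| > 1, adjusted p < 0.01.

The synthetic generator plants all of this: alternating A/B blocks
(with condition switches), TAD boundaries, ≤1 Mb loops biased into A
compartments, compartment-dependent gene density, switch-linked
expression effects, and compartment-biased peaks. See the methods
vignette (`vignettes/chromhier-methods.Rmd`) for the generative model
and every numerical decision.

## Worked example

```r
library(chromhier)

genome <- makeGenome(n_mac = 0, n_mic = 3, mic_range = c(8e6, 1.2e7), seed = 7)
genome
#> GenomeLayout: 3 chromosomes (0 MAC > 50 Mb, 3 MIC), 30.0 Mb total

truth <- plantTruth(genome, n_boundaries_per_chrom = 6, n_loops = 50, seed = 7)
truth
#> SyntheticTruth: 31 compartment blocks, 43 boundaries, 50 loops

map <- simulateContacts(genome, truth, resolution = 1e4, depth = 1e7, seed = 7)
map
#> ContactMap: 10000 bp resolution, 1181095 non-zero entries, total 1.798e+07

totalContacts(normalizeLibrary(map, 1e9))
#> [1] 1e+09

bal    <- balanceAll(map)
ins    <- data.table::rbindlist(lapply(bal, insulationScore))
bounds <- padBoundaries(callBoundaries(ins), genome)
nrow(bounds); table(bounds$end - bounds$start)
#> [1] 45
#> 90000
#>    45

loops <- clusterAndMerge(list(data.table::rbindlist(lapply(bal, callLoops))))
c(peaks = loops$n_peaks, loci = loops$n_loci, max_span = max(loops$loops$span))
#>    peaks     loci max_span
#>       94      180   990000
```

Reading the output: the 30 Mb three-chromosome genome carries 43 planted
boundaries (compartment-block junctions plus within-block boundaries)
and 50 planted loops. Library normalization lands exactly on the 1e9
target. The insulation caller finds 45 boundaries, every one padded to a
90 kb final interval; the loop caller's 94 peaks (180 distinct anchor
loci) include the planted anchors — the test suite scores recall ≥ 80%
within one bin, and ~100% is achieved at these settings — and no call
spans more than 1 Mb.

The whole pipeline, including expression, switches and peak
integration, runs as one call with a hashed, seed-reproducible output
manifest:

```r
runAll(defaultConfig(), "out_dir", seed = 3)
```

A thin command-line wrapper lives at `inst/cli/chromhier.R`
(`Rscript chromhier.R run-all --outdir DIR --seed N`).

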