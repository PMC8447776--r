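---
title: "Methods: hierarchical chromatin architecture from binned Hi-C contacts"
author: "chromhier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical chromatin architecture from binned Hi-C contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

chromhier analyses the three layers of chromatin architecture that binned
Hi-C contact maps resolve — A/B compartments at 100 kb, topologically
associating domains (TADs) at 10 kb, and focal chromatin loops at
10/25 kb — and integrates them with gene expression and histone-mark
peaks (H3ac as the activating mark, H3K27me3 as the repressive one).
Because real snake-venom-gland Hi-C libraries are large and external, the
package carries a first-class synthetic-data generator that plants all
three layers with known coordinates, so every caller can be scored
against ground truth. This vignette records the models, the parameter
choices and the numerical decisions.

# The synthetic contact model

The generator is the minimal multiplicative model under which every
downstream caller's assumptions hold. For two bins of the same
chromosome at bin distance $d$, the expected intensity is

$$
\mu_{ij} \;\propto\; (1+d)^{-\alpha}
 \cdot c^{\,[\mathrm{same\ compartment}]}
 \cdot t^{\,[\mathrm{same\ TAD}]}
 \cdot \ell^{\,[\mathrm{near\ a\ planted\ anchor\ pair}]},
$$

with Poisson counts around $\mu$ and the genome-wide total scaled to the
requested depth. Defaults: decay exponent $\alpha = 1.0$ (the classic
fractal-globule-like slope), compartment factor $c = 2.5$, TAD factor
$t = 2.0$, loop factor $\ell = 8$ applied in the one-bin neighborhood of
each anchor pair. Inter-chromosomal pixels get a flat intensity equal to
`trans_level` (default 0.01) times the mean intra intensity, doubled for
micro-chromosome pairs (`mic_trans_boost = 2`) because micro-chromosomes
sit spatially closer; the magnitude of that boost is not an estimate of
anything — no quantitative value exists to calibrate it against — so it
is an explicit free parameter.

Karyotypes follow the macro/micro split of snake genomes: chromosomes
longer than 50 Mb are macro (MAC), shorter ones micro (MIC); lengths
exactly at the threshold are disallowed so the classification is total.

Three structural conventions matter downstream:

* **Compartment blocks alternate A/B** (starting with A) at a block size
  that must be a multiple of the 100 kb compartment bin. A configurable
  fraction of blocks (default 0.2) flips its label in a second condition;
  that flip is the planted "compartment switch".
* **Compartment block junctions are TAD boundaries too.** Under the
  multiplicative model a block junction insulates exactly like a domain
  boundary, so the truth records it as one; `n_boundaries_per_chrom`
  additional boundaries subdivide the blocks, kept at least 500 kb apart
  and at least two insulation windows from chromosome ends. Without this
  convention any insulation-based caller would report block junctions as
  "false positives" that are in fact real planted structure.
* **Loops are planted inside A blocks with probability 0.7** (spans
  50 kb–1 Mb on the 10 kb grid), mimicking the predominance of
  euchromatic loops.

Gene annotation is Poisson along each chromosome with compartment-
dependent density (defaults 12 genes/Mb in A, 4 in B — A is gene-dense),
gene lengths log-normal around 12 kb (4–100 kb). Genes are thinned to be
non-overlapping with a 1.2 kb upstream guard so that each gene's
promoter-plus-body window is disjoint from its neighbors'; this is what
makes the mark–expression coupling below exact rather than attenuated by
cross-gene peak contamination, at the cost of not modelling overlapping
or nested genes. Expression is negative-binomial (dispersion 0.1) around
a log-normal baseline; genes in switching blocks receive a
$\pm$`lfc_switch_effect` (default 1.5) mean log2 fold change, and FPKM is
count / (gene kb × library millions).

Histone peaks come from two generators: a compartment-level one that
drops peaks into the preferred compartment with probability `a_bias`
(exponential lengths, overlaps resolved by dropping later intervals), and
a promoter-anchored one for correlation benchmarks that draws each
gene's peak length from a Gaussian copula with its log2(FPKM+1), so the
measured Pearson correlation approximates a chosen target (defaults 0.56
for H3ac and −0.45 for H3K27me3, chosen to echo the magnitudes real
venom-gland data show). With ~2 000 genes the sampling error on the
recovered correlation is about 0.02, well inside the ±0.1 band the tests
use.

All generators pin the RNG kind (Mersenne-Twister / Inversion /
Rejection) for their own stream and restore the caller's RNG state on
exit, so a fixed seed reproduces byte-identical output regardless of the
ambient RNG configuration. The pipeline derives per-stage seeds from one
global seed in a fixed documented order (`childSeed`).

# Contact-map normalization

**Library-size normalization** rescales a map so its genome-wide total
(off-diagonal entries counted twice, diagonal once) equals a target,
1×10⁹ by default, making libraries directly comparable.

**ICE balancing** fits multiplicative per-bin biases by symmetric
iterative proportional fitting with a damped (square-root) update. Bins
with zero coverage, or coverage below the 2% quantile of non-zero
coverages, are masked; the quantile uses the inverted-ECDF definition
(type 1) so the cut is an observed value and small matrices do not mask
their minimum-coverage bin. Convergence is declared when unmasked row
sums agree within 1e-5 relative (cap 200 iterations), and the converged
matrix is rescaled to preserve the unmasked total so balanced values stay
on the count scale — the loop caller's Poisson test depends on that.

**Observed/expected** divides each entry by the mean balanced value at
its bin distance (expected 0 ⇒ O/E 0). The interaction summary
normalizes each chromosome pair's total by its bin-pair count, the only
normalization that makes micro- and macro-chromosome classes comparable,
and uses Welch t-tests between classes (classes with fewer than two
members report NA rather than erroring).

# Compartment calling

Per chromosome, the Pearson correlation matrix of the O/E matrix is
computed over unmasked bins with the distance-0 (diagonal) entries
excluded pairwise; the exclusion is done in closed form (diagonal zeroed,
sums corrected per column pair) so it costs a single matrix product
instead of an O(n³) scan. The eigenvector of the largest-magnitude
eigenvalue, zero-filled at masked bins and unit-normed, is the
compartment track. Its sign is oriented so it correlates positively with
gene density (genes overlapping each 100 kb bin): positive = A
(gene-dense), negative = B. Zero-variance gene density leaves the
orientation unresolved; labels are still emitted with a warning flag
rather than a guess. Orientation is an involution — orienting an
oriented profile changes nothing.

Switches between two profiles are classified per bin (A→A, A→B, B→A,
B→B; masked in either profile ⇒ masked), with fractions over unmasked
bins both genome-wide and per chromosome — per-bin fractions are the one
denominator that is reproducible without knowing how segment-level
percentages were pooled. Expression change across switch categories
uses a two-sided Wilcoxon rank-sum test of each switching category
against the pooled stable group (A→A ∪ B→B), on per-gene log2 fold
changes with genes assigned to bins by TSS; TSS assignment matches the
promoter-centric ChIP analysis conventions. Categories with fewer than
two genes are reported not-applicable.

A known limitation is inherited from eigenvector compartment calling in
general: on real chromosomes the first PC can track chromosome arms or
large copy-number features instead of compartments. The synthetic data
have no centromeres or arms, so this failure mode is untested here.

# TAD boundaries and domains

The insulation score of bin $i$ is the mean balanced signal in the
$w \times w$ square of upstream rows $(i-w \ldots i-1)$ by downstream
columns $(i \ldots i+w-1)$, $w = $ window/resolution (default 100 kb at
10 kb). Scores are log2 ratios to the chromosome's **geometric** mean,
so unmasked scores average exactly zero and the track is invariant to
global matrix scaling. Bins whose window leaves the chromosome, or whose
square is more than half masked, are masked. An all-zero square (a
perfectly insulated junction) is a deep minimum, not missing data: it is
floored to half the smallest positive windowed mean before the log.

Boundaries sit at negative-to-positive zero crossings of the delta
vector (mean score over the next `delta_window` bins minus the previous
ones), localized at the local insulation minimum (leftmost on ties), and
kept when the minimum's depth — the lower flanking maximum minus the
minimum — reaches `min_strength` (default 0.1 log2 units). Each raw
10 kb boundary bin is then padded by 40 kb per side into a 90 kb final
boundary, absorbing replicate-to-replicate jitter; boundaries running off
a chromosome end are clipped and flagged, never silently shortened.

TADs span between consecutive boundary midpoints plus the two
chromosome-end domains; domains under 3 bins merge into the smaller
neighbor, and a chromosome with fewer than two boundaries is one whole-
chromosome domain. Two boundary sets are compared by ≥1 bp interval
intersection (the weakest criterion consistent with 90 kb tolerance
windows) plus a bp-level Jaccard on merged intervals. Feature counts in
boundaries versus TADs use TSS containment, with boundary intervals
taking precedence, and are reported as densities per Mb alongside raw
counts because the two territories differ grossly in total length.

This insulation-based segmentation deliberately replaces corner-score
(arrowhead-style) TAD calling; domain counts from the two approaches are
not comparable, and no attempt is made to reproduce any published TAD
count.

# Loop calling

For every intra-chromosomal pixel within the distance band
($p < j-i \le$ 1 Mb/resolution), four local background expectations are
computed HICCUPS-style — donut annulus, lower-left quadrant, horizontal
and vertical stripes (inner half-width $p = 1$, outer $w = 5$ bins) —
each as the neighborhood's observed/expected ratio times the
distance-decay expectation at the pixel. All neighborhood sums come from
summed-area tables, so the full band costs O(n·maxdist). Neighborhoods
renormalize by their unmasked pixel count; a pixel with more than half of
a neighborhood masked is dropped. A call requires the observed value to
exceed 1.5× every neighborhood expectation and a Poisson upper-tail
p-value against the largest expectation to survive Benjamini–Hochberg
correction at FDR 0.1 per chromosome. Balanced values are not integers,
so the Poisson tail uses its continuous extension
$P(X \ge o) = P(\Gamma(o) \le \lambda)$ (the regularized gamma function),
which coincides with `ppois` at integer observations. BH across the
whole band replaces the lambda-chunked FDR of the original HICCUPS
procedure — a calibration simplification, not a mechanical one.

Candidate pixels cluster by single linkage within a Chebyshev radius of
2 bins; the most significant pixel represents the cluster (a "loop
peak"), and the unique anchor intervals across both sides are the
"distinct peak loci". When both anchors of a 25 kb peak overlap a 10 kb
peak's anchors, the finer call wins. Loops are labelled A/B/mixed by the
compartment of both anchor midpoints, and loop-gene coupling compares
the fraction of anchor-TSS genes above FPKM 20 (the conventional
high-expression cut) against unanchored genes with a two-proportion
test.

Loop testing runs on raw-count-scale balanced matrices: significance is
a property of counts, so the pipeline balances the un-normalized map for
boundary and loop statistics and uses the 1e9-normalized map only for
cross-library comparisons. Scaling a matrix and adjusting it back leaves
the call set unchanged.

# Peak and expression integration

Enrichment of peaks in a feature class (compartment bins, boundaries,
anchors) reports three things: a permutation z-score from repositioning
peaks uniformly within their chromosome (lengths preserved, 1000
shuffles by default, seeded); an odds ratio from the bp-overlap 2×2
table; and a Fisher p-value on that table discretized to 100 bp units to
keep the exact test tractable. Under uniform placement the z is
standard-normal to good approximation (checked over 200 replicates).
Promoters are the strand-aware 1 kb upstream of the TSS, half-open, so a
peak midpoint exactly at the TSS is outside. TSS meta-profiles average
strand-oriented bp coverage in ±3 kb windows at 100 bp bins.
Mark–expression correlation uses total peak bp overlapping
[TSS − 1 kb, gene end] (strand-aware) against log2(FPKM+1).

The differential-expression routine is deliberately simple:
median-of-ratios size factors, log2 fold change of normalized group
means with pseudo-count 0.5, Welch t-test on log2 normalized counts, BH
adjustment, calls at |lfc| > 1 and adjusted p < 0.01. It is not a
shrinkage-based negative-binomial model, and its power is accordingly
lower: simulation puts the raw Welch p below 0.01 for a 4-fold change at
dispersion 0.05 with 3 replicates in only ~80% of runs (a Welch t with
~4 degrees of freedom has heavy tails), reaching ~92% for the full
BH-corrected call at 5 replicates in a 21-gene panel. The tests freeze
those measured operating points; anyone needing publication-grade DE
calls should use a dedicated DE package on the exported count table.

# Problem sizes, tolerances and what the tests show

The benchmark fixtures are sized so the whole suite runs comfortably on
one CPU: a 3-microchromosome ~30 Mb genome at 10 kb (boundaries, loops)
and a 4×20 Mb genome at 100 kb (compartments, switches, integration),
both at depth 10⁷. At those sizes the suite verifies: ICE row sums
within 1e-4; O/E of distance-only matrices equal to one; ≥95% planted
compartment label recovery at compartment strength 2.5 (achieved ~1.00);
TAD-boundary recall and precision ≥80% within one bin at TAD strength 2
(achieved ~0.98/0.93); loop recall ≥80% within one bin at loop strength
8 (achieved ~1.00); switch-category Wilcoxon rejection at α = 0.01 in
≥95 of 100 replicates; permutation z-scores with |mean| < 0.1 and sd in
[0.9, 1.1]; and mark–expression correlations within 0.1 of their
targets. Padding arithmetic (90 kb final boundaries, 80 kb added) and
the 1 Mb loop-span cap are exact checks.

Passing on synthetic data shows the callers recover the structures the
generative model plants, under Poisson noise at realistic depth. It does
not show robustness to what the generator omits: centromeres and
assembly gaps, restriction-fragment and mappability bias (ICE removes
smooth bias but the generator plants none), replicate variability,
copy-number variation, nested or overlapping genes, and trans
compartment structure. Those caveats bound any claim made from the green
suite.
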