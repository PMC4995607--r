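---
title: "Breed-specific selection scans with altsweep: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-specific selection scans with altsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altsweep)
```

## The problem

Domestic populations kept at high altitude for many generations accumulate
allele-frequency shifts at loci that matter for hypoxia tolerance. Against a
background of drift shared with lowland relatives, a completed or nearly
completed sweep leaves a recognizable footprint: one breed (or a small group
of breeds) strongly differentiated from many lowland reference breeds at the
same narrow genomic interval. `altsweep` implements the scan that detects
this footprint from SNP-array genotypes and the follow-up analyses that
interrogate a candidate interval with dense re-sequencing data.

## The model and the statistic

**Pairwise F_ST.** For a focal population $i$ and a reference $j$ we use the
unbiased Weir–Cockerham (1984) estimator at each locus, built from three
variance components: $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), with
$\hat\theta = a/(a+b+c)$. Two choices matter and are deliberate:

* Negative per-locus $\hat\theta$ values are **retained**. Truncating them
  at zero would shift the genome-wide mean and standard deviation that
  standardize $d_i$, biasing the scan.
* Loci monomorphic in both populations of a pair are **undefined**, not
  zero; they are excluded pairwise, so a locus can be defined against one
  reference and undefined against another.
* Genome-wide summaries use the **ratio-of-sums** estimator
  $\sum a / \sum (a+b+c)$, never the mean of per-locus ratios, which weights
  loci by their information content.

**The d_i statistic.** For focal population $i$ at each locus,

$$d_i = \sum_j \frac{F_{ST}(i,j) - \mathrm{E}[F_{ST}(i,j)]}
                    {\mathrm{sd}[F_{ST}(i,j)]},$$

summing over the reference populations $j$, where the expectation and
standard deviation are taken over all scanned loci for that pair (sample
standard deviation, $n-1$). A locus where the focal breed is unusually
differentiated from *many* references at once accumulates a large sum; a
locus drifted in one reference only does not. Per-pair standardized terms
are retained in the result for audit.

**Empirical significance.** The genome is its own null:
$P_E = \#\{k: d_k \ge d\}/N$. Loci with $P_E < 0.005$ (strictly) are
significant. With $N$ distinct values this keeps the top $k$ loci where $k$
is the largest integer with $k/N < 0.005$ — for example exactly 219 loci
out of 43,835. We chose the strict-inequality reading over "top
$\lceil 0.005N\rceil$" because it is what the tail-proportion definition of
$P_E$ implies; the two differ by at most one locus.

**Region merging.** Significant SNPs within 500 kb of each other (gap
$\le$ 500,000 bp, inclusive, single-linkage so chains merge transitively)
become one region. Region bounds are member SNP positions, not extended
flanks: three SNPs at 57,764,872 / 57,816,492 / 57,915,106 bp give a
150.234-kb region; the first two alone give 51.620 kb. Isolated SNPs form
width-0 regions rather than being dropped, so regions always partition the
significant set.

**Scan-level MAF filter.** Before scanning, loci with pooled minor-allele
frequency below 0.05 across the union of focal + reference samples are
excluded (kept at exactly 0.05). Pooled-union was chosen over per-population
filtering because the scan's moments are genome-wide properties of the
pooled comparison set; the choice is exposed as `scan_min_maf`.

## Quality control and LD utilities

QC applies, in a fixed order: sample missingness (> 0.10 removed), locus
call rate (< 0.90 removed) and locus missingness (> 0.10 removed), minor
allele frequency (< 0.05 removed, strict), then restriction to a supplied
autosome list (chromosome labels are opaque strings; no species is
hard-coded). Because removing loci changes sample missingness and vice
versa, the pass is iterated to a fixpoint, which makes `qc_filter`
idempotent — a property the test suite asserts. Every removal is reported
with its triggering rule.

LD is summarized by the composite genotype $r^2$ (squared Pearson
correlation of dosage vectors) since no phasing is assumed. Pruning follows
the familiar 50-SNP/5-SNP/0.2 sliding-window scheme; within an offending
pair the lower-MAF locus is removed (tie: the later one in map order) — a
tie-break the external tools leave unspecified, fixed here so output is
deterministic.

## What the simulator emulates — and what it does not

`simulate_panel()` draws, for each locus, an ancestral frequency $p$
(uniform on (0.05, 0.95) by default) and per-population frequencies from
the Balding–Nichols Beta distribution with mean $p$ and variance
$p(1-p)F$; genotypes are two independent allele draws (Hardy–Weinberg
within populations). $F$ is the expected fixation index of each population
against the ancestral pool, so configured drift is directly recoverable
from the realized data — the estimator-recovery tests exploit this
closed-form control, which is why Balding–Nichols was preferred over a
coalescent simulator for a scan that only consumes allele-frequency
structure.

Defaults mirror a SheepHapMap-scale study: 12 populations (4 highland, 8
lowland) of 24 diploids, 45,000 autosomal SNPs on 26 chromosomes, drift
$F = 0.10$ (pairwise differentiation in the 0.08–0.20 band). Tests and the
acceptance script run deliberately scaled-down panels (hundreds to a few
thousand loci, 2–6 populations) chosen so that every statistical property
they assert is already stable at that size.

Sweeps are modelled as **end states**: a sweep locus's highland frequency
is overridden with a target value (e.g. 0.95) while lowland populations
keep their drifted frequencies. No selection trajectory, recombination map
or mutation model is simulated. Loci are independent unless the LD-block
mode is enabled, in which case adjacent loci copy a shared template
genotype column with a small per-genotype resampling rate — enough LD
structure to exercise pruning and decay curves, but not a realistic
haplotype model. Consequently, passing tests show the *estimators and
rules* behave correctly under the assumed frequency model; they say nothing
about ascertainment bias, family structure, or genotyping artefacts in real
array data.

`simulate_reseq_panel()` emulates a small candidate-gene re-sequencing
panel (default: 400 sites over chr7:57,774,972–57,846,735, 4 highland vs 8
lowland diploids): divergent sites are fixed for the alternate allele in
the highland group and strictly polymorphic (frequency in (0.2, 0.8)) in
the lowland group, the footprint of a completed local sweep.

One root seed drives named sub-streams per stage (ancestral draws, drift,
genotypes, missingness), so each stage is independently reproducible.

## Follow-up analyses

Each re-sequencing site is tested with a two-sided Fisher's exact test on
the 2×2 table of (alt, ref) chromosome counts by group, using the standard
"as-or-less-probable tables" two-sided rule (`stats::fisher.test`; the test
suite checks it against exhaustive enumeration to 1e-12). Significance is
strict $p < 0.001$. Worth knowing about the test's resolution at these
sample sizes: a site fixed in 4 highland diploids against fixed-reference
in 8 lowland diploids reaches $p = 1/\binom{24}{8} \approx 1.4\times
10^{-6}$, but fixed-vs-balanced (8/8 vs 8/16) does **not** reach 0.001.
Sites are pre-filtered at pooled MAF > 0.05 (strict); pooled rather than
per-group because the filter describes the combined panel.

Site classification against a gene model partitions every position into
exonic / intronic / upstream / downstream / intergenic. Upstream distance
is measured to the **start codon** (how regulatory variants are
conventionally reported), the flank defaults to 5 kb, and a site beyond the
flank is intergenic. Conserved-element overlap converts the 1-based site
position to the 0-based half-open BED convention in exactly one place
(`overlap_conserved`), where it is tested at both boundary positions.

The altitude-gradient summary orders per-population frequencies by
altitude rank and reports the Spearman correlation (midranks for ties;
undefined and flagged when frequencies are constant).

## Population-structure companions

PCA is standard centred-dosage PCA with per-locus mean imputation of
missing genotypes; signs are fixed (largest-magnitude loading positive) so
output is deterministic. Population distances are genome-wide ratio-of-sums
$\theta$ — the paper-style alternative (Nei's distance) would serve
equally for tree drawing, and since trees on real data are not a
reproduction target the simpler choice that reuses the differentiation
module was taken; slightly negative $\theta$ for undifferentiated pairs is
clamped to 0 so the matrix is a valid distance. Neighbor joining is the
classic Saitou–Nei agglomeration with the lowest-index tie-break and
negative branch lengths clamped to 0 with a warning; on additive matrices
it reproduces the generating tree's path lengths exactly, which the tests
verify against an independent implementation.

## Numerical and degenerate-input choices

* A reference pair with zero F_ST standard deviation contributes 0 to
  every locus's $d_i$ and triggers a loud warning rather than aborting the
  scan.
* Undefined $\theta$ terms contribute 0 to $d_i$ and are counted in a
  message.
* Non-finite $d_i$ values are excluded from the empirical-p denominator
  with a warning.
* Fisher tables with a zero margin give $p = 1$ and a degenerate flag.
* An all-missing population at a locus yields an undefined allele
  frequency (`NA` + flag), never 0.
* PED/MAP I/O writes a 6-column MAP (alleles appended) so the
  dosage-counting allele (`a2`, the second listed) survives a round trip;
  4-column MAPs are read with lexicographic allele assignment. The PED
  missing code is `0 0`.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(
  n_loci = 5000,
  populations = data.frame(
    name = c("H1", "H2", "L1", "L2", "L3", "L4"),
    altitude = rep(c("high", "low"), c(2, 4)),
    n = 25, drift_F = 0.05),
  sweep_loci = data.frame(index = 2500L, high_freq = 0.95, ancestral = 0.1),
  n_chrom = 4, seed = 1)
sim <- simulate_panel(cfg)
res <- run_scan(sim$matrix, "H1", c("L1", "L2", "L3", "L4"))
res
subset(res$scan, significant)
res$regions
```

## Known limitations

* The scan consumes unphased genotype dosages only; haplotype-based
  statistics (EHH, iHS, Rsb) are out of scope.
* Binary PLINK BED files, imputation and phasing are not supported.
* The simulator's independence-across-loci default understates the
  correlation of neighbouring d_i values on real arrays; merged-region
  counts on simulated data are therefore not comparable to real-data
  region counts.
* Multi-population (r > 2) joint $\theta$ and bootstrap confidence
  intervals are not implemented; the scan needs only the pairwise moments.
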