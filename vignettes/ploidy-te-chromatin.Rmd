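---
title: "Comparing TE-associated H3K27me3 between ploidy levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing TE-associated H3K27me3 between ploidy levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyTE)
```

## The question and the model

Whole-genome doubling (WGD) changes expression for only a small fraction of
genes, and part of that change appears to be epigenetic. ploidyTE implements
an interval-based comparison of the repressive histone mark H3K27me3 between
a diploid and a tetraploid line, organized around transposable elements
(TEs): TE bodies inside genes tend to be depleted of the mark, while the
non-TE chromatin next to them is enriched, and in the tetraploid that
enrichment is stronger for some TE superfamilies. The package quantifies
these patterns, tests them, and asks whether the cognate genes' expression
moves in the opposite direction, as expected for a repressive mark.

The analysis unit is a *(gene, region kind, segment class)* triple:

* region kinds: the gene **body** and fixed, strand-oriented 2 kb
  **upstream** and **downstream** flanks;
* segment classes: the **TE** part and the **non-TE** part of the region,
  obtained by clipping all TE annotations to the region, merging overlapping
  or bookended spans, and complementing (the two classes tile the region
  exactly).

Every TE record also receives a single genomic context by a
majority-overlap rule: the first category in the priority order
body > upstream > downstream whose feature union covers *strictly more than
half* of the TE's length; otherwise intergenic. Feature unions are reduced
per category first, so split or overlapping gene annotations cannot
double-count a base. The priority order is our tie-break; the rule itself
only fixes "more than half against a genomic feature", and a deterministic
order makes the classification reproducible.

## Signal definition

H3K27me3 is quantified from paired-end ChIP fragments at mononucleosome
resolution. Each properly paired, primary alignment with MAPQ strictly
greater than 50 contributes one fragment (the template span of the leftmost
mate); "uniquely mapped" is operationalized as the MAPQ filter alone because
tag conventions are aligner-specific. The fragment's **midpoint**
`floor((start + end)/2)` is a point mass — no extension or smoothing, which
is appropriate for ~150 bp MNase fragments. Duplicates are kept, since the
protocol this models does not deduplicate.

For an interval set of total length $L$ with $k$ midpoints in a library of
$N$ fragments, the density is

$$ d = \frac{k}{L \cdot N/10^6} $$

(midpoints per bp per million fragments), and the reported signal is the
IgG-corrected ratio

$$ r = \frac{d_\mathrm{ChIP} + \varepsilon}{d_\mathrm{IgG} + \varepsilon},
   \qquad \varepsilon = 10^{-3}. $$

We use a ratio rather than a subtraction because it is scale-free across
library depths and non-negative by construction; the symmetric pseudocount
$\varepsilon$ (configurable) only matters for nearly empty IgG intervals and
is small relative to typical enriched densities (order 0.1–1 in these
units). Per gene, counts are summed across all segments of a class and
divided by the summed length — a length-weighted aggregate that is robust to
tiny segments left over by clipping.

## Testing

Matched per-gene signal values are compared with the paired Wilcoxon
signed-rank test: zero differences dropped, average ranks for ties,
$W = \min(W^+, W^-)$. For up to 25 retained pairs the two-sided p-value is
exact, from the full $2^n$ sign-assignment distribution (computed by a
subset-sum convolution over the doubled rank values, so ties are handled
exactly); beyond that, a normal approximation with tie correction and a 0.5
continuity correction. The crossover at 25 keeps enumeration cheap where the
approximation is weakest. Dropping zeros (rather than Pratt's method)
matches the default of the statistical software commonly used for this test.

Three families of tests are run per study:

* **ploidy comparisons** — tetraploid vs diploid `igg_ratio`, for every
  region kind × segment class × superfamily stratum (plus an `all` stratum);
  a stratum is the set of genes carrying that superfamily *in that region
  kind*, which keeps flank panels region-local;
* **TE vs non-TE contrasts** — within one condition, each gene's TE segment
  value against its non-TE segment value in the same region;
* **expression linkage** — per superfamily, paired TPM (tetraploid vs
  diploid) over the body-carrier genes; a link is *concordant negative*
  when the chromatin and expression directions oppose each other.

Benjamini–Hochberg adjustment is applied once across all records of a run
(a single coherent error rate, rather than per-panel control), via
`p.adjust`. Strata with fewer than 5 matched genes are reported with
`p = NA` rather than silently dropped. DE labels from externally supplied
statistics use the strict thresholds FDR < 0.01 and |log2FC| > 1; the
fold-change threshold is read as two-sided since both directions are
reported downstream. Reported percentages round half away from zero at the
printed precision, which is how the headline shared-gene percentages are
reproduced.

## What the generator plants, and what it does not

`synth_config()` fixes the synthetic study conditions. Geometry: five 1 Mb
chromosomes; 500 single-exon genes of 1.5–2.5 kb placed uniformly,
non-overlapping, with both 2 kb flanks inside bounds and disjoint from other
genes' footprints; 75 TEs per superfamily of 0.2–1 kb, split 30/15/15/15
into bodies, upstream flanks, downstream flanks and intergenic gaps, each
placed fully inside its target feature and at most one TE per (gene, region
kind). The one-TE-per-region choice keeps superfamily strata disjoint, so a
planted effect in one superfamily cannot leak into another's panel; the
dissection and category code are exercised on overlapping and nested TEs by
the property tests instead.

Intensity model (midpoints per bp): IgG flat at 0.02; ChIP piecewise
constant at $\lambda = 0.02$ background, $\lambda\delta$ on TE bodies
($\delta = 0.3$), $\lambda\varphi$ on non-TE segments of TE-carrying regions
($\varphi = 1.4$), times $\beta = 1.5$ in the tetraploid for regions
carrying one of the five boosted superfamilies (LINE, CACTA, PIF/Harbinger,
Tc1/Mariner, unclassed DNA transposons). The boost deliberately applies only
to non-TE segments: TE bodies themselves show equal-or-lower signal in the
tetraploid. Midpoint counts per segment are Poisson with mean intensity ×
length (exact and fast, and the same algebra used to reason about expected
counts in tests), positions uniform, fragments reconstructed as 150 bp
spans centred on the midpoint with MAPQ 60. At these settings a library is
roughly 100k fragments — a realistic depth for a 5 Mb toy genome — giving
per-gene non-TE body counts of ~40, i.e. noticeable but not overwhelming
Poisson noise.

Expression: per gene and condition, NB counts (two replicates,
dispersion 0.05) with mean
$200 \cdot 2^{s\,(r_g - \bar r)}$, where $r_g$ is the realized genic IgG
ratio and $s = -0.8$ the coupling slope; centring on the grand mean across
both conditions preserves between-condition differences. Every stage is
seeded deterministically from one integer seed (separate derived streams
per stage, so regenerating one track never shifts another).

The generator emulates planted enrichment structure, not real data: no
mapping artifacts, duplicates, MAPQ noise, replicate ChIP libraries,
isoforms, nested TE annotations, or chromatin domains beyond the planted
piecewise intensity. Passing tests therefore demonstrate that the pipeline
recovers the structure it is pointed at, under Poisson/NB noise at realistic
depth — not that the biological effect exists in any particular organism.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; conversion happens only at
  the GFF3 boundary. Midpoint counting is left-closed, right-open.
* Empty fragment sets build a valid index with library size 0; density then
  errors rather than returning 0/0.
* All-zero paired differences give $p = 1$ and no direction (a convention,
  not an error); all-zero counts give all-zero TPM.
* A TE on a chromosome without genes is intergenic (with a warning), and a
  TE shared by two genes' regions contributes to both dissections: context
  is per-TE, dissection is per-gene.
* Whether 2 kb flanks are strand-aware is ambiguous in the field; we orient
  them by gene strand. With symmetric flank widths this only relabels
  upstream vs downstream.
* The estimated tetraploid boost (median per-gene tetraploid/diploid ratio
  over boosted genic non-TE records) is biased slightly low (~5–10%)
  because the boost itself inflates the tetraploid library size, which the
  per-million normalization divides back out. This is inherent to
  depth-normalized signal and stays well within the ±15% recovery band used
  in the tests.

## Problem sizes used by the test-suite

Unit and property tests run on small per-chromosome fixtures (hundreds of
bases to kilobases, 100–1000 random repetitions). Integration tests use a
reduced study (2 × 0.2 Mb chromosomes, 24 genes, 6 TEs per superfamily,
intensity 0.05). The acceptance-level checks use the default 500-gene study:
one full pipeline run for recovery/linkage checks, a 20-seed replicate of
the stratified comparison for the specificity check, and 2000 simulated
paired datasets of size 20 for null calibration of the signed-rank test.

## Known limitations

* One ChIP library per condition; pooling replicates is the caller's
  responsibility.
* No peak calling, browser tracks, TE age/divergence analysis, or negative
  binomial DE model — DE statistics are accepted as input and only
  thresholded here.
* The pipeline reports associations between TE context, H3K27me3 and
  expression; it makes no causal claim about deposition mechanisms.
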