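---
title: "Methods: clone discrimination, clonal diversity and spatial architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone discrimination, clonal diversity and spatial architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalarch)
```

## The problem

Clonal plants blur the unit of counting: a single sexually produced
individual (a *genet*) can cover tens of square meters with hundreds of
stems (*ramets*). Field protocols therefore sample one ramet per grid
cell per life stage, genotype each at a panel of co-dominant SSR loci,
and reconstruct the genets statistically. `clonalarch` implements that
reconstruction and everything downstream of it: diversity indices,
spatial genet architecture, and group comparisons, plus a ground-truthed
simulator so the whole chain can be validated end to end.

## Data model and conventions

A sample is a row: id, quadrat, 1-based grid cell (row, col), life stage
(`on_floor` / `on_tree`), and two integer allele calls per locus. Allele
pairs are stored in canonical ascending order, so (102, 100) and
(100, 102) are one genotype. Missing data must be whole-locus (one
present allele is a scoring inconsistency and a hard error), and the
default policy is *strict*: any sample with a missing locus is dropped
before clone discrimination, matching how SSR clonality studies retain
only fully genotyped samples.

The protocol records presence per 1-m cell, not sub-cell coordinates, so
the metric position of a ramet is its **cell center**. This is the only
defensible choice, but it quantises geometry: the smallest positive hull
area for a genet spanning a 2×2 block of cells is 1 m², and published
genet areas computed from other conventions are only approximable.
File order is the canonical order for every deterministic tie-break
downstream (MLG ids, round-robin representatives, genet numbering).

## Clone discrimination

**MLGs.** Exact genotype identity across the chosen loci. Marker
resolution is assessed by the genotype accumulation curve: MLG counts
over all $\binom{L}{k}$ locus subsets (exhaustive up to
`max_exhaustive = 1000` subsets per size, sampled beyond), with the
plateau statistic the smallest $k$ whose maximal count already equals
the full-panel count.

**$P_{gen}$ and $P_{sex}$.** $P_{gen} = \prod_i f_{a_i} f_{b_i} \cdot 2^h$
(Parks & Werth), with $h$ the number of heterozygous loci, computed in
log space. Allele frequencies use the round-robin estimator: for locus
$i$, collapse on all loci except $i$, keep the first sample of each such
MLG, and count alleles over those representatives — removing the
inflation large clones cause. $P_{sex}$ is the binomial upper tail
starting at $n$ (the printed convention; `n_minus_1` is exposed as an
option). A somatic-mutant allele may occur in no representative; its MLG
then has no defined round-robin $P_{gen}$ and the pipeline reports NA
rather than imputing a frequency.

**Distances and MLLs.** The dissimilarity is the total allele-mismatch
count with optimal within-locus pairing (0, 1 or 2 per locus) — the
standard metric for co-dominant markers; e.g. (100, 102) vs (102, 104)
counts 1. MLGs are agglomerated into MLLs under farthest-neighbour
(complete) linkage by default: conservative, because a chain of mutants
can never bridge two distinct genets. Merges proceed by ascending pair
distance, ties broken by lowest MLG id, so results are permutation-stable.

**Threshold prediction.** Candidate cutoffs are the *distinct* merge
heights of the full agglomeration (the distances at which the MLL count
changes while sweeping the cutoff upward). The first
$\lceil \mathrm{clonal\_fraction} \times n \rceil$ candidates are
retained (default fraction 0.5) and the threshold is the midpoint of the
largest gap between consecutive retained candidates, ties to the lowest
gap; fewer than two candidates yield threshold 0 (no collapsing).
Deduplication matters: the mutation-scale heights collapse to a couple of
distinct values (1, 2, …), so the retained half reaches the first
founder-scale height and the exploited gap separates the two scales.

Two regimes deserve honesty. *No noise:* there are no mutation-scale
distances, the height spectrum is unimodal, and the predictor can only
return a founder-scale midpoint — which over-merges. Clone calling
without noise is exact MLG matching (threshold 0), and that is how the
noise-free recovery tests are run. *Very few genets:* with $G \le 5$
there are at most four distinct founder-scale heights; the retained half
of the candidate list may never reach them and the threshold lands at
mutation scale, splitting mutant clouds. The remedy — used by the field
workflow this package mirrors, and by our acceptance tests — is to
estimate one threshold from the pooled campaign (all quadrats), where
founder-scale heights are plentiful. Pooled campaigns recover the true
genet count in 20/20 seeded runs across the whole stated mutation range
(1e-3 to 1e-2 per allele per ramet).

## Diversity indices

With clone sizes $n_i$, $N = \sum n_i$, $G$ genets:

- richness $R = (G-1)/(N-1)$;
- Simpson $D = 1 - \sum n_i(n_i-1)/[N(N-1)]$, with range
  $D_{min} = \frac{(2N-G)(G-1)}{N^2}\cdot\frac{N}{N-1}$ (one dominant
  clone plus singletons) to
  $D_{max} = \frac{G-1}{G}\cdot\frac{N}{N-1}$ (even partition), and
  evenness $V = (D-D_{min})/(D_{max}-D_{min})$ — reported as *undefined*
  for $G = 1$, where the range degenerates (a design choice; no benchmark
  quadrat constrains it);
- Pareto $\beta$: OLS of $\log_{10} N_{\ge X}$ on $\log_{10} X$ over the
  *distinct observed* clone sizes (this choice makes {4, 2, 1, 1} exactly
  collinear with $\beta = 1$), refused below 3 distinct sizes — the same
  refusal the benchmark applies to its two-genet quadrat. A perfect fit
  has zero residual variance, where the slope t-test degenerates; the
  p-value limit 0 is reported.

Cross-quadrat summaries use the sample SD ($n-1$); this reproduces the
published 77.0 ± 28.2 for ramet counts (98, 88, 45), confirming the
convention, and the percentage rows are summarised from unrounded
percentages (rounding first would give 0.7 where 0.6 is printed).

## Spatial architecture

Genet hulls are convex polygons over cell centers; 1–2 distinct points or
collinear sets are degenerate (area 0). Overlap between two polygons
means *positive-area* intersection (Sutherland–Hodgman clipping of convex
polygons); boundary touching is measure-zero contact, not intermingling,
and does not count. A degenerate hull overlaps a polygon iff it touches
the polygon's closure; two degenerate hulls never overlap. The overlap
count's jackknife: $G$ leave-one-genet-out totals $\theta_{(i)}$,
variance $\frac{G-1}{G}\sum(\theta_{(i)}-\bar\theta)^2$, CI
$\bar\theta \pm 1.96\,SE$; a percentile CI over the leave-one-out values
is available. Quadrats are called different when CIs do not overlap. The
exact CI construction of the originating field protocol is not published;
this standard estimator is a declared substitute.

Identity-by-distance bins all $\binom{N}{2}$ ramet pairs into half-open
1-m bins (the sampling grain) and reports the per-bin fraction sharing a
genet; forest-type aggregation is the mean ± SD of per-quadrat fractions.
Stem density is the mean of ten 1-m² sub-quadrat counts.

## Group statistics

The rank-sum test enumerates the permutation null over the observed
midranks when both groups have ≤ 10 observations (valid under ties),
otherwise uses the tie-corrected normal approximation; two-sided p is
twice the smaller tail, capped at 1. Fisher's exact test sums
hypergeometric probabilities ≤ that of the observed table; the effect is
the sample odds ratio with a Woolf CI (NA with a zero cell). Tukey HSD
uses `stats::ptukey` on the one-way layout with Tukey–Kramer standard
errors — the contract is the adjusted p, not a bespoke quadrature — and
the compact letter display uses insert-and-absorb with deterministic
label ordering.

## The simulator: a stated world

Each scenario fixes: founders placed uniformly (young: 2–5; old-growth:
14–30, drawn uniformly under the seed); HWE founder genotypes from
symmetric Dirichlet(1) population frequencies over 8 alleles/locus at 11
dinucleotide loci, with founders redrawn until all pairwise genetic
distances are ≥ 4 (the "well-separated founders" premise that makes
threshold-based clone calling identifiable at all); per-founder ramet
budgets that are negative binomial (dispersion 5) around ≈ 1000 total
ramets for young (≈ 10 stems/m²) and ≈ 14500 for old-growth
(≈ 145 stems/m², the > 14× published contrast); branching stolon random
walks (exponential steps, mean 0.8 m young / 0.6 m old; branching
probability 0.2 / 0.3; reflection at the quadrat boundary); on-tree
probability 0.2 (the ≈ 4–5× on-floor excess); stepwise somatic mutation
(± one repeat unit) and pool-redraw genotyping error, both default 0.
Sampling keeps one uniformly chosen occupant per (cell, stage).

These defaults are the stated world: where the benchmark states a value
(founder ranges, densities, stage ratio, mutation regime) it is used;
where it does not (allele counts, Dirichlet concentration, step lengths,
dispersion), a realistic value was fixed once and is not tuned against
test outcomes.

What a green test does establish: the pipeline recovers known genet
structure exactly without noise, and with realistic mutation noise when
the threshold is estimated from a pooled campaign; diversity and spatial
statistics behave per their analytic contracts. What it does not: real
SSR data have null alleles, stutter, linkage, non-uniform allele ladders
and spatially autocorrelated founder placement, none of which the
generator emulates — so agreement with the generator is necessary, not
sufficient, evidence of field validity. The published real-data results
(densities 10.5 vs 145.1 stems/m², per-quadrat curves) require the
archived genotype deposit and are deliberately not asserted.

## Numerical choices and degenerate inputs

Geometry uses an epsilon of 1e-9 on cross products and requires
intersection area > 1e-8 m² to call an overlap (cell-center coordinates
make true slivers vanishingly rare). Pgen is computed in log space.
`clonal_richness` is undefined for N < 2, `simpson_evenness` errors when
sizes do not sum to N, `pareto_index` refuses < 3 distinct sizes, the
jackknife CI is NA for G < 2, and an all-identical rank-sum input returns
p = 1 with a warning. All randomness flows from explicit seeds; equal
seeds give byte-identical output files.

## Known limitations

- Cell-center positions quantise hull areas; sub-cell mapping would need
  field coordinates the protocol does not record.
- The cutoff predictor needs several distinct founder-scale merge
  heights; single quadrats with $G \le 5$ should inherit a pooled
  campaign threshold (see above).
- Round-robin Pgen is undefined for alleles seen only in
  non-representative samples (reported NA).
- No null-allele or stutter error model; no spatial autocorrelation
  statistics (Sp, kinship regression) — out of scope by design.
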