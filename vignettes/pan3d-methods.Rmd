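---
title: "Methods: pan-3D genome analysis of multi-accession Hi-C panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-3D genome analysis of multi-accession Hi-C panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pan3d)
```

## Overview

`pan3d` re-implements, as a tested pipeline, the chromatin-structure layer
of a pan-genome analysis: per-accession calling of A/B compartments,
I regions, TAD boundaries, contact domains and directionality indices from
Hi-C contact matrices, followed by cross-accession classification
(conservative/variable compartments, the coefficient of compartment
variation, core/dispensable/private boundary clusters) and association of
3D-genome variation with structural variants (SVs), genomic features, gene
expression, and windowed $F_{ST}$ selection scans. A synthetic
multi-accession generator with planted ground truth stands in for real
Hi-C panels, so every stage is testable end to end without external data.

## Contact matrices and balancing

A `ContactMatrix` is a symmetric, binned intra-chromosomal count matrix;
coordinates are 0-based half-open throughout the package and GFF3 is
converted at the boundary. Trans (inter-chromosomal) matrices are out of
model: all structures called here are cis.

Balancing removes multiplicative per-bin biases so that every retained bin
has the same total contact. `ice_balance()` is the iterative-correction
scheme: divide by the (square root of the) normalized row sums until the
relative deviation falls below `tol` (default `1e-8`). The square-root
damping leaves the fixed point unchanged but converges on weakly connected
support where the undamped iteration oscillates. `kr_balance()` computes
the Knight-Ruiz scaling `diag(b) M diag(b)` with unit row sums via a
damped symmetric Sinkhorn iteration. Because the doubly stochastic scaling
of a symmetric non-negative matrix with total support is unique up to a
global factor, KR and ICE agree up to scale on strictly positive matrices
(asserted to `1e-6` in the tests); on reducible support (disconnected
blocks), where the scaling is not unique, KR falls back to ICE with a
warning.

Masking: bins with zero total count are always excluded. For structural
(25-kb) matrices, bins in the lowest 2% of total counts are additionally
masked (`low_quantile = 0.02`), a stand-in for the low-coverage filters
used on real data. The compartment pipeline at 100 kb masks only
zero-coverage bins: under the generator's uniform coverage a relative
quantile filter would mask a different random bin set in every accession
and manufacture spurious pan-compartment variability. Both choices are
arguments, not constants.

`observed_expected()` divides each cell by the mean of unmasked cells at
the same diagonal distance; distances with zero expectation yield NA, never
infinities. `estimate_map_resolution()` returns the smallest bin size at
which at least 80% of loci carry at least 1000 contacts.

## A/B compartments

Compartment signal is the leading structure of the Pearson correlation
matrix of the observed/expected map at 100-kb resolution.
`compute_eigs()` returns the top three eigenvectors by eigenvalue
magnitude. The eigenvector sign and index are arbitrary, so `call_ab()`
selects the eigenvector with the largest absolute correlation to gene
density — automating what is traditionally a manual adjudication of the
E1/E2/E3 tracks against gene density — orients it so the correlation is
positive, and labels positive bins A, negative bins B. The chosen index
and orientation are stored on the track for audit. If no eigenvector
reaches the correlation floor (default |r| = 0.2) the chromosome is
flagged uncallable and all labels are NA. After orientation, A is always
the gene-dense, positive side, regardless of the raw solver sign.

I regions are the A/B intersection zones: a bin is an I bin when the
5-bin (500-kb) window consisting of it and the following four bins
contains both A and B labels. Windows truncated by the chromosome end are
evaluated when at least two labeled bins remain; NA bins neither create
nor veto I status. The partition A-regions / B-regions / I-region-A /
I-region-B covers all labeled bins exactly once, and the I set is
invariant under a global A/B exchange.

## TAD boundaries, domains, directionality

`insulation_score()` slides a 500 kb x 500 kb (20 x 20 bin) square along
the diagonal; for bin $i$ the square covers rows $i-20..i-1$ by columns
$i+1..i+20$ — the off-diagonal flanking form of the insulation method,
which excludes the bin's own row and column (switchable via the span
arguments). Bins within one span of a chromosome end are undefined.
Normalization is $\log_2$ of each bin's raw score over the chromosome
mean.

`call_boundaries()` forms the delta vector — the mean normalized
insulation over the 5 bins (125 kb) left of the bin minus the mean over
the 5 bins right — and takes downward zero-crossings (insulation valleys;
upward crossings are peaks and are discarded). The boundary bin is the
deeper valley of the two crossing bins, descended at most 3 bins to the
local insulation minimum; ties at an exact zero resolve to the left bin.
Boundary strength is the delta at the nearest local maximum left of the
boundary minus the delta at the nearest local minimum right; boundaries
with strength below 0.1 are removed. TADs are the intervals between
consecutive boundaries, with chromosome-end flanks flagged open. The
boundary region — the boundary bin plus one flank bin each side, 75 kb —
is the unit of all cross-accession comparison.

`arrowhead_transform()` computes
$A_{i,i+d} = (M_{i,i-d} - M_{i,i+d}) / (M_{i,i-d} + M_{i,i+d})$, defined
where the denominator is positive. `call_domains_arrowhead()` is a
deliberately simplified corner-score caller: each candidate interval is
scored by the mean of $A$ over the wedge of cells whose upstream mirror
falls inside the interval and whose partner falls beyond it; candidates
reaching the score threshold enter a weighted-interval dynamic program
maximizing net wedge evidence (wedge sum minus half the threshold per
cell, so a full domain beats both splits and dilutions). The variance and
sign-consistency terms of the full Arrowhead heuristic are intentionally
omitted; the caller is corroborative, not the primary boundary method.

`directionality_index()` uses
$DI = \mathrm{sign}(B-A)\,[(A-E)^2/E + (B-E)^2/E]$ with $E = (A+B)/2$,
where $A$ and $B$ are the contact totals to the upstream and downstream
2 Mb. The formula is undefined at $A = B$ (division by $|B-A|$); the
package reports 0 there with a flag, and flags bins whose window is
truncated by a chromosome end.

## Pan-classification

`classify_pan_compartments()` classifies each 100-kb bin by its status
vector across the panel: conservative-A/B/NA when all accessions agree
(including all-NA as its own class, reported separately so percentages
can be quoted with or without it), and variable-onlyA / variable-onlyB /
variable-AB otherwise. The coefficient of compartment variation,
$\mathrm{CCV} = \ln(\#B/\#A)$, is defined exactly on variable-AB bins;
its sign gives the leaning (positive toward B) and it is antisymmetric
under exchanging the counts. `pan_saturation_curve()` draws random
accession orderings and classifies every prefix, so conservative counts
are non-increasing and variable counts non-decreasing in the panel size
within each randomization, and the full-panel point reproduces the exact
classification.

Boundary comparison works on 75-kb boundary regions lifted through exact
coordinate maps (`liftover_interval()`, which unions colinear mapped
pieces and fails below 50% coverage). Two regions match when they overlap
by at least half the shorter region — for exact 3-bin regions precisely a
boundary shift of at most one bin, the stated shift allowance. Matched
boundaries are common, others specific; query boundaries that fail
coordinate conversion are query-specific. `cluster_boundary_regions()`
builds the match graph over all accessions' regions (an edge wherever the
directed similarity reaches the cutoff, default 0.5, in either direction)
and takes single-linkage connected components; a cluster is core when its
members span every accession, private with exactly one accession,
dispensable otherwise. Single linkage was chosen because it is
deterministic, order-independent, and matches the "chain of pairwise
matches" semantics of pairwise alignment evidence; the similarity cutoff
is a config knob logged in every report.

## SV association and selection scan

`classify_sv_vs_boundary()` calls an SV ABA (absolute boundary-affecting)
when it spans a whole 25-kb boundary bin, PBA when it overlaps one
partially, NBA when it lies strictly inside a TAD. The boundary unit is
the bin, not the 75-kb region — the region is a comparison construct; a
switch to region-based classification is provided. Effect and
contribution per SV class follow the definitions: contribution = the
fraction of specific boundaries carrying the SV class; effect = the
fraction of SV-carrying boundaries that are specific; the one-sided
Fisher P comes from `fisher.test` (the hypergeometric tail). In pairwise
comparisons, these statistics are computed on the reference side: a
boundary deleted in the query is reference-specific and carries the
query's SV.

`sv_compartment_enrichment()` compares the observed SV count in a segment
set (e.g. A compartments or I regions) with a null built by re-placing
the per-chromosome segment length multiset uniformly and without overlap
(rejection sampling with a capped retry, then placement into a random
sufficient gap). The empirical P uses the +1 correction and is therefore
never exactly zero; a normal-approximation P from the z score is reported
alongside.

`windowed_fst()` uses the Weir-Cockerham variance components in their
allele-count form (the package consumes allele-count tables, not
genotypes, so the within-individual heterozygosity correction is not
computable; Hudson's estimator is available as an option). Window values
are ratios of sums over polymorphic sites; windows with fewer than 5 such
sites are undefined and excluded from ranking. Selected regions are the
top 5% of defined windows, merged when adjacent. The estimator is
unbiased around zero, so identical allele frequencies give slightly
negative values — the tests assert $F_{ST} \in [-\epsilon, 1]$, not
non-negativity.

## The synthetic panel

`simulate_reference()` builds a reference genome model: alternating A/B
blocks (geometric lengths, mean 1.5 Mb) on a 100-kb grid; a TAD tiling
with log-normal sizes of median 475 kb (the soybean scale), clamped to
[150 kb, 1.5 Mb]; TSS, GC and repeat tracks whose means differ between A
and B (defaults: 8 vs 3 TSS per 100 kb, GC 0.32 vs 0.38, repeat coverage
0.30 vs 0.60, with B repeat draws weighted toward Gypsy and satellite
among the 17 repeat subtypes). Feature means are mixed through a 5-bin
window of the local A fraction, so bins near compartment transitions —
the future I regions — carry intermediate features by construction.

`simulate_contact_matrix()` draws Poisson counts around
$\lambda(i,j) = s\,\max(|i-j|,1)^{-\alpha}\, c^{[\text{same comp}]}\,
t^{[\text{same TAD}]}$ with defaults $s = 150$, $\alpha = 1$, $c = 1.6$,
$t = 2$ — contact enrichments in the range reported for plant Hi-C; a
negative-binomial option exists but is off by default, and `noise =
"none"` returns rounded expectations for deterministic tests. No
published noise model or effect sizes exist for these quantities, so all
generator magnitudes are explicit free parameters, fixed once here and
not claims about soybean.

`simulate_accession_panel()` derives each accession from the reference by
a non-overlapping SV edit list applied left-to-right in reference
coordinates: PAV deletions, CNV gains modeled as tandem duplications
(the extra copy is unmapped in the coordinate map, which must stay
one-to-one), inversions, and reciprocal translocations. Expected counts
per accession default to PAV 30, CNV 12, INV 6, TRANS 1. Ten percent of
PAVs are planted to delete a TAD boundary bin entirely (the ABA case) and
ten percent to clip it partially (PBA); 3% of border-adjacent compartment
bins flip A/B per accession. Every accession records its exact
piecewise coordinate map (round-trip-exact on fully mapped intervals) and
truth labels: lost boundaries and flipped bins.

Two details matter for honest scoring. First, boundary truth is taken
from the accession's own structural track in query coordinates (the
partition its matrix is simulated from), because inversions relocate
junctions non-locally and naively lifting reference junction bins gives
wrong truth near inversion edges. Second, SV edits can slice TADs into
slivers of a few bins at inversion/translocation edges; fragments below
the minimum TAD size are merged into the preceding domain, since
chromatin domains below that scale are not stable and no insulation
method could separate them.

Reference-space matrices emulate reference-mapped Hi-C (deleted sequence
depletes coverage; fully deleted bins are masked); self-space matrices
emulate self-mapped Hi-C on the accession's own genome. Compartments are
called in reference space at 100 kb, boundaries in self space at 25 kb,
mirroring the dual-mapping design of real pan-3D analyses.

`simulate_expression()` draws log-normal FPKM with A-mean 20 and B-mean 4
(ratio ~5, typical of active/inactive compartments), per-accession noise
sdlog 0.2, and multiplies genes within 100 kb of a lost boundary by a
shift factor 4 in the affected accession; the DEG table applies the
|fold change| > 2 convention. `simulate_genotypes()` draws two-population
allele counts from a Balding-Nichols model with divergence 0.02 genome
wide and 0.6 in a designated 5% of 25-kb windows (60 allele copies per
population, 10 sites per window).

## What the tests show — and what they do not

All planted-truth results are statements about this generator, not about
soybean: Poisson counts with uniform coverage, exact coordinate maps,
ideal block compartments. Real data add restriction-site and coverage
biases, mapping errors, chain-file gaps, and pericentromeric masking that
the generator deliberately omits. Recovery numbers are computed over the
callable region — boundaries more than one insulation span plus one delta
span (625 kb) from a chromosome end — because the method is undefined
closer to the ends.

On the test panel (two 10-Mb chromosomes, 6 accessions, default noise,
fixed seed) boundary recall within one bin is about 95% and compartment
label agreement above 99%; planted boundary deletions surface as
accession-absent in the clustering at above 95%. At the full study-scale
panel (two 20-Mb chromosomes, 27 accessions) recall settles around 88%:
the extra misses are adjacent boundaries 150-350 kb apart whose
insulation valleys merge under the 500-kb square — an intrinsic
resolution limit of the insulation method when TADs are barely larger
than the window, visible even with noise off. We report that number as
is rather than tuning the TAD size distribution around it.

Problem sizes: the test suite uses 10-Mb chromosomes and 6 accessions;
`scripts/acceptance.R` runs the full 27-accession panel on 20-Mb
chromosomes with 2,000 bootstrap replicates for the enrichment null
(10,000 remains the function default).

## Numerical conventions

Degenerate and edge cases are all given explicit conventions: DI at
$A = B$ is 0 (flagged); O/E on zero-expectation diagonals is NA;
`ccv()` is NA unless both counts are positive; effect size with a zero
denominator is NA, never 0; monomorphic sites contribute nothing to
$F_{ST}$; repeat-fragment midpoints on a bin edge belong to the
right-open bin starting there; boundary-strength ties at exact zero go to
the left bin; empirical bootstrap P values carry the +1 correction.
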