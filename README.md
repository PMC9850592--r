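# pan3d

Pan-3D genome analysis of multi-accession Hi-C panels in R.

Population-scale Hi-C makes it possible to ask how chromatin architecture —
A/B compartments and topologically associating domains (TADs) — varies
across the accessions of one species, and how that variation relates to
structural variants (SVs), genomic features, gene expression, and
selection. `pan3d` implements that analysis as a reusable pipeline for
anyone working with binned intra-chromosomal contact matrices from several
genotypes of one species:

* **Per-accession structure calling** — ICE and Knight-Ruiz (KR) matrix
  balancing; observed/expected transformation; A/B compartments from the
  leading eigenvector of the O/E Pearson correlation matrix at 100 kb,
  oriented against gene density (A = gene dense); I regions (bins whose
  500-kb window contains both A and B); insulation-score TAD boundaries at
  25 kb with the delta-vector strength filter; a simplified arrowhead
  contact-domain caller; the directionality index
  `DI = sign(B−A)·[(A−E)²/E + (B−E)²/E]`, `E = (A+B)/2`.
* **Pan-classification** — conservative vs variable compartment bins and
  the coefficient of compartment variation `CCV = ln(#B/#A)`; saturation
  curves over random accession subsets; boundary-region (75 kb) matching
  through exact coordinate maps with a one-bin shift allowance; single-
  linkage clustering into core / dispensable / private boundary clusters.
* **Variation association** — ABA/PBA/NBA classification of SVs against
  boundaries; bootstrap enrichment of SVs in compartment segments; effect
  and contribution of each SV class to boundary variation with one-sided
  Fisher tests; windowed feature tracks (GC, TSS density, repeat
  coverage); repeat and DEG meta-profiles around boundary classes;
  nonVariation genes; windowed Weir-Cockerham F_ST with the top-5%
  selected-region rule.
* **A synthetic panel generator** — a reference model (compartment blocks,
  TAD tiling with median 475 kb, feature tracks, 17 repeat subtypes)
  edited per accession by PAV/CNV/INV/TRANS events with exact coordinate
  maps and planted ground truth (deleted boundaries, flipped compartment
  bins, shifted expression, selected F_ST windows), so the whole pipeline
  is testable without any external download.

Contact matrices are plain COO TSV (`chrom, bin1_start, bin2_start,
count`, 0-based half-open bin starts); annotations go in and out as
BED/BEDGraph/GFF3/TSV.

## Worked example

Simulate a 6-accession panel on one 10-Mb chromosome, call structures,
and classify the pan-3D genome:

```r
library(pan3d)
ref   <- simulate_reference(list(n_chrom = 1, chrom_length = 1e7), seed = 42)
panel <- simulate_accession_panel(ref, n_accessions = 6, seed = 42)
panel
#> AccessionPanel: 6 accessions, 45-53 SVs per query accession

comps <- pan_compartment_status(panel)     # reference space, 100 kb
comps$tracks$q01$chr1
#> CompartmentTrack q01/chr1: 100 bins (56 A, 44 B, 0 NA), E1

bounds <- lapply(names(panel$accessions),
                 function(a) call_boundaries_accession(panel, a))  # self space, 25 kb
names(bounds) <- names(panel$accessions)
head(bounds$q01$chr1$boundaries, 3)
#>   bin   start     end  strength region_start region_end
#> 1  41 1000000 1025000 0.8516411       975000    1050000
#> 2  70 1725000 1750000 0.8403838      1700000    1775000
#> 3 105 2600000 2625000 0.4437273      2575000    2650000

cls <- classify_pan_compartments(comps$status)
table(cls$class)
#> conservative-A conservative-B    variable-AB
#>             48             36             16

pbc <- pan_boundary_clusters(panel, bounds)
pbc$summary
#>   n_clusters core dispensable private directed_comparisons
#> 1         22    4          16       2                   36
```

Reading the output: accession `q01`'s first chromosome is 56% A
compartment; its first TAD boundary sits at bin 41 (1.000-1.025 Mb) with
insulation strength 0.85, and its 75-kb boundary region (0.975-1.050 Mb)
is the unit used for cross-accession matching. Across the panel, 84 of
100 compartment bins are conservative (same status in all six
accessions) and 16 switch between A and B in at least one accession.
The 6 accessions' boundary regions collapse into 22 clusters: 4 core
(present in every accession), 16 dispensable, 2 private.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/pan3d.R`, with subcommands `simulate`, `compartments`,
`tads` (flags `--is`, `--ids`, `--min-strength`) and `fst`
(`--window`, `--top`).

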