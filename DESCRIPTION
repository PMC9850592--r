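Package: pan3d
Title: Pan-3D Genome Analysis of Multi-Accession Hi-C Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-accession chromatin-structure calling from Hi-C contact
    matrices (ICE/KR balancing, A/B compartment eigenvectors, I regions,
    insulation-score TAD boundaries, arrowhead contact domains,
    directionality index) followed by cross-accession pan-classification
    (conservative/variable compartments, coefficient of compartment
    variation, core/dispensable/private boundary clusters) and association
    of 3D-genome variation with structural variants, genomic features,
    differential expression, and windowed F_ST selection scans. Includes a
    fully specified synthetic multi-accession panel generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
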