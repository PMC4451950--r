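Package: somapiR
Title: Simulation and Quantification of Somatic piRNA Populations from Small-RNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotation, normalization and quantification of PIWI-interacting RNA
    (piRNA) populations in small-RNA sequencing libraries from Drosophila ovarian
    follicle cells. Implements the small-RNA annotation cascade (abundant ncRNA
    subtraction, miRNA identity, size-based siRNA/piRNA classes), perfect genome
    mapping with uniqueness calls, mismatch-tolerant mapping to transposable-element
    consensus sequences, normalization to one million genome-unique piRNAs from a
    germline reference cluster, per-family count tables, 5'-end density profiles,
    fold-change and RNA-IP enrichment computations, efficiency-corrected qPCR and
    ChIP-qPCR quantification, and a normality-gated two-sample testing procedure.
    Includes a synthetic-data generator that builds a self-consistent toy reference
    (piRNA clusters, TE consensi, genic 3'UTR sources, ncRNA and miRNA sets) and
    simulates libraries under named perturbation scenarios for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils,
    car,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
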