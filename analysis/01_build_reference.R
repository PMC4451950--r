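#!/usr/bin/env Rscript

# Step 1: build the toy reference bundle all later steps share.
#
# The bundle has one random chromosome carrying a germline normalizer piRNA
# cluster (42AB-like), a somatic cluster with every soma-dominant TE
# consensus embedded antisense (flamenco-like), three genic 3'UTR piRNA
# sources, two exact genomic copies of each germline-dominant TE, plus
# ncRNA and miRNA sets. Written under results/reference/.

suppressPackageStartupMessages(library(somapiR))

SEED <- 20240901

bundle <- build_reference(seed = SEED)
validate_bundle(bundle)
write_reference(bundle, "results/reference")

cat("Reference bundle written to results/reference\n")
print(bundle)
cat("\nClusters:\n"); print(bundle$clusters)
cat("\nTE panel:\n"); print(bundle$te_panel)
cat("\n3'UTR sources:\n"); print(bundle$utr_sources)
cat("\nCluster 23-mers genome-unique:", cluster_kmers_unique(bundle), "\n")
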