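#!/usr/bin/env Rscript

# Step 4: normalization, per-feature counting, profiles and comparisons.
#
# Every library is scaled to one million genome-unique piRNAs from the
# 42AB-like normalizer cluster; TE-family counts (<= 4 mismatches against
# the consensus) and genome-unique interval counts are tabulated; each
# perturbed condition is compared with the control: scatter + Pearson r,
# per-feature fold changes, and the gated two-sample test contrasting
# soma-dominant against germline-dominant family log2 fold changes.

suppressPackageStartupMessages(library(somapiR))

bundle <- read_reference("results/reference")
ann_files <- list.files("scratch", pattern = "\\.annotated\\.rds$",
                        full.names = TRUE)
stopifnot(length(ann_files) > 0)

tables_te <- list(); tables_iv <- list()
for (f in ann_files) {
  ann <- readRDS(f)
  id <- attr(ann, "library_id")
  bd <- annotation_breakdown(ann, bundle)
  sf <- normalization_factor(bd)
  tables_te[[id]] <- te_counts(ann, bundle, 4, sf)
  tables_iv[[id]] <- feature_counts(ann, bundle, scale_factor = sf)
  write.table(as.data.frame(tables_te[[id]]),
              file.path("results", paste0(id, ".te_counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(tables_iv[[id]]),
              file.path("results", paste0(id, ".feature_counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (fid in c("ZAM_like", "Felement_like", "cluster_flamenco_like",
                "tj_like")) {
    export_profile(profile_feature(ann, bundle, fid, scale_factor = sf),
                   file.path("results", paste0(id, ".profile.", fid, ".tsv")))
  }
  cat(sprintf("%-16s scale factor %.3f\n", id, sf))
}

control <- "WT_Drosha_like"
stopifnot(control %in% names(tables_te))
summary_rows <- list()
for (id in setdiff(names(tables_te), control)) {
  cmp <- compare_libraries(tables_te[[id]], tables_te[[control]])
  fc_te <- fold_changes(tables_te[[id]], tables_te[[control]])
  fc_iv <- fold_changes(tables_iv[[id]], tables_iv[[control]])
  write.table(rbind(fc_te, fc_iv),
              file.path("results", paste0(id, "_vs_", control,
                                          ".fold_changes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tst <- compare_two_samples(
    log2(fc_te$ratio[fc_te$class == "soma_dominant"]),
    log2(fc_te$ratio[fc_te$class == "germline_dominant"]))
  flam <- fc_iv$ratio[fc_iv$feature_id == "cluster_flamenco_like"]
  utr <- mean(fc_iv$ratio[fc_iv$class == "utr"])
  summary_rows[[id]] <- data.frame(
    condition = id, pearson_r = cmp$pearson_r,
    flamenco_fold_depletion = 1 / flam, mean_utr_fold_change = utr,
    soma_vs_germline_test = tst$test_used, p_value = tst$p_value)
  cat(sprintf(
    "%-16s r = %+.3f | flamenco depleted %4.2fx | mean 3'UTR FC %.3f | %s p = %.3g\n",
    id, cmp$pearson_r, 1 / flam, utr, tst$test_used, tst$p_value))
}
summary_df <- do.call(rbind, summary_rows)
write.table(summary_df, "results/condition_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nComparison summary -> results/condition_comparisons.tsv\n")
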