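test_that("normalization factor scales the cluster to one million", {
  expect_equal(normalization_factor(manual_breakdown(500000L)), 2.0)
  expect_equal(normalization_factor(manual_breakdown(1000000L)), 1.0)
  expect_error(normalization_factor(manual_breakdown(0L)), "unusable")
  expect_error(normalization_factor(manual_breakdown(10L), "nope"), "unknown")
})

test_that("after scaling, normalizer-cluster piRNA mass is exactly 1e6", {
  b <- fix_bundle()
  ann <- fix_annotated()
  bd <- annotation_breakdown(ann, b)
  sf <- normalization_factor(bd)
  fc <- feature_counts(ann, b, scale_factor = sf)
  mass <- fc$norm_total[fc$feature_id == "cluster_42AB_like"]
  expect_equal(mass, 1e6, tolerance = 1e-12)
})

test_that("TE counting follows the once-per-family rule", {
  b <- fix_bundle()
  # a read sampled sense from the ZAM-like consensus
  read <- substr(b$te_seqs[["ZAM_like"]], 33, 58)
  ann <- manual_annotated(read)
  tab <- te_counts(ann, b, scale_factor = 2.5)
  zam <- tab[tab$feature_id == "ZAM_like", ]
  expect_equal(zam$sense, 1)
  expect_equal(zam$antisense, 0)
  expect_equal(zam$norm_total, 2.5)
  expect_equal(sum(tab$norm_total), 2.5)  # one family only

  # a read matching two families contributes one count to each row
  b2 <- b
  shared <- substr(b$te_seqs[["ZAM_like"]], 1, 40)
  b2$te_seqs[["Chimeric_like"]] <- paste0(shared,
                                          substr(b$te_seqs[["Tabor_like"]], 1, 200))
  b2$te_panel <- rbind(b2$te_panel,
                       data.frame(id = "Chimeric_like", class = "soma_dominant",
                                  length = 240L))
  ann2 <- manual_annotated(substr(shared, 5, 32))
  tab2 <- te_counts(ann2, b2)
  expect_equal(tab2$sense[tab2$feature_id == "ZAM_like"], 1)
  expect_equal(tab2$sense[tab2$feature_id == "Chimeric_like"], 1)
})

test_that("zero-substitution TE totals match the truth-label oracle", {
  b <- fix_bundle()
  # no somatic-cluster reads, so TE hits come from TE-class reads alone
  w <- stats::setNames(c(0.3, 0, 0.25, 0.25, 0.1, 0.05, 0.05),
                       somapiR:::SOURCE_CLASSES)
  sc <- scenario_config("clean_te", w, mismatch_rate = 0, seed = 8)
  lib <- simulate_library(b, sc, 20000)
  ann <- classify_reads(lib, b)
  tab <- te_counts(ann, b)
  truth <- table(lib$truth$feature[grepl("TE_piRNA", lib$truth$class)])
  for (id in b$te_panel$id) {
    expect_equal(tab$sense[tab$feature_id == id] +
                   tab$antisense[tab$feature_id == id],
                 as.numeric(truth[id]), info = id)
  }
})

test_that("5'-end profiles place single reads and conserve mass", {
  b <- fix_bundle()
  glc <- b$clusters[b$clusters$role == "germline_normalizer", ]
  read_start <- glc$start + 100L
  read <- substr(b$genome, read_start, read_start + 24L)
  ann <- manual_annotated(read, genome_unique = TRUE,
                          hit_start = read_start, hit_strand = "+")
  trk <- profile_feature(ann, b, "cluster_42AB_like", scale_factor = 3)
  expect_equal(trk$policy, "genome_unique_only")
  expect_equal(trk$sense[101], 3)
  expect_equal(sum(trk$sense) + sum(trk$antisense), 3)

  # conservation on a simulated library: mass = scale x contributing reads
  ann2 <- fix_annotated()
  trk2 <- profile_feature(ann2, b, "tj_like", scale_factor = 1)
  gu <- ann2[ann2$genome_unique & ann2$category == "piRNA", ]
  utr <- b$utr_sources[b$utr_sources$id == "tj_like", ]
  n_in <- sum(gu$hit_start >= utr$start &
                gu$hit_start + gu$length - 1 <= utr$end)
  expect_equal(sum(trk2$sense) + sum(trk2$antisense), n_in)

  expect_error(profile_feature(ann2, b, "no_such_feature"), "unknown")
})

test_that("minus-strand 3'UTR profiles are reported on the gene strand", {
  b <- fix_bundle()
  utr <- b$utr_sources[b$utr_sources$strand == "-", ][1, ]
  # a read on the gene (minus) strand whose 5' end is at genome position
  # utr$end - 10 -> feature coordinate 11
  g_end <- utr$end - 10L
  g_start <- g_end - 23L
  read <- revcomp(substr(b$genome, g_start, g_end))
  ann <- manual_annotated(read, genome_unique = TRUE,
                          hit_start = g_start, hit_strand = "-")
  trk <- profile_feature(ann, b, utr$id)
  expect_equal(trk$sense[11], 1)
  expect_equal(sum(trk$antisense), 0)
})

test_that("somatic TE profiles are overwhelmingly antisense", {
  b <- fix_bundle()
  ann <- fix_annotated()
  trk <- profile_feature(ann, b, "ZAM_like")
  expect_gt(sum(trk$antisense), 5 * sum(trk$sense))
})

test_that("profile export negates antisense values in the TSV", {
  b <- fix_bundle()
  ann <- fix_annotated()
  trk <- profile_feature(ann, b, "ZAM_like")
  path <- tempfile(fileext = ".tsv")
  export_profile(trk, path)
  tbl <- read.delim(path)
  expect_equal(nrow(tbl), trk$length)
  expect_true(all(tbl$antisense <= 0))
  expect_equal(-tbl$antisense, trk$antisense, tolerance = 1e-9)
})

test_that("library comparison reproduces closed-form Pearson r", {
  mk <- function(x, id) {
    df <- data.frame(feature_id = letters[seq_along(x)], class = "te",
                     sense = x, antisense = 0)
    somapiR:::new_count_table(df, id, 1)
  }
  a <- mk(c(1, 2, 3), "A")
  expect_equal(compare_libraries(a, a)$pearson_r, 1.0)
  expect_equal(compare_libraries(a, mk(c(3, 2, 1), "B"))$pearson_r, -1.0)

  x <- c(1, 2, 4); y <- c(2, 3, 9)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compare_libraries(mk(x, "A"), mk(y, "B"))$pearson_r, r_oracle)

  flat <- compare_libraries(mk(c(2, 2, 2), "A"), mk(x, "B"))
  expect_true(flat$flagged)
  expect_true(is.na(flat$pearson_r))
  expect_error(compare_libraries(a, mk(c(1, 2), "B")), "panels differ")
})

test_that("fold changes recover exact ratios and respect the pseudocount", {
  mk <- function(x, id) {
    df <- data.frame(feature_id = letters[seq_along(x)], class = "te",
                     sense = x, antisense = 0)
    somapiR:::new_count_table(df, id, 1)
  }
  a <- mk(c(10, 20, 40), "A")
  expect_equal(fold_changes(a, a)$ratio, rep(1, 3))
  fc <- fold_changes(mk(c(10, 20, 40) / 4, "B"), a, pseudocount = 0)
  expect_equal(fc$ratio, rep(0.25, 3))
})

test_that("doubling sequencing depth leaves normalized quantities unchanged", {
  b <- fix_bundle()
  lib <- fix_library()
  dup <- lib
  dup$reads <- rbind(lib$reads,
                     transform(lib$reads, read_id = paste0(read_id, "_d")))
  dup$truth <- NULL
  ann1 <- fix_annotated()
  ann2 <- classify_reads(dup, b)
  sf1 <- normalization_factor(annotation_breakdown(ann1, b))
  sf2 <- normalization_factor(annotation_breakdown(ann2, b))
  expect_equal(sf2, sf1 / 2)
  t1 <- te_counts(ann1, b, scale_factor = sf1)
  t2 <- te_counts(ann2, b, scale_factor = sf2)
  expect_equal(t2$norm_total, t1$norm_total, tolerance = 1e-12)
  expect_equal(compare_libraries(t1, t2)$pearson_r, 1.0)
  f1 <- feature_counts(ann1, b, scale_factor = sf1)
  f2 <- feature_counts(ann2, b, scale_factor = sf2)
  expect_equal(fold_changes(f2, f1, pseudocount = 0)$ratio, rep(1, nrow(f1)))
})

test_that("RNA-IP enrichment scales both fractions to 1e6 genome-unique reads", {
  b <- fix_bundle()
  # input: uniform across sources; IP: flamenco-bound fraction up-weighted
  w_in <- stats::setNames(c(0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1),
                          somapiR:::SOURCE_CLASSES)
  w_ip <- w_in; w_ip["somatic_cluster_piRNA"] <- w_ip["somatic_cluster_piRNA"] * 8
  sc_in <- scenario_config("input", w_in, seed = 41)
  sc_ip <- scenario_config("ip", w_ip, seed = 42)
  ann_in <- classify_reads(simulate_library(b, sc_in, 15000), b)
  ann_ip <- classify_reads(simulate_library(b, sc_ip, 15000), b)

  same <- rip_enrichment(ann_in, ann_in, b)
  expect_equal(same$enrichment, rep(1, nrow(same)), tolerance = 1e-12)

  enr <- rip_enrichment(ann_ip, ann_in, b)
  fl <- enr$enrichment[enr$feature_id == "cluster_flamenco_like"]
  expect_true(all(fl > enr$enrichment[enr$feature_id != "cluster_flamenco_like"]))

  none <- manual_annotated(strrep("T", 25), category = "nonmapper")
  expect_error(rip_enrichment(none, ann_in, b), "zero genome-unique")
})
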