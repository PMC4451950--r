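# helper: wrap raw sequences as a library
as_lib <- function(seqs, id = "t") {
  structure(list(library_id = id,
                 reads = data.frame(read_id = sprintf("%s%03d", id,
                                                      seq_along(seqs)),
                                    sequence = seqs,
                                    stringsAsFactors = FALSE),
                 truth = NULL),
            class = "small_rna_library")
}

test_that("cascade assigns categories by the fixed order across all lengths", {
  b <- fix_bundle()
  glc <- b$clusters[b$clusters$role == "germline_normalizer", ]
  # genome-copied reads of every length 18-29 from the (genome-unique) cluster
  lens <- 18:29
  seqs <- substring(b$genome, glc$start + seq_along(lens) * 40,
                    glc$start + seq_along(lens) * 40 + lens - 1)
  ann <- classify_reads(as_lib(seqs), b)
  expected <- ifelse(lens == 21, "siRNA",
                     ifelse(lens >= 23, "piRNA", "unclassified"))
  expect_equal(ann$category, expected)
  expect_true(all(ann$genome_unique))

  # a 25-nt read absent from the genome is a nonmapper
  ann2 <- classify_reads(as_lib(paste0(strrep("AC", 12), "A")), b)
  expect_equal(ann2$category, "nonmapper")
  expect_equal(ann2$genome_hits, 0L)

  # ncRNA subtraction precedes everything: a 25-nt rRNA fragment
  frag <- substr(b$ncrna[["rRNA_like"]], 11, 35)
  expect_equal(classify_reads(as_lib(frag), b)$category, "abundant_ncRNA")
})

test_that("miRNA identity precedes the genome and size rules", {
  b <- fix_bundle()
  glc <- b$clusters[b$clusters$role == "germline_normalizer", ]
  # plant a miRNA whose sequence is also a perfect genome match
  b2 <- b
  planted <- substr(b$genome, glc$start + 5, glc$start + 25)  # 21 nt
  b2$mirna[["mir_planted"]] <- planted
  ann <- classify_reads(as_lib(planted), b2)
  expect_equal(ann$category, "miRNA")  # not siRNA despite length 21
})

test_that("categories partition every library and classification is idempotent", {
  ann <- fix_annotated()
  expect_false(anyNA(ann$category))
  bd <- annotation_breakdown(ann, fix_bundle())
  expect_equal(sum(bd$categories), bd$total)
  expect_equal(bd$total, nrow(fix_library()$reads))
  ann2 <- classify_reads(fix_library(), fix_bundle())
  expect_identical(ann$category, ann2$category)
  expect_true(all(bd$cluster_unique <= bd$categories[["piRNA"]]))
})

test_that("zero-substitution simulations reproduce truth-label counts exactly", {
  lib <- fix_clean_library()
  ann <- fix_clean_annotated()
  truth_n <- table(lib$truth$class)
  cats <- table(ann$category)
  expect_equal(as.integer(cats["abundant_ncRNA"]),
               as.integer(truth_n["ncRNA_fragment"]))
  expect_equal(as.integer(cats["miRNA"]), as.integer(truth_n["miRNA"]))
  pirna_classes <- grep("piRNA$", names(truth_n), value = TRUE)
  expect_equal(as.integer(cats["piRNA"]), as.integer(sum(truth_n[pirna_classes])))
  expect_false("nonmapper" %in% names(cats))
  expect_false("siRNA" %in% names(cats))
})

test_that("normalizer-only libraries put every piRNA in the normalizer cluster", {
  b <- fix_bundle()
  w <- stats::setNames(c(1, 0, 0, 0, 0, 0, 0), somapiR:::SOURCE_CLASSES)
  sc <- scenario_config("pure42AB", w, seed = 3)
  lib <- simulate_library(b, sc, 2000)
  ann <- classify_reads(lib, b)
  bd <- annotation_breakdown(ann, b)
  expect_equal(unname(bd$cluster_unique["cluster_42AB_like"]),
               unname(bd$categories[["piRNA"]]))
  expect_equal(bd$categories[["piRNA"]], 2000L)
})

test_that("size histograms recount the generator's lengths exactly", {
  lib <- fix_library()
  ann <- fix_annotated()
  h <- size_histogram(ann)
  expect_equal(sum(h), nrow(lib$reads))
  truth_h <- table(factor(nchar(lib$reads$sequence), levels = 18:29))
  expect_equal(unname(h), as.integer(truth_h))
  # filtered histogram sums to the number of selected reads
  hp <- size_histogram(ann, "piRNA")
  expect_equal(sum(hp), sum(ann$category == "piRNA"))
  expect_true(all(hp[as.character(18:22)] == 0))
  # degenerate cases
  empty <- ann[0, ]
  class(empty) <- class(ann)
  expect_equal(sum(size_histogram(empty)), 0)
  one <- manual_annotated(strrep("A", 25))
  expect_equal(unname(size_histogram(one)["25"]), 1L)
})

test_that("base composition rows sum to one and recover the configured 1U bias", {
  poly_t <- manual_annotated(rep(strrep("T", 24), 5), category = "nonmapper")
  bc <- base_composition(poly_t, k = 10)
  expect_equal(unname(bc[, "T"]), rep(1, 10))
  expect_equal(unname(rowSums(bc)), rep(1, 10))

  ann <- fix_annotated()
  bc2 <- base_composition(ann, categories = "piRNA", k = 15)
  expect_equal(unname(rowSums(bc2)), rep(1, 15), tolerance = 1e-12)
  n <- sum(ann$category == "piRNA")
  u1 <- 0.75  # scenario default
  expect_lt(abs(bc2[1, "T"] - u1), 3 * sqrt(u1 * (1 - u1) / n))

  expect_error(base_composition(ann[0, ]), "empty")
  expect_error(base_composition(ann, k = 50), "shortest")
})

test_that("classification demands a genome", {
  b <- fix_bundle()
  b$genome <- ""
  expect_error(classify_reads(fix_library(), b), "empty genome")
})
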