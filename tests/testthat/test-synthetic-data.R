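test_that("reference building is deterministic for a fixed seed", {
  b1 <- build_reference(tiny_params(), seed = 42)
  b2 <- build_reference(tiny_params(), seed = 42)
  expect_identical(b1, b2)
  b3 <- build_reference(tiny_params(), seed = 43)
  expect_false(identical(b1$genome, b3$genome))
})

test_that("somatic cluster carries every soma-dominant consensus antisense", {
  b <- fix_bundle()
  smc <- b$clusters[b$clusters$role == "somatic", ]
  smc_seq <- substr(b$genome, smc$start, smc$end)
  soma <- b$te_panel$id[b$te_panel$class == "soma_dominant"]
  expect_gt(length(soma), 0)
  for (id in soma) {
    expect_true(grepl(revcomp(b$te_seqs[[id]]), smc_seq, fixed = TRUE),
                info = id)
    # and never in sense orientation
    expect_false(grepl(b$te_seqs[[id]], b$genome, fixed = TRUE))
  }
})

test_that("infeasible packing is rejected with an explicit error", {
  p <- tiny_params()
  p$genome_length <- 1000L
  expect_error(build_reference(p, seed = 1), "infeasible packing")
})

test_that("bundle intervals are in bounds, non-overlapping, ids unique, cluster 23-mers genome-unique", {
  b <- fix_bundle()
  expect_silent(validate_bundle(b))
  iv <- rbind(b$clusters[, c("start", "end")], b$utr_sources[, c("start", "end")])
  expect_true(all(iv$start >= 1 & iv$end <= nchar(b$genome)))
  iv <- iv[order(iv$start), ]
  expect_true(all(iv$start[-1] > iv$end[-nrow(iv)]))
  expect_true(cluster_kmers_unique(b, k = 23))
})

test_that("simulating zero reads yields an empty library", {
  lib <- simulate_library(fix_bundle(), scenario_control(seed = 1), 0)
  expect_s3_class(lib, "small_rna_library")
  expect_equal(nrow(lib$reads), 0)
  expect_equal(nrow(lib$truth), 0)
})

test_that("library simulation is deterministic and read ids are unique", {
  b <- fix_bundle()
  sc <- scenario_control(seed = 9)
  l1 <- simulate_library(b, sc, 5000)
  l2 <- simulate_library(b, sc, 5000)
  expect_identical(l1, l2)
  expect_false(anyDuplicated(l1$reads$read_id) > 0)
  expect_true(all(nchar(l1$reads$sequence) >= 18 &
                    nchar(l1$reads$sequence) <= 29))
  pir <- grepl("piRNA$", l1$truth$class)
  expect_true(all(nchar(l1$reads$sequence[pir]) >= 23 &
                    nchar(l1$reads$sequence[pir]) <= 29))
})

test_that("empirical class fractions follow weight x depletion within 3 binomial SD", {
  b <- fix_bundle()
  sc <- scenario_control(seed = 77)
  n <- 100000
  lib <- simulate_library(b, sc, n)
  p <- sc$source_weights * sc$depletion
  p <- p / sum(p)
  obs <- table(factor(lib$truth$class, levels = names(p)))
  for (cl in names(p)) {
    sd3 <- 3 * sqrt(n * p[[cl]] * (1 - p[[cl]]))
    expect_lt(abs(obs[[cl]] - n * p[[cl]]), sd3 + 1)
  }
})

test_that("1U bias sets the 5'-T fraction of piRNA-class reads", {
  b <- fix_bundle()
  sc <- scenario_control(seed = 21)
  sc$u1_bias <- 0.8
  lib <- simulate_library(b, sc, 40000)
  pir <- grepl("piRNA$", lib$truth$class) & lib$truth$mismatches == 0
  first <- substring(lib$reads$sequence[pir], 1, 1)
  n <- sum(pir)
  frac <- mean(first == "T")
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("every truth label aligns back to its recorded origin", {
  b <- fix_bundle()
  lib <- fix_library()
  idx <- seq(1, nrow(lib$truth), by = 7)  # systematic subsample
  tr <- lib$truth[idx, ]
  seqs <- lib$reads$sequence[idx]
  for (i in seq_along(idx)) {
    src <- if (tr$ref[i] == "genome") b$genome
      else if (tr$ref[i] %in% names(b$te_seqs)) b$te_seqs[[tr$ref[i]]]
      else if (tr$ref[i] %in% names(b$mirna)) b$mirna[[tr$ref[i]]]
      else b$ncrna[[tr$ref[i]]]
    l <- nchar(seqs[i])
    seg <- substr(src, tr$start[i], tr$start[i] + l - 1L)
    aligned <- if (tr$strand[i] == "+") seqs[i] else revcomp(seqs[i])
    mm <- sum(strsplit(aligned, "")[[1]] != strsplit(seg, "")[[1]])
    expect_equal(mm, tr$mismatches[i])
    expect_lte(mm, if (grepl("TE_piRNA", tr$class[i])) 4 else 0)
  }
})

test_that("class counts scale linearly with the depletion factor", {
  b <- fix_bundle()
  D <- 3
  sc1 <- scenario_control(seed = 31)
  sc2 <- scenario_control(seed = 31)
  sc2$depletion["soma_TE_piRNA"] <- 1 / D
  n <- 80000
  l1 <- simulate_library(b, sc1, n, seed = 31)
  l2 <- simulate_library(b, sc2, n, seed = 32)
  c1 <- sum(l1$truth$class == "soma_TE_piRNA")
  c2 <- sum(l2$truth$class == "soma_TE_piRNA")
  # normalize away the multinomial renormalization of the other classes
  g1 <- sum(l1$truth$class == "germline_cluster_piRNA")
  g2 <- sum(l2$truth$class == "germline_cluster_piRNA")
  ratio <- (c1 / g1) / (c2 / g2)
  expect_lt(abs(ratio - D) / D, 0.15)
})

test_that("scenario validation rejects out-of-domain parameters", {
  w <- stats::setNames(rep(1, 7), somapiR:::SOURCE_CLASSES)
  expect_error(scenario_config("x", w * 0), "positive sum")
  expect_error(scenario_config("x", w, depletion = stats::setNames(rep(0, 7),
    somapiR:::SOURCE_CLASSES)), "depletion")
  expect_error(scenario_config("x", w, u1_bias = 1.5), "u1_bias")
  lm <- default_length_model()
  names(lm$utr_piRNA) <- c(20, 24:29)
  expect_error(scenario_config("x", w, length_model = lm), "23")
})
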