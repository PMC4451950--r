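test_that("perfect mapping finds planted reads with correct orientation", {
  b <- fix_bundle()
  read <- substr(b$genome, 1001, 1025)  # 25 nt copied from position 1001
  h <- map_perfect(read, b$genome)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1001)
  expect_equal(h$strand, "+")
  expect_equal(h$five_prime, 1001)

  hr <- map_perfect(revcomp(read), b$genome)
  expect_equal(nrow(hr), 1)
  expect_equal(hr$strand, "-")
  expect_equal(hr$start, 1001)
  expect_equal(hr$five_prime, 1001 + 25 - 1)

  absent <- strrep("ACGT", 7)  # periodic 28-mer, absent from random sequence
  expect_equal(nrow(map_perfect(absent, b$genome)), 0)

  expect_error(map_perfect("ACGTACGTACGT", b$genome), "shorter")
})

test_that("germline TE copies are multi-mappers, cluster sequence genome-unique", {
  b <- fix_bundle()
  te <- b$te_panel$id[b$te_panel$class == "germline_dominant"][1]
  read <- substr(b$te_seqs[[te]], 101, 126)
  h <- map_perfect(read, b$genome)
  expect_equal(nrow(h), b$params$germline_te_copies)
  glc <- b$clusters[b$clusters$role == "germline_normalizer", ]
  cread <- substr(b$genome, glc$start + 200, glc$start + 225)
  expect_equal(nrow(map_perfect(cread, b$genome)), 1)
})

test_that("consensus mapping honors the mismatch budget", {
  b <- fix_bundle()
  cons <- b$te_seqs[["ZAM_like"]]
  read <- substr(cons, 51, 76)
  h <- map_consensus(read, b$te_seqs["ZAM_like"])
  expect_true(any(h$start == 51 & h$mismatches == 0 & h$strand == "+"))

  # five substitutions exceed the budget of four at the origin
  mut <- strsplit(read, "")[[1]]
  pos <- c(3, 8, 13, 18, 23)
  mut[pos] <- vapply(mut[pos], function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                     character(1))
  h5 <- map_consensus(paste(mut, collapse = ""), b$te_seqs["ZAM_like"])
  expect_false(any(h5$start == 51 & h5$strand == "+"))
  h5b <- map_consensus(paste(mut, collapse = ""), b$te_seqs["ZAM_like"],
                       max_mismatches = 5)
  expect_true(any(h5b$start == 51 & h5b$strand == "+" & h5b$mismatches == 5))
})

test_that("500 seeded reads match the brute-force scan exactly on both mappers", {
  set.seed(1234)
  b <- fix_bundle()
  panel <- b$te_seqs[c("ZAM_like", "Felement_like")]  # <= 10 kb total
  # mixture: random reads, exact consensus reads, mutated consensus reads
  mk_random <- function(n) vapply(sample(18:29, n, TRUE), function(l)
    paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""), character(1))
  mk_from <- function(n, mm) {
    vapply(seq_len(n), function(i) {
      ref <- panel[[sample(2, 1)]]
      l <- sample(23:29, 1)
      s <- sample(nchar(ref) - l + 1, 1)
      x <- strsplit(substr(ref, s, s + l - 1), "")[[1]]
      if (mm > 0) {
        pos <- sample(l, mm)
        x[pos] <- vapply(x[pos], function(ch)
          sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
      }
      if (stats::runif(1) < 0.5) paste(x, collapse = "")
      else paste(rev(chartr("ACGT", "TGCA", x)), collapse = "")
    }, character(1))
  }
  reads <- c(mk_random(300), mk_from(100, 0), mk_from(50, 2), mk_from(50, 4))

  got <- sort_hits(map_consensus(reads, panel, 4))
  want <- sort_hits(oracle_scan(reads, panel, 4))
  expect_equal(got, want)

  # perfect genome mapping against the same oracle at zero mismatches
  sub <- reads[1:150]
  gotp <- sort_hits(map_perfect(sub, b$genome))
  wantp <- sort_hits(oracle_scan(sub, c(genome = b$genome), 0))
  expect_equal(gotp, wantp)
})

test_that("strand symmetry: mapping the reverse complement swaps strands", {
  set.seed(99)
  b <- fix_bundle()
  panel <- b$te_seqs["Tabor_like"]
  reads <- vapply(seq_len(30), function(i) {
    l <- sample(23:29, 1)
    s <- sample(nchar(panel[[1]]) - l + 1, 1)
    x <- strsplit(substr(panel[[1]], s, s + l - 1), "")[[1]]
    pos <- sample(l, 2)
    x[pos] <- vapply(x[pos], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    paste(x, collapse = "")
  }, character(1))
  h1 <- map_consensus(reads, panel, 4)
  h2 <- map_consensus(revcomp(reads), panel, 4)
  flip <- function(h) {
    h$strand <- ifelse(h$strand == "+", "-", "+")
    h$five_prime <- ifelse(h$strand == "+", h$start,
                           h$start + nchar(reads)[h$query] - 1L)
    sort_hits(h)
  }
  expect_equal(flip(h1), sort_hits(h2))
})

test_that("hit sets grow monotonically with the mismatch budget", {
  set.seed(7)
  b <- fix_bundle()
  panel <- b$te_seqs[c("ZAM_like", "Burdock_like")]
  reads <- vapply(seq_len(40), function(i)
    paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = ""),
    character(1))
  # seed a few true near-matches so lower budgets are non-trivial
  reads <- c(reads, substr(panel[[1]], 11, 36), substr(panel[[2]], 21, 44))
  prev <- -1
  for (k in 0:4) {
    n <- nrow(map_consensus(reads, panel, k))
    expect_gte(n, prev)
    prev <- n
  }
})
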