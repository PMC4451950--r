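#' Simulate a small-RNA library under a scenario
#'
#' Draws `n_reads` reads with class probability proportional to
#' `source_weights x depletion`. Cluster- and 3'UTR-derived reads are exact
#' subsequences of their interval on the feature strand; TE-derived reads
#' are drawn from the consensus (mostly antisense) and, with probability
#' `mismatch_rate`, carry 1-4 substitutions uniform over positions and
#' alternative bases; miRNA reads are exact copies of mature miRNAs; ncRNA
#' fragments are sense subsequences of the ncRNA set. The 1U bias is applied
#' to piRNA classes by sampling the 5'-end origin from T-start (respectively
#' non-T-start) positions, so the expected 5'-T fraction equals `u1_bias`
#' exactly. Truth labels (class, origin, strand, substitution count) are
#' retained in a sidecar table the pipeline never reads.
#'
#' @param bundle a `reference_bundle`.
#' @param scenario a `scenario_config`.
#' @param n_reads number of reads to draw (>= 0).
#' @param seed integer seed; defaults to the scenario's seed.
#' @param library_id library label; defaults to the scenario name.
#' @return an object of class `small_rna_library` with elements `library_id`,
#'   `reads` (read_id, sequence) and `truth` (read_id, class, feature, ref,
#'   start, strand, mismatches).
#' @export
simulate_library <- function(bundle, scenario, n_reads,
                             seed = scenario$seed,
                             library_id = scenario$name) {
  stopifnot(inherits(bundle, "reference_bundle"))
  validate_scenario(scenario)
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 0) stop("n_reads must be >= 0")

  empty <- data.frame(sequence = character(0), class = character(0),
                      feature = character(0), ref = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (n_reads == 0L) {
    return(structure(list(library_id = library_id,
                          reads = data.frame(read_id = character(0),
                                             sequence = character(0),
                                             stringsAsFactors = FALSE),
                          truth = cbind(data.frame(read_id = character(0),
                                                   stringsAsFactors = FALSE),
                                        empty[, -1])),
                     class = "small_rna_library"))
  }

  set.seed(as.integer(seed))
  prob <- scenario$source_weights * scenario$depletion
  counts <- as.vector(stats::rmultinom(1, n_reads, prob))
  names(counts) <- SOURCE_CLASSES

  parts <- list(
    sim_interval_class(bundle, scenario, "germline_cluster_piRNA",
                       counts[["germline_cluster_piRNA"]]),
    sim_interval_class(bundle, scenario, "somatic_cluster_piRNA",
                       counts[["somatic_cluster_piRNA"]]),
    sim_te_class(bundle, scenario, "soma_TE_piRNA",
                 counts[["soma_TE_piRNA"]]),
    sim_te_class(bundle, scenario, "germline_TE_piRNA",
                 counts[["germline_TE_piRNA"]]),
    sim_interval_class(bundle, scenario, "utr_piRNA",
                       counts[["utr_piRNA"]]),
    sim_mirna(bundle, counts[["miRNA"]]),
    sim_ncrna(bundle, scenario, counts[["ncRNA_fragment"]])
  )
  all <- do.call(rbind, parts)
  all <- all[sample.int(nrow(all)), , drop = FALSE]
  rownames(all) <- NULL
  read_id <- sprintf("%s_r%07d", library_id, seq_len(nrow(all)))

  structure(list(
    library_id = library_id,
    reads = data.frame(read_id = read_id, sequence = all$sequence,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, all[, -1, drop = FALSE],
                       stringsAsFactors = FALSE)
  ), class = "small_rna_library")
}

# sample read lengths from the class length model
sample_lengths <- function(scenario, class, n) {
  lm <- scenario$length_model[[class]]
  as.integer(sample(as.integer(names(lm)), n, replace = TRUE, prob = lm))
}

# sample 5'-end origins on a sequence honoring the 1U bias.
# seq_chars: character vector of the source sequence (forward orientation);
# lo/hi: admissible 5'-end positions; want_t: logical per read.
# plus strand: 5' base = seq[p]; minus strand: 5' base = complement(seq[p]),
# i.e. a T-start requires seq[p] == "A".
sample_p5 <- function(seq_chars, lo, hi, strand, want_t) {
  rng <- lo:hi
  target <- if (strand == "+") "T" else "A"
  is_t <- seq_chars[rng] == target
  p <- integer(length(want_t))
  t_pos <- rng[is_t]; o_pos <- rng[!is_t]
  nt <- sum(want_t)
  if (nt > 0) {
    pool <- if (length(t_pos) > 0) t_pos else rng  # degenerate: no T available
    p[want_t] <- pool[sample.int(length(pool), nt, replace = TRUE)]
  }
  if (nt < length(want_t)) {
    pool <- if (length(o_pos) > 0) o_pos else rng
    p[!want_t] <- pool[sample.int(length(pool), length(want_t) - nt,
                                  replace = TRUE)]
  }
  p
}

# reads from genomic intervals (clusters on the cluster strand, 3'UTRs on
# the gene strand); exact genome subsequences, truth start = leftmost coord
sim_interval_class <- function(bundle, scenario, class, n) {
  out <- new_read_block(0L)
  if (n == 0L) return(out)
  feats <- switch(class,
    germline_cluster_piRNA =
      bundle$clusters[bundle$clusters$role == "germline_normalizer", ],
    somatic_cluster_piRNA =
      bundle$clusters[bundle$clusters$role == "somatic", ],
    utr_piRNA = bundle$utr_sources)
  gch <- get_genome_chars(bundle)
  widths <- feats$end - feats$start + 1L
  fidx <- sample.int(nrow(feats), n, replace = TRUE, prob = widths)
  lens <- sample_lengths(scenario, class, n)
  bias <- stats::runif(n) < scenario$u1_bias

  res <- vector("list", 0)
  for (fi in unique(fidx)) {
    st <- feats$strand[fi]
    for (l in unique(lens[fidx == fi])) {
      sel <- which(fidx == fi & lens == l)
      if (st == "+") {
        p5 <- sample_p5(gch, feats$start[fi], feats$end[fi] - l + 1L,
                        "+", bias[sel])
        starts <- p5
      } else {
        p5 <- sample_p5(gch, feats$start[fi] + l - 1L, feats$end[fi],
                        "-", bias[sel])
        starts <- p5 - l + 1L
      }
      seqs <- substring(bundle$genome, starts, starts + l - 1L)
      if (st == "-") seqs <- revcomp(seqs)
      res[[length(res) + 1L]] <- data.frame(
        sequence = seqs, class = class, feature = feats$id[fi],
        ref = "genome", start = starts, strand = st, mismatches = 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# TE-derived reads: drawn from the consensus, antisense with class-specific
# probability, substitutions applied per mismatch_rate (1-4, <= budget 4)
sim_te_class <- function(bundle, scenario, class, n) {
  if (n == 0L) return(new_read_block(0L))
  te_class <- if (class == "soma_TE_piRNA") "soma_dominant" else "germline_dominant"
  panel <- bundle$te_panel[bundle$te_panel$class == te_class, ]
  fidx <- sample.int(nrow(panel), n, replace = TRUE, prob = panel$length)
  lens <- sample_lengths(scenario, class, n)
  bias <- stats::runif(n) < scenario$u1_bias
  anti <- stats::runif(n) < scenario$te_antisense_frac[[class]]

  res <- vector("list", 0)
  for (fi in unique(fidx)) {
    cons <- bundle$te_seqs[[panel$id[fi]]]
    cch <- strsplit(cons, "", fixed = TRUE)[[1]]
    m <- nchar(cons)
    for (l in unique(lens[fidx == fi])) {
      for (a in c(FALSE, TRUE)) {
        sel <- which(fidx == fi & lens == l & anti == a)
        if (length(sel) == 0) next
        if (!a) {
          p5 <- sample_p5(cch, 1L, m - l + 1L, "+", bias[sel])
          starts <- p5
        } else {
          p5 <- sample_p5(cch, l, m, "-", bias[sel])
          starts <- p5 - l + 1L
        }
        seqs <- substring(cons, starts, starts + l - 1L)
        if (a) seqs <- revcomp(seqs)
        res[[length(res) + 1L]] <- data.frame(
          sequence = seqs, class = class, feature = panel$id[fi],
          ref = panel$id[fi], start = starts,
          strand = if (a) "-" else "+", mismatches = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  apply_substitutions(out, scenario$mismatch_rate)
}

# with probability `rate`, substitute 1-4 distinct positions of a read
apply_substitutions <- function(block, rate) {
  if (rate <= 0 || nrow(block) == 0) return(block)
  hit <- which(stats::runif(nrow(block)) < rate)
  for (i in hit) {
    s <- strsplit(block$sequence[i], "", fixed = TRUE)[[1]]
    k <- sample.int(4L, 1L)
    pos <- sample.int(length(s), min(k, length(s)))
    for (p in pos) s[p] <- sample(setdiff(BASES, s[p]), 1L)
    block$sequence[i] <- paste(s, collapse = "")
    block$mismatches[i] <- length(pos)
  }
  block
}

sim_mirna <- function(bundle, n) {
  if (n == 0L) return(new_read_block(0L))
  ids <- sample(names(bundle$mirna), n, replace = TRUE)
  data.frame(sequence = unname(bundle$mirna[ids]), class = "miRNA",
             feature = ids, ref = ids, start = 1L, strand = "+",
             mismatches = 0L, stringsAsFactors = FALSE)
}

sim_ncrna <- function(bundle, scenario, n) {
  if (n == 0L) return(new_read_block(0L))
  nc_len <- nchar(bundle$ncrna)
  ids <- sample(names(bundle$ncrna), n, replace = TRUE, prob = nc_len)
  lens <- sample_lengths(scenario, "ncRNA_fragment", n)
  lens <- pmin(lens, nc_len[ids])
  starts <- 1L + floor(stats::runif(n) * (nc_len[ids] - lens + 1L))
  data.frame(sequence = substring(bundle$ncrna[ids], starts, starts + lens - 1L),
             class = "ncRNA_fragment", feature = ids, ref = ids,
             start = as.integer(starts), strand = "+", mismatches = 0L,
             stringsAsFactors = FALSE)
}

new_read_block <- function(n) {
  data.frame(sequence = character(n), class = character(n),
             feature = character(n), ref = character(n), start = integer(n),
             strand = character(n), mismatches = integer(n),
             stringsAsFactors = FALSE)
}

# cache the split genome on the bundle environment-free way: recompute cheaply
get_genome_chars <- function(bundle) {
  strsplit(bundle$genome, "", fixed = TRUE)[[1]]
}

#' @export
print.small_rna_library <- function(x, ...) {
  cat("small_rna_library", x$library_id, "with", nrow(x$reads), "reads\n")
  invisible(x)
}
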