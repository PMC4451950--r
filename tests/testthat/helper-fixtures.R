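# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, fn(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small reference: everything downstream of the generator runs in seconds
tiny_params <- function() {
  list(
    genome_length = 20000L,
    germline_cluster_length = 1500L,
    somatic_cluster_spacer = 100L,
    utr_lengths = c(tj_like = 400L, jim_like = 350L, CG32000_like = 300L),
    utr_strands = c("+", "-", "+"),
    soma_te_lengths = c(ZAM_like = 600L, Tabor_like = 500L),
    germline_te_lengths = c(Felement_like = 500L),
    germline_te_copies = 2L,
    ncrna_lengths = c(rRNA_like = 800L, tRNA_like = 90L),
    n_mirna = 5L,
    min_gap = 30L
  )
}

fix_bundle <- function() memo("bundle", function() {
  build_reference(tiny_params(), seed = 42)
})

fix_library <- function() memo("library", function() {
  simulate_library(fix_bundle(), scenario_control(seed = 5), 20000)
})

fix_annotated <- function() memo("annotated", function() {
  classify_reads(fix_library(), fix_bundle())
})

# zero-substitution simulation: truth labels map 1:1 onto categories
fix_clean_library <- function() memo("clean_library", function() {
  sc <- scenario_control(seed = 6)
  sc$mismatch_rate <- 0
  simulate_library(fix_bundle(), sc, 20000)
})

fix_clean_annotated <- function() memo("clean_annotated", function() {
  classify_reads(fix_clean_library(), fix_bundle())
})

# annotated_reads built by hand, for operations that only need rows
manual_annotated <- function(sequence, category = "piRNA",
                             genome_unique = FALSE, hit_start = NA_integer_,
                             hit_strand = NA_character_, library_id = "manual") {
  out <- data.frame(
    read_id = sprintf("m%03d", seq_along(sequence)),
    sequence = sequence,
    length = nchar(sequence),
    category = category,
    genome_hits = ifelse(category %in% c("abundant_ncRNA", "miRNA"),
                         NA_integer_,
                         ifelse(category == "nonmapper", 0L,
                                ifelse(genome_unique, 1L, 2L))),
    genome_unique = genome_unique,
    hit_start = hit_start,
    hit_strand = hit_strand,
    stringsAsFactors = FALSE
  )
  class(out) <- c("annotated_reads", "data.frame")
  attr(out, "library_id") <- library_id
  out
}

manual_breakdown <- function(normalizer_count,
                             normalizer = "cluster_42AB_like") {
  structure(list(
    library_id = "manual", total = normalizer_count,
    categories = stats::setNames(
      c(0L, 0L, 0L, normalizer_count, 0L, 0L),
      c("abundant_ncRNA", "miRNA", "siRNA", "piRNA", "unclassified",
        "nonmapper")),
    cluster_unique = stats::setNames(c(normalizer_count, 0L),
                                     c(normalizer, "cluster_flamenco_like")),
    utr_unique = integer(0)
  ), class = "annotation_breakdown")
}
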