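READ_CATEGORIES <- c("abundant_ncRNA", "miRNA", "siRNA", "piRNA",
                     "unclassified", "nonmapper")

#' Annotation cascade for a small-RNA library
#'
#' Applies the fixed classification order: (1) exact substring of an
#' abundant ncRNA (rRNA/tRNA/snRNA stand-ins, stored strand only) ->
#' `abundant_ncRNA`; (2) exact full-length identity with a mature miRNA ->
#' `miRNA`; (3) no perfect genome hit -> `nonmapper`; (4) length 21 ->
#' `siRNA`; (5) length 23-29 -> `piRNA`; (6) otherwise `unclassified`.
#' Every read receives exactly one category. Genome hit counts and the sole
#' hit's coordinates (for genome-unique reads) are recorded for the reads
#' that pass the ncRNA/miRNA subtraction.
#'
#' @param library a `small_rna_library`.
#' @param bundle a `reference_bundle` providing genome, ncRNA and miRNA sets
#'   (empty ncRNA/miRNA sets simply skip those stages).
#' @param pirna_range inclusive piRNA length bounds.
#' @param sirna_len siRNA length.
#' @return a data.frame of class `annotated_reads` with one row per read:
#'   read_id, sequence, length, category, genome_hits, genome_unique,
#'   hit_start, hit_strand.
#' @export
classify_reads <- function(library, bundle, pirna_range = c(23L, 29L),
                           sirna_len = 21L) {
  stopifnot(inherits(library, "small_rna_library"),
            inherits(bundle, "reference_bundle"))
  if (is.null(bundle$genome) || nchar(bundle$genome) == 0) {
    stop("empty genome")
  }
  reads <- library$reads
  u <- unique(reads$sequence)

  nc_set <- if (length(bundle$ncrna) > 0) {
    all_substrings(unname(bundle$ncrna), 18:29)
  } else character(0)
  is_nc <- u %in% nc_set
  is_mir <- !is_nc & (u %in% bundle$mirna)
  rest <- which(!is_nc & !is_mir)

  cat_u <- rep(NA_character_, length(u))
  cat_u[is_nc] <- "abundant_ncRNA"
  cat_u[is_mir] <- "miRNA"
  n_hits <- rep(NA_integer_, length(u))
  hit_start <- rep(NA_integer_, length(u))
  hit_strand <- rep(NA_character_, length(u))

  if (length(rest) > 0) {
    hs <- perfect_hit_summary(u[rest], bundle$genome)
    n_hits[rest] <- hs$n_hits
    hit_start[rest] <- hs$hit_start
    hit_strand[rest] <- hs$hit_strand
    lens <- nchar(u[rest])
    cat_u[rest] <- ifelse(hs$n_hits == 0L, "nonmapper",
                   ifelse(lens == sirna_len, "siRNA",
                   ifelse(lens >= pirna_range[1] & lens <= pirna_range[2],
                          "piRNA", "unclassified")))
  }

  m <- match(reads$sequence, u)
  out <- data.frame(
    read_id = reads$read_id,
    sequence = reads$sequence,
    length = nchar(reads$sequence),
    category = cat_u[m],
    genome_hits = n_hits[m],
    genome_unique = !is.na(n_hits[m]) & n_hits[m] == 1L,
    hit_start = hit_start[m],
    hit_strand = hit_strand[m],
    stringsAsFactors = FALSE
  )
  class(out) <- c("annotated_reads", "data.frame")
  attr(out, "library_id") <- library$library_id
  attr(out, "pirna_range") <- pirna_range
  out
}

#' Per-library annotation summary
#'
#' Category counts (which partition the library) plus counts of
#' genome-unique piRNAs whose sole alignment falls entirely inside each
#' piRNA cluster or 3'UTR source interval, the per-library layout used for
#' sequencing-count tables.
#'
#' @param annotated an `annotated_reads` data.frame.
#' @param bundle the matching `reference_bundle`.
#' @return an `annotation_breakdown`: list with library_id, total,
#'   categories (named counts), cluster_unique and utr_unique (named counts
#'   of genome-unique piRNAs per interval).
#' @export
annotation_breakdown <- function(annotated, bundle) {
  stopifnot(inherits(annotated, "annotated_reads"))
  categories <- table(factor(annotated$category, levels = READ_CATEGORIES))
  categories <- stats::setNames(as.integer(categories), READ_CATEGORIES)
  total <- nrow(annotated)
  stopifnot(sum(categories) == total)

  gu <- annotated[annotated$genome_unique &
                    annotated$category == "piRNA", , drop = FALSE]
  count_in <- function(iv) {
    vapply(seq_len(nrow(iv)), function(i) {
      sum(gu$hit_start >= iv$start[i] &
            gu$hit_start + gu$length - 1L <= iv$end[i])
    }, integer(1))
  }
  cluster_unique <- stats::setNames(count_in(bundle$clusters),
                                    bundle$clusters$id)
  utr_unique <- stats::setNames(count_in(bundle$utr_sources),
                                bundle$utr_sources$id)
  structure(list(
    library_id = attr(annotated, "library_id"),
    total = total,
    categories = categories,
    cluster_unique = cluster_unique,
    utr_unique = utr_unique
  ), class = "annotation_breakdown")
}

#' @export
print.annotation_breakdown <- function(x, ...) {
  cat("annotation_breakdown for", x$library_id, "-", x$total, "reads\n")
  print(x$categories)
  cat("cluster-unique piRNAs:\n")
  print(x$cluster_unique)
  invisible(x)
}

#' @export
as.data.frame.annotation_breakdown <- function(x, ...) {
  data.frame(library_id = x$library_id, total = x$total,
             t(x$categories), t(x$cluster_unique), t(x$utr_unique),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read-length histogram
#'
#' @param annotated an `annotated_reads` data.frame.
#' @param categories optional subset of categories to keep (default all).
#' @return named integer vector of counts for lengths 18-29.
#' @export
size_histogram <- function(annotated, categories = NULL) {
  sel <- select_categories(annotated, categories)
  h <- table(factor(sel$length, levels = 18:29))
  stats::setNames(as.integer(h), names(h))
}

#' Per-position base-composition matrix
#'
#' Relative proportion of each nucleotide at read positions 1..k over the
#' selected reads (the numeric content of a sequence logo).
#'
#' @param annotated an `annotated_reads` data.frame.
#' @param categories optional subset of categories.
#' @param k number of 5' positions; defaults to (and may not exceed) the
#'   shortest selected read.
#' @return k x 4 matrix with columns A, C, G, T; rows sum to 1.
#' @export
base_composition <- function(annotated, categories = NULL, k = NULL) {
  sel <- select_categories(annotated, categories)
  if (nrow(sel) == 0) stop("empty read selection")
  kmax <- min(sel$length)
  k <- k %||% kmax
  if (k > kmax) stop("k exceeds the shortest selected read (", kmax, ")")
  out <- matrix(0, nrow = k, ncol = 4, dimnames = list(seq_len(k), BASES))
  for (i in seq_len(k)) {
    b <- substring(sel$sequence, i, i)
    out[i, ] <- tabulate(factor(b, levels = BASES), nbins = 4) / nrow(sel)
  }
  out
}

select_categories <- function(annotated, categories) {
  stopifnot(inherits(annotated, "annotated_reads"))
  if (is.null(categories)) return(annotated)
  bad <- setdiff(categories, READ_CATEGORIES)
  if (length(bad) > 0) stop("unknown categories: ", paste(bad, collapse = ", "))
  annotated[annotated$category %in% categories, , drop = FALSE]
}
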