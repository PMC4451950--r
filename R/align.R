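#' Perfect genome mapping with uniqueness calls
#'
#' Returns every exact occurrence of each read, or of its reverse
#' complement, on the genome. "Mappers" in the library summaries are reads
#' with at least one such hit; genome-unique reads have exactly one.
#' Coordinates are 1-based on the forward strand; `five_prime` is the
#' reference coordinate of the read's 5' end (the leftmost aligned base for
#' a "+" hit, the rightmost for a "-" hit).
#'
#' @param reads character vector of read sequences (optionally named).
#' @param genome single genome sequence.
#' @param min_len guard against spurious hits from very short queries.
#' @return data.frame with columns query (index into `reads`), read_id, ref,
#'   start, strand, mismatches (always 0) and five_prime.
#' @export
map_perfect <- function(reads, genome, min_len = 15L) {
  stopifnot(is.character(reads), is.character(genome), length(genome) == 1)
  if (nchar(genome) == 0) stop("empty genome")
  if (length(reads) == 0) return(empty_hits())
  if (any(nchar(reads) < min_len)) {
    stop("reads shorter than ", min_len, " nt are not mapped")
  }
  ids <- names(reads) %||% as.character(seq_along(reads))
  gseq <- Biostrings::DNAString(genome)

  res <- vector("list", 0)
  lens <- nchar(reads)
  for (l in unique(lens)) {
    idx <- which(lens == l)
    u <- unique(reads[idx])
    uset <- Biostrings::DNAStringSet(u)
    for (st in c("+", "-")) {
      pats <- if (st == "+") uset else Biostrings::reverseComplement(uset)
      m <- Biostrings::matchPDict(Biostrings::PDict(pats), gseq)
      sidx <- Biostrings::startIndex(m)
      nh <- lengths(sidx)
      hit_u <- which(nh > 0)
      if (length(hit_u) == 0) next
      for (ui in hit_u) {
        starts <- sidx[[ui]]
        ridx <- idx[reads[idx] == u[ui]]
        res[[length(res) + 1L]] <- data.frame(
          query = rep(ridx, each = length(starts)),
          ref = "genome",
          start = rep(starts, times = length(ridx)),
          strand = st,
          mismatches = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) return(empty_hits())
  out <- do.call(rbind, res)
  out$read_id <- ids[out$query]
  out$five_prime <- ifelse(out$strand == "+", out$start,
                           out$start + nchar(reads)[out$query] - 1L)
  out <- out[order(out$query, out$start, out$strand), ]
  rownames(out) <- NULL
  out[, c("query", "read_id", "ref", "start", "strand", "mismatches",
          "five_prime")]
}

#' Mismatch-tolerant mapping to TE consensus sequences
#'
#' Ungapped all-position scan of each read, in both orientations, against
#' each consensus; every alignment with Hamming distance at most
#' `max_mismatches` (default 4) is reported. A read may hit several families
#' and several positions per family.
#'
#' @param reads character vector of read sequences (optionally named).
#' @param te_seqs named character vector of consensus sequences, or a
#'   `reference_bundle` (its `te_seqs` is used).
#' @param max_mismatches mismatch budget (>= 0).
#' @return data.frame with columns query, read_id, ref (family id), start,
#'   strand, mismatches and five_prime (1-based consensus coordinates).
#' @export
map_consensus <- function(reads, te_seqs, max_mismatches = 4L) {
  if (inherits(te_seqs, "reference_bundle")) te_seqs <- te_seqs$te_seqs
  stopifnot(is.character(reads), is.character(te_seqs))
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (length(reads) == 0 || length(te_seqs) == 0) return(empty_hits())
  ids <- names(reads) %||% as.character(seq_along(reads))

  # scan unique sequences once, then fan results back out to reads
  u <- unique(reads)
  hits <- .scan_hits(u, unname(te_seqs), as.integer(max_mismatches))
  if (nrow(hits) == 0) return(empty_hits())
  uq <- match(reads, u)
  per_read <- split(seq_along(uq), uq)
  keep <- per_read[as.character(hits$query)]
  reps <- lengths(keep)
  out <- hits[rep(seq_len(nrow(hits)), reps), , drop = FALSE]
  out$query <- unlist(keep, use.names = FALSE)
  out$read_id <- ids[out$query]
  out$ref <- names(te_seqs)[out$ref]
  out$five_prime <- ifelse(out$strand == "+", out$start,
                           out$start + nchar(reads)[out$query] - 1L)
  out <- out[order(out$query, match(out$ref, names(te_seqs)), out$start,
                   out$strand), ]
  rownames(out) <- NULL
  out[, c("query", "read_id", "ref", "start", "strand", "mismatches",
          "five_prime")]
}

empty_hits <- function() {
  data.frame(query = integer(0), read_id = character(0), ref = character(0),
             start = integer(0), strand = character(0),
             mismatches = integer(0), five_prime = integer(0),
             stringsAsFactors = FALSE)
}

# per-sequence perfect-hit counts plus sole-hit coordinates, for the
# annotation cascade; operates on unique sequences. Hash-joins each length
# class of reads against the genome's substring set of that length (both
# orientations), which is much faster than pattern matching for the short,
# highly duplicated queries of a small-RNA library.
perfect_hit_summary <- function(seqs, genome) {
  n <- length(seqs)
  out <- data.frame(sequence = seqs, n_hits = 0L,
                    hit_start = NA_integer_, hit_strand = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  glen <- nchar(genome)
  lens <- nchar(seqs)
  for (l in unique(lens)) {
    idx <- which(lens == l)
    if (l > glen) next
    starts <- seq_len(glen - l + 1L)
    gsubs <- substring(genome, starts, starts + l - 1L)
    fwd <- seqs[idx]
    rev <- revcomp(fwd)
    mf <- match(gsubs, fwd)   # fwd occurrence: read matches + strand
    mr <- match(gsubs, rev)   # revcomp occurrence: read matches - strand
    nf <- tabulate(mf[!is.na(mf)], nbins = length(idx))
    nr <- tabulate(mr[!is.na(mr)], nbins = length(idx))
    out$n_hits[idx] <- nf + nr
    one_f <- which(nf == 1L & nr == 0L)
    one_r <- which(nf == 0L & nr == 1L)
    if (length(one_f) > 0) {
      out$hit_start[idx[one_f]] <- match(fwd[one_f], gsubs)
      out$hit_strand[idx[one_f]] <- "+"
    }
    if (length(one_r) > 0) {
      out$hit_start[idx[one_r]] <- match(rev[one_r], gsubs)
      out$hit_strand[idx[one_r]] <- "-"
    }
  }
  out
}
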