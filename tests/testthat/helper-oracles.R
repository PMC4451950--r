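# Independent brute-force alignment oracles: naive position-by-position
# scans, sharing no code with the package implementations.

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Hamming distance of `read` against every window of `ref`; integer vector
# of length nchar(ref) - nchar(read) + 1
oracle_window_mismatches <- function(read, ref) {
  l <- nchar(read); m <- nchar(ref)
  if (m < l) return(integer(0))
  rch <- strsplit(ref, "", fixed = TRUE)[[1]]
  qch <- strsplit(read, "", fixed = TRUE)[[1]]
  starts <- seq_len(m - l + 1L)
  win <- matrix(rch[outer(0:(l - 1L), starts, `+`)], nrow = l)
  as.integer(colSums(win != qch))
}

# all ungapped hits of reads (both orientations) on named references with
# at most max_mm mismatches; same column layout as the package mappers
oracle_scan <- function(reads, refs, max_mm) {
  ids <- names(reads)
  if (is.null(ids)) ids <- as.character(seq_along(reads))
  rows <- list()
  for (i in seq_along(reads)) {
    l <- nchar(reads[i])
    for (j in seq_along(refs)) {
      for (st in c("+", "-")) {
        q <- if (st == "+") reads[[i]] else oracle_revcomp(reads[[i]])
        mm <- oracle_window_mismatches(q, refs[[j]])
        hit <- which(mm <= max_mm)
        if (length(hit) > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            query = i, read_id = ids[i],
            ref = names(refs)[j] %||% as.character(j),
            start = hit, strand = st, mismatches = mm[hit],
            five_prime = if (st == "+") hit else hit + l - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(query = integer(0), read_id = character(0),
                      ref = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0),
                      five_prime = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical ordering and type normalization so hit sets can be compared
sort_hits <- function(h) {
  for (col in c("query", "start", "mismatches", "five_prime")) {
    h[[col]] <- as.integer(h[[col]])
  }
  h <- h[order(h$query, h$ref, h$start, h$strand, h$mismatches), ]
  rownames(h) <- NULL
  h
}
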