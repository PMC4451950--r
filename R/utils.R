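#' @useDynLib somapiR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' T is used as the DNA-alphabet stand-in for U throughout the package.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0) return(character(0))
  unname(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# fast random DNA of length n
random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# deterministic TSV writer: fixed quoting/format so identical inputs give
# byte-identical files (pipeline determinism contract)
write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", format(x, digits = 15, trim = TRUE, scientific = FALSE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# all substrings of lengths in `lens` from sequences `seqs` (character vector)
all_substrings <- function(seqs, lens) {
  out <- vector("list", length(seqs) * length(lens))
  k <- 1L
  for (s in seqs) {
    n <- nchar(s)
    for (l in lens) {
      if (n >= l) {
        starts <- seq_len(n - l + 1L)
        out[[k]] <- substring(s, starts, starts + l - 1L)
        k <- k + 1L
      }
    }
  }
  unique(unlist(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
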