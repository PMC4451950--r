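#' Write / read a reference bundle on disk
#'
#' Sequences go to FASTA (`genome.fa`, `te_consensi.fa`, `ncrna.fa`,
#' `mirna.fa`), intervals to BED (0-based half-open; `clusters.bed`,
#' `utrs.bed`), and roles, classes, embedded-copy coordinates and build
#' parameters to `meta.yaml`.
#'
#' @param bundle a `reference_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wfa <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 80L)
  }
  wfa(c(chr_toy = bundle$genome), file.path(dir, "genome.fa"))
  wfa(bundle$te_seqs, file.path(dir, "te_consensi.fa"))
  wfa(bundle$ncrna, file.path(dir, "ncrna.fa"))
  wfa(bundle$mirna, file.path(dir, "mirna.fa"))
  write_bed(bundle$clusters, file.path(dir, "clusters.bed"))
  write_bed(bundle$utr_sources, file.path(dir, "utrs.bed"))
  meta <- list(
    clusters = bundle$clusters,
    te_panel = bundle$te_panel,
    te_embeds = bundle$te_embeds,
    te_copies = bundle$te_copies,
    utr_sources = bundle$utr_sources,
    params = bundle$params,
    seed = bundle$seed
  )
  yaml::write_yaml(lapply(meta, function(x)
    if (is.data.frame(x)) as.list(x) else x), file.path(dir, "meta.yaml"))
  invisible(dir)
}

# BED is 0-based half-open; internal intervals are 1-based inclusive
write_bed <- function(df, path) {
  bed <- data.frame(chrom = "chr_toy", start = df$start - 1L, end = df$end,
                    name = df$id, score = 0L, strand = df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(dir) {
  rfa <- function(path) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  as_df <- function(x) as.data.frame(x, stringsAsFactors = FALSE)
  structure(list(
    genome = unname(rfa(file.path(dir, "genome.fa"))[1]),
    clusters = as_df(meta$clusters),
    te_panel = as_df(meta$te_panel),
    te_seqs = rfa(file.path(dir, "te_consensi.fa")),
    te_embeds = as_df(meta$te_embeds),
    te_copies = as_df(meta$te_copies),
    utr_sources = as_df(meta$utr_sources),
    ncrna = rfa(file.path(dir, "ncrna.fa")),
    mirna = rfa(file.path(dir, "mirna.fa")),
    params = meta$params,
    seed = meta$seed
  ), class = "reference_bundle")
}

#' Write / read a simulated small-RNA library
#'
#' Reads are written as FASTQ (constant quality "I") or FASTA; truth labels
#' go to a sidecar `<id>.truth.tsv` that the analysis pipeline never reads.
#'
#' @param lib a `small_rna_library`.
#' @param dir output directory.
#' @param format "fastq" or "fasta".
#' @param truth also write the sidecar truth table.
#' @return path of the reads file, invisibly.
#' @export
write_library <- function(lib, dir, format = c("fastq", "fasta"),
                          truth = TRUE) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, paste0(lib$library_id, ".", format))
  if (format == "fastq") {
    qual <- strrep("I", nchar(lib$reads$sequence))
    writeLines(paste0("@", lib$reads$read_id, "\n", lib$reads$sequence,
                      "\n+\n", qual), path)
  } else {
    writeLines(paste0(">", lib$reads$read_id, "\n", lib$reads$sequence), path)
  }
  if (truth && !is.null(lib$truth)) {
    write_tsv_det(lib$truth, file.path(dir, paste0(lib$library_id,
                                                   ".truth.tsv")))
  }
  invisible(path)
}

#' @rdname write_library
#' @param path reads file (FASTQ/FASTA, extension-sniffed).
#' @param library_id optional id; defaults to the file stem.
#' @export
read_library <- function(path, library_id = NULL) {
  fmt <- if (grepl("\\.(fastq|fq)$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  id <- library_id %||% sub("\\.[^.]+$", "", basename(path))
  structure(list(
    library_id = id,
    reads = data.frame(read_id = sub(" .*", "", names(x)),
                       sequence = as.character(x), stringsAsFactors = FALSE),
    truth = NULL
  ), class = "small_rna_library")
}
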