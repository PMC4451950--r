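#' Default parameters for the toy reference bundle
#'
#' The bundle emulates the feature classes of an ovarian small-RNA study:
#' a germline normalizer piRNA cluster (42AB-like), a somatic cluster built
#' from antisense fragments of soma-dominant TE consensi (flamenco-like),
#' germline-dominant TE families present as two exact genomic copies
#' (multi-mappers), genic 3'UTR piRNA sources (traffic jam / jim-like),
#' abundant ncRNA stand-ins (rRNA/tRNA/snRNA) and a set of mature miRNAs.
#'
#' @return named list of build parameters.
#' @export
default_build_params <- function() {
  list(
    genome_length          = 60000L,
    germline_cluster_length = 4000L,
    somatic_cluster_spacer = 150L,   # backbone padding around embedded TE copies
    utr_lengths            = c(tj_like = 900L, jim_like = 800L, CG32000_like = 700L),
    utr_strands            = c("+", "-", "+"),
    soma_te_lengths        = c(ZAM_like = 1500L, Tabor_like = 1200L, Idefix_like = 900L),
    germline_te_lengths    = c(Felement_like = 1400L, Burdock_like = 1000L),
    germline_te_copies     = 2L,
    ncrna_lengths          = c(rRNA_like = 1500L, tRNA_like = 90L, snRNA_like = 150L),
    n_mirna                = 8L,
    min_gap                = 50L
  )
}

SOURCE_CLASSES <- c("germline_cluster_piRNA", "somatic_cluster_piRNA",
                    "soma_TE_piRNA", "germline_TE_piRNA",
                    "utr_piRNA", "miRNA", "ncRNA_fragment")

#' Build a self-consistent toy reference bundle
#'
#' Generates a single random chromosome and places, without overlap: a
#' germline normalizer piRNA cluster, a somatic piRNA cluster carrying one
#' antisense copy of every soma-dominant TE consensus, 3'UTR piRNA source
#' intervals, and two exact genomic copies of every germline-dominant TE
#' consensus. Soma-dominant consensi occur in the genome only inside the
#' somatic cluster, so their piRNAs are genome-unique cluster mappers (as for
#' flamenco), while germline TE piRNAs are genomic multi-mappers. Cluster
#' 23-mer genome-uniqueness is enforced by rejection sampling.
#'
#' @param build_params list as from [default_build_params()]; supplied entries
#'   override the defaults, unknown entries are an error.
#' @param seed integer seed; the bundle is byte-identical for a fixed seed.
#' @param max_tries rebuild attempts if the uniqueness check fails.
#' @return an object of class `reference_bundle`.
#' @export
build_reference <- function(build_params = list(), seed = 1L, max_tries = 10L) {
  defaults <- default_build_params()
  unknown <- setdiff(names(build_params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown build parameters: ", paste(unknown, collapse = ", "))
  }
  p <- utils::modifyList(defaults, build_params)

  for (try in seq_len(max_tries)) {
    set.seed(as.integer(seed) + (try - 1L) * 1000003L)
    bundle <- build_reference_once(p)
    if (cluster_kmers_unique(bundle, k = 23L)) {
      bundle$seed <- as.integer(seed)
      return(bundle)
    }
  }
  stop("could not build a bundle with genome-unique cluster 23-mers after ",
       max_tries, " attempts")
}

build_reference_once <- function(p) {
  # soma TE consensi; one antisense copy of each is embedded in the somatic cluster
  soma_te <- vapply(p$soma_te_lengths, random_dna, character(1))
  germ_te <- vapply(p$germline_te_lengths, random_dna, character(1))

  n_soma <- length(soma_te)
  somatic_cluster_length <- sum(nchar(soma_te)) +
    p$somatic_cluster_spacer * (n_soma + 1L)

  # features to place, in genome order after a random shuffle
  feat <- data.frame(
    id = c("cluster_42AB_like", "cluster_flamenco_like",
           names(p$utr_lengths),
           unlist(lapply(names(germ_te), function(id)
             paste0(id, "_copy", seq_len(p$germline_te_copies))))),
    type = c("cluster", "cluster",
             rep("utr", length(p$utr_lengths)),
             rep("te_copy", length(germ_te) * p$germline_te_copies)),
    len = c(p$germline_cluster_length, somatic_cluster_length,
            unname(p$utr_lengths),
            rep(unname(nchar(germ_te)), each = p$germline_te_copies)),
    stringsAsFactors = FALSE
  )
  n_feat <- nrow(feat)
  needed <- sum(feat$len) + p$min_gap * (n_feat + 1L)
  if (needed > p$genome_length) {
    stop("infeasible packing: features plus minimum gaps need ", needed,
         " bp but the genome is only ", p$genome_length, " bp")
  }

  feat <- feat[sample.int(n_feat), , drop = FALSE]
  slack <- p$genome_length - needed
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, n_feat + 1L)))
  gaps <- (p$min_gap + extra)[seq_len(n_feat)]
  starts <- cumsum(gaps + c(0L, feat$len[-n_feat])) + 1L
  feat$start <- starts
  feat$end <- starts + feat$len - 1L

  genome <- random_dna(p$genome_length)

  # overwrite genomic copies of germline TEs with the exact consensus
  for (i in which(feat$type == "te_copy")) {
    te_id <- sub("_copy[0-9]+$", "", feat$id[i])
    substr(genome, feat$start[i], feat$end[i]) <- germ_te[[te_id]]
  }

  # lay antisense soma TE copies into the somatic cluster, spacer bp apart
  smc <- feat[feat$id == "cluster_flamenco_like", ]
  embeds <- data.frame(te_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
  at <- smc$start + p$somatic_cluster_spacer
  for (id in names(soma_te)) {
    frag <- revcomp(soma_te[[id]])
    substr(genome, at, at + nchar(frag) - 1L) <- frag
    embeds <- rbind(embeds, data.frame(te_id = id, start = at,
                                       end = at + nchar(frag) - 1L,
                                       strand = "-", stringsAsFactors = FALSE))
    at <- at + nchar(frag) + p$somatic_cluster_spacer
  }

  clusters <- data.frame(
    id = c("cluster_42AB_like", "cluster_flamenco_like"),
    start = c(feat$start[feat$id == "cluster_42AB_like"], smc$start),
    end = c(feat$end[feat$id == "cluster_42AB_like"], smc$end),
    role = c("germline_normalizer", "somatic"),
    strand = c("+", "+"),
    stringsAsFactors = FALSE
  )

  utr_order <- match(names(p$utr_lengths), feat$id)
  utr_sources <- data.frame(
    id = feat$id[utr_order],
    start = feat$start[utr_order],
    end = feat$end[utr_order],
    strand = p$utr_strands,
    stringsAsFactors = FALSE
  )

  te_copies <- feat[feat$type == "te_copy",
                    c("id", "start", "end"), drop = FALSE]
  te_copies$te_id <- sub("_copy[0-9]+$", "", te_copies$id)
  te_copies$strand <- "+"
  rownames(te_copies) <- NULL

  ncrna <- vapply(p$ncrna_lengths, random_dna, character(1))
  mirna <- vapply(seq_len(p$n_mirna), function(i)
    random_dna(sample(21:23, 1)), character(1))
  names(mirna) <- sprintf("mir_like_%02d", seq_len(p$n_mirna))

  te_panel <- data.frame(
    id = c(names(soma_te), names(germ_te)),
    class = c(rep("soma_dominant", length(soma_te)),
              rep("germline_dominant", length(germ_te))),
    length = c(unname(nchar(soma_te)), unname(nchar(germ_te))),
    stringsAsFactors = FALSE
  )

  structure(list(
    genome = genome,
    clusters = clusters,
    te_panel = te_panel,
    te_seqs = c(soma_te, germ_te),
    te_embeds = embeds,
    te_copies = te_copies,
    utr_sources = utr_sources,
    ncrna = ncrna,
    mirna = mirna,
    params = p
  ), class = "reference_bundle")
}

#' Check genome-uniqueness of cluster k-mers
#'
#' TRUE iff every k-mer inside a cluster interval occurs exactly once on the
#' genome forward strand and never on the reverse strand.
#'
#' @param bundle a `reference_bundle`.
#' @param k word size (default 23).
#' @export
cluster_kmers_unique <- function(bundle, k = 23L) {
  g <- bundle$genome
  n <- nchar(g)
  starts <- seq_len(n - k + 1L)
  kmers <- substring(g, starts, starts + k - 1L)
  counts <- table(kmers)
  for (i in seq_len(nrow(bundle$clusters))) {
    cs <- bundle$clusters$start[i]; ce <- bundle$clusters$end[i]
    cs_starts <- seq.int(cs, ce - k + 1L)
    ck <- substring(g, cs_starts, cs_starts + k - 1L)
    if (any(counts[ck] != 1L)) return(FALSE)
    if (any(revcomp(unique(ck)) %in% kmers)) return(FALSE)
  }
  TRUE
}

#' Validate reference-bundle invariants
#'
#' Checks interval bounds and pairwise non-overlap, id uniqueness, and the
#' presence of every soma-dominant consensus as an antisense substring of the
#' somatic cluster. Errors on the first violation.
#'
#' @param bundle a `reference_bundle`.
#' @return the bundle, invisibly.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  iv <- rbind(bundle$clusters[, c("id", "start", "end")],
              bundle$utr_sources[, c("id", "start", "end")])
  if (any(iv$start < 1L) || any(iv$end > nchar(bundle$genome))) {
    stop("interval outside genome bounds")
  }
  iv <- iv[order(iv$start), ]
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
    stop("overlapping intervals")
  }
  ids <- c(iv$id, bundle$te_panel$id, names(bundle$ncrna), names(bundle$mirna))
  if (anyDuplicated(ids)) stop("duplicated feature ids")
  smc <- bundle$clusters[bundle$clusters$role == "somatic", ]
  smc_seq <- substr(bundle$genome, smc$start, smc$end)
  soma <- bundle$te_panel$id[bundle$te_panel$class == "soma_dominant"]
  for (id in soma) {
    if (!grepl(revcomp(bundle$te_seqs[[id]]), smc_seq, fixed = TRUE)) {
      stop("somatic cluster lacks antisense copy of ", id)
    }
  }
  invisible(bundle)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("reference_bundle:", nchar(x$genome), "bp genome;",
      nrow(x$clusters), "clusters;", nrow(x$te_panel), "TE consensi;",
      nrow(x$utr_sources), "3'UTR sources;",
      length(x$ncrna), "ncRNAs;", length(x$mirna), "miRNAs\n")
  invisible(x)
}
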