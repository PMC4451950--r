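#' Cluster-anchored normalization factor
#'
#' Libraries are made comparable by scaling each to one million piRNAs that
#' map uniquely to the germline normalizer cluster, which is unaffected by
#' follicle-cell-restricted perturbations. The factor multiplies raw counts.
#'
#' @param breakdown an `annotation_breakdown`.
#' @param normalizer id of the normalizer cluster
#'   (default "cluster_42AB_like").
#' @return scale factor = 1e6 / (genome-unique piRNA count in the cluster).
#' @export
normalization_factor <- function(breakdown, normalizer = "cluster_42AB_like") {
  stopifnot(inherits(breakdown, "annotation_breakdown"))
  n <- breakdown$cluster_unique[normalizer]
  if (is.na(n)) stop("unknown normalizer cluster: ", normalizer)
  if (n == 0) stop("library unusable: zero genome-unique piRNAs in ",
                   normalizer)
  1e6 / as.numeric(n)
}

new_count_table <- function(df, library_id, scale_factor) {
  df$norm_total <- (df$sense + df$antisense) * scale_factor
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  attr(df, "library_id") <- library_id
  attr(df, "scale_factor") <- scale_factor
  df
}

#' Per-TE-family piRNA count table
#'
#' Each piRNA-category read that hits a consensus within the mismatch
#' budget contributes one count to that family (once per family, however
#' many positions it matches), split by the strand of its best hit.
#'
#' @param annotated an `annotated_reads` data.frame.
#' @param bundle a `reference_bundle` (panel and consensi).
#' @param max_mismatches mismatch budget (default 4).
#' @param scale_factor normalization factor applied to totals.
#' @return a `count_table` with one row per TE family: feature_id, class,
#'   sense, antisense, norm_total.
#' @export
te_counts <- function(annotated, bundle, max_mismatches = 4L,
                      scale_factor = 1) {
  stopifnot(inherits(annotated, "annotated_reads"))
  if (nrow(bundle$te_panel) == 0) stop("empty TE panel")
  pir <- annotated[annotated$category == "piRNA", , drop = FALSE]
  base <- data.frame(feature_id = bundle$te_panel$id,
                     class = bundle$te_panel$class,
                     sense = 0, antisense = 0, stringsAsFactors = FALSE)
  if (nrow(pir) > 0) {
    u <- unique(pir$sequence)
    mult <- as.vector(table(factor(pir$sequence, levels = u)))
    hits <- map_consensus(u, bundle$te_seqs, max_mismatches)
    if (nrow(hits) > 0) {
      # one contribution per (read, family): keep the best hit
      # (fewest mismatches, sense wins ties)
      hits <- hits[order(hits$query, hits$ref, hits$mismatches,
                         hits$strand), ]
      best <- hits[!duplicated(hits[, c("query", "ref")]), , drop = FALSE]
      best$weight <- mult[best$query]
      agg <- stats::aggregate(weight ~ ref + strand, data = best, FUN = sum)
      for (i in seq_len(nrow(agg))) {
        row <- match(agg$ref[i], base$feature_id)
        col <- if (agg$strand[i] == "+") "sense" else "antisense"
        base[row, col] <- base[row, col] + agg$weight[i]
      }
    }
  }
  new_count_table(base, attr(annotated, "library_id"), scale_factor)
}

#' Per-interval genome-unique piRNA count table
#'
#' Counts genome-unique piRNAs whose sole perfect alignment lies entirely
#' within each cluster or 3'UTR source interval; sense means the hit strand
#' equals the feature strand.
#'
#' @inheritParams te_counts
#' @param features data.frame with id, start, end, strand and optionally a
#'   class column; defaults to the bundle's clusters and 3'UTR sources.
#' @return a `count_table` with one row per interval feature.
#' @export
feature_counts <- function(annotated, bundle, features = NULL,
                           scale_factor = 1) {
  stopifnot(inherits(annotated, "annotated_reads"))
  if (is.null(features)) {
    cl <- bundle$clusters[, c("id", "start", "end", "strand")]
    cl$class <- bundle$clusters$role
    ut <- bundle$utr_sources[, c("id", "start", "end", "strand")]
    ut$class <- "utr"
    features <- rbind(cl, ut)
  }
  if (is.null(features$class)) features$class <- "interval"
  gu <- annotated[annotated$genome_unique &
                    annotated$category == "piRNA", , drop = FALSE]
  sense <- antisense <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    inside <- gu$hit_start >= features$start[i] &
      gu$hit_start + gu$length - 1L <= features$end[i]
    sense[i] <- sum(inside & gu$hit_strand == features$strand[i])
    antisense[i] <- sum(inside & gu$hit_strand != features$strand[i])
  }
  base <- data.frame(feature_id = features$id, class = features$class,
                     sense = sense, antisense = antisense,
                     stringsAsFactors = FALSE)
  new_count_table(base, attr(annotated, "library_id"), scale_factor)
}

#' 5'-end density profile of a feature
#'
#' Collapses qualifying piRNA reads to their 5'-end coordinate along the
#' feature and accumulates `scale_factor` per hit into strand-specific
#' vectors. TE consensi are profiled from all mismatch-tolerant hits
#' (policy `all_hits`); clusters and 3'UTR intervals from genome-unique
#' perfect hits only (policy `genome_unique_only`), with coordinates
#' reported 5'->3' on the feature strand.
#'
#' @param annotated an `annotated_reads` data.frame.
#' @param bundle a `reference_bundle`.
#' @param feature_id a TE family, cluster or 3'UTR source id.
#' @param scale_factor normalization factor (default 1, i.e. raw).
#' @param max_mismatches mismatch budget for TE profiles.
#' @return a `profile_track`: list with feature_id, length, sense and
#'   antisense vectors, policy, scale_factor.
#' @export
profile_feature <- function(annotated, bundle, feature_id, scale_factor = 1,
                            max_mismatches = 4L) {
  stopifnot(inherits(annotated, "annotated_reads"))
  pir <- annotated[annotated$category == "piRNA", , drop = FALSE]
  if (feature_id %in% bundle$te_panel$id) {
    L <- nchar(bundle$te_seqs[[feature_id]])
    sense <- antisense <- numeric(L)
    if (nrow(pir) > 0) {
      hits <- map_consensus(pir$sequence,
                            bundle$te_seqs[feature_id], max_mismatches)
      if (nrow(hits) > 0) {
        for (st in c("+", "-")) {
          fp <- hits$five_prime[hits$strand == st]
          if (length(fp) > 0) {
            acc <- tabulate(fp, nbins = L) * scale_factor
            if (st == "+") sense <- acc else antisense <- acc
          }
        }
      }
    }
    policy <- "all_hits"
  } else {
    iv <- rbind(bundle$clusters[, c("id", "start", "end", "strand")],
                bundle$utr_sources[, c("id", "start", "end", "strand")])
    row <- iv[iv$id == feature_id, , drop = FALSE]
    if (nrow(row) == 0) stop("unknown feature id: ", feature_id)
    L <- row$end - row$start + 1L
    gu <- pir[pir$genome_unique, , drop = FALSE]
    inside <- gu$hit_start >= row$start &
      gu$hit_start + gu$length - 1L <= row$end
    gu <- gu[inside, , drop = FALSE]
    sense <- antisense <- numeric(L)
    if (nrow(gu) > 0) {
      g5 <- ifelse(gu$hit_strand == "+", gu$hit_start,
                   gu$hit_start + gu$length - 1L)
      rel <- if (row$strand == "+") g5 - row$start + 1L else row$end - g5 + 1L
      is_sense <- gu$hit_strand == row$strand
      if (any(is_sense)) {
        sense <- tabulate(rel[is_sense], nbins = L) * scale_factor
      }
      if (any(!is_sense)) {
        antisense <- tabulate(rel[!is_sense], nbins = L) * scale_factor
      }
    }
    policy <- "genome_unique_only"
  }
  structure(list(feature_id = feature_id, length = L, sense = sense,
                 antisense = antisense, policy = policy,
                 scale_factor = scale_factor),
            class = "profile_track")
}

#' @export
print.profile_track <- function(x, ...) {
  cat("profile_track", x$feature_id, "(", x$length, "nt,", x$policy, ")",
      "sense mass", sum(x$sense), "antisense mass", sum(x$antisense), "\n")
  invisible(x)
}

#' Export a profile track as TSV
#'
#' Positions are 1-based inclusive; antisense values are negated in the
#' file (plotting convention: sense up, antisense down) though stored
#' non-negative in the object.
#'
#' @param track a `profile_track`.
#' @param path output TSV path.
#' @export
export_profile <- function(track, path) {
  write_tsv_det(data.frame(position = seq_len(track$length),
                           sense = track$sense,
                           antisense = -track$antisense), path)
}

#' Pairwise library comparison over a feature panel
#'
#' Emits per-feature normalized totals of both libraries and their Pearson
#' correlation (the scatter-plot statistic). With fewer than two features
#' or zero variance in either vector, r is undefined and flagged.
#'
#' @param table_a,table_b `count_table`s over the same feature panel.
#' @param log10_mode correlate log10(x + 1) instead of raw normalized counts.
#' @return list with `pairs` (feature_id, class, a, b), `pearson_r`, and
#'   `flagged` (TRUE when r is undefined).
#' @export
compare_libraries <- function(table_a, table_b, log10_mode = FALSE) {
  stopifnot(inherits(table_a, "count_table"), inherits(table_b, "count_table"))
  if (!identical(sort(table_a$feature_id), sort(table_b$feature_id))) {
    stop("feature panels differ between libraries")
  }
  b <- table_b[match(table_a$feature_id, table_b$feature_id), ]
  x <- table_a$norm_total; y <- b$norm_total
  if (log10_mode) { x <- log10(x + 1); y <- log10(y + 1) }
  flagged <- length(x) < 2 || stats::var(x) == 0 || stats::var(y) == 0
  r <- if (flagged) NA_real_ else stats::cor(x, y, method = "pearson")
  list(pairs = data.frame(feature_id = table_a$feature_id,
                          class = table_a$class, a = table_a$norm_total,
                          b = b$norm_total, stringsAsFactors = FALSE),
       pearson_r = r, flagged = flagged)
}

#' Per-feature fold changes between conditions
#'
#' Ratio of normalized totals, condition relative to control, with a
#' pseudocount guarding zeros.
#'
#' @param table_condition,table_control `count_table`s over the same panel.
#' @param pseudocount added to both totals (default 1).
#' @return data.frame feature_id, class, condition, control, ratio.
#' @export
fold_changes <- function(table_condition, table_control, pseudocount = 1) {
  stopifnot(inherits(table_condition, "count_table"),
            inherits(table_control, "count_table"))
  if (!identical(sort(table_condition$feature_id),
                 sort(table_control$feature_id))) {
    stop("feature panels differ between libraries")
  }
  ctl <- table_control[match(table_condition$feature_id,
                             table_control$feature_id), ]
  data.frame(feature_id = table_condition$feature_id,
             class = table_condition$class,
             condition = table_condition$norm_total,
             control = ctl$norm_total,
             ratio = (table_condition$norm_total + pseudocount) /
               (ctl$norm_total + pseudocount),
             stringsAsFactors = FALSE)
}

#' RNA-IP enrichment over an input library
#'
#' Both libraries are scaled to one million genome-unique reads (all
#' categories); enrichment is the scaled IP count over the scaled input
#' count per feature, with a pseudocount.
#'
#' @param ip_annotated,input_annotated `annotated_reads` for the IP and
#'   input fractions.
#' @param bundle a `reference_bundle`.
#' @param features character vector of feature ids (TE families or
#'   intervals); defaults to clusters plus 3'UTR sources.
#' @param pseudocount added to scaled counts (default 1).
#' @param max_mismatches budget for TE-family attribution.
#' @return data.frame feature_id, ip_scaled, input_scaled, enrichment.
#' @export
rip_enrichment <- function(ip_annotated, input_annotated, bundle,
                           features = NULL, pseudocount = 1,
                           max_mismatches = 4L) {
  features <- features %||% c(bundle$clusters$id, bundle$utr_sources$id)
  scale_of <- function(ann) {
    gu <- sum(ann$genome_unique, na.rm = TRUE)
    if (gu == 0) stop("library has zero genome-unique reads")
    1e6 / gu
  }
  count_of <- function(fid, ann) {
    if (fid %in% bundle$te_panel$id) {
      u <- unique(ann$sequence)
      mult <- as.vector(table(factor(ann$sequence, levels = u)))
      hits <- map_consensus(u, bundle$te_seqs[fid], max_mismatches)
      if (nrow(hits) == 0) return(0)
      sum(mult[unique(hits$query)])
    } else {
      iv <- rbind(bundle$clusters[, c("id", "start", "end")],
                  bundle$utr_sources[, c("id", "start", "end")])
      row <- iv[iv$id == fid, , drop = FALSE]
      if (nrow(row) == 0) stop("unknown feature id: ", fid)
      gu <- ann[ann$genome_unique, , drop = FALSE]
      sum(gu$hit_start >= row$start &
            gu$hit_start + gu$length - 1L <= row$end)
    }
  }
  s_ip <- scale_of(ip_annotated); s_in <- scale_of(input_annotated)
  ip <- vapply(features, count_of, numeric(1), ann = ip_annotated) * s_ip
  inp <- vapply(features, count_of, numeric(1), ann = input_annotated) * s_in
  data.frame(feature_id = features, ip_scaled = ip, input_scaled = inp,
             enrichment = (ip + pseudocount) / (inp + pseudocount),
             stringsAsFactors = FALSE, row.names = NULL)
}
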