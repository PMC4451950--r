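#' Build a validated pipeline configuration
#'
#' Collects every tunable of the workflow: the reference build, the
#' scenarios to simulate, library depth, the annotation parameters, the
#' normalizer cluster, pseudocounts, the statistical gate alpha and the
#' master seed. Unknown entries are rejected and every parameter is checked
#' against its documented domain before any computation.
#'
#' @param ... entries overriding the defaults; see Details.
#' @details Recognised entries: `reference` (build-parameter list, or a
#'   directory written by [write_reference()]), `scenarios` (list of
#'   `scenario_config`s; the first is the control), `n_reads`,
#'   `max_mismatches`, `pirna_range`, `sirna_len`, `normalizer`,
#'   `pseudocount`, `gate_alpha`, `seed`, `profile_features` (feature ids to
#'   export 5'-end profiles for), `write_libraries` (write FASTQ + truth).
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    reference = list(),
    scenarios = list(scenario_control(), scenario_tn_drosha()),
    n_reads = 200000L,
    max_mismatches = 4L,
    pirna_range = c(23L, 29L),
    sirna_len = 21L,
    normalizer = "cluster_42AB_like",
    pseudocount = 1,
    gate_alpha = 0.05,
    seed = 1L,
    profile_features = character(0),
    write_libraries = FALSE
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  cfg[names(user)] <- user
  if (cfg$max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (cfg$n_reads < 0) stop("n_reads must be >= 0")
  if (length(cfg$pirna_range) != 2 || cfg$pirna_range[1] > cfg$pirna_range[2] ||
      cfg$pirna_range[1] < 18 || cfg$pirna_range[2] > 29) {
    stop("pirna_range must be an ordered pair within [18, 29]")
  }
  if (!(cfg$sirna_len %in% 18:29)) stop("sirna_len must lie in [18, 29]")
  if (cfg$pseudocount < 0) stop("pseudocount must be >= 0")
  if (cfg$gate_alpha <= 0 || cfg$gate_alpha >= 1) {
    stop("gate_alpha must lie in (0, 1)")
  }
  if (length(cfg$scenarios) < 1 ||
      !all(vapply(cfg$scenarios, inherits, logical(1), "scenario_config"))) {
    stop("scenarios must be a non-empty list of scenario_config objects")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis chain
#'
#' Builds (or loads) the reference, simulates one library per scenario,
#' annotates and summarizes each, computes the cluster-anchored
#' normalization, TE-family and interval count tables and requested 5'-end
#' profiles, then compares every non-control scenario against the control:
#' scatter table with Pearson r, per-feature fold changes, and the gated
#' two-sample test contrasting soma-dominant against germline-dominant
#' TE-family log2 fold changes. All tables are tab-separated; a manifest
#' records parameters and seeds, so identical configurations reproduce
#' byte-identical result directories.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created; must not pre-exist unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with bundle, breakdowns, count tables,
#'   comparisons and the output paths.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && !overwrite) {
    stop("output directory exists: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- if (is.character(config$reference)) {
    read_reference(config$reference)
  } else {
    build_reference(config$reference, seed = config$seed)
  }
  validate_bundle(bundle)
  write_reference(bundle, file.path(out_dir, "reference"))

  breakdowns <- list(); tables_te <- list(); tables_iv <- list()
  scen_names <- vapply(config$scenarios, function(s) s$name, character(1))
  if (anyDuplicated(scen_names)) stop("duplicate scenario names")

  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    lib <- simulate_library(bundle, sc, config$n_reads,
                            seed = config$seed + i)
    if (isTRUE(config$write_libraries)) {
      write_library(lib, file.path(out_dir, "libraries"))
    }
    ann <- classify_reads(lib, bundle, pirna_range = config$pirna_range,
                          sirna_len = config$sirna_len)
    bd <- annotation_breakdown(ann, bundle)
    write_tsv_det(as.data.frame(bd),
                  file.path(out_dir, paste0(sc$name, ".breakdown.tsv")))
    sf <- normalization_factor(bd, config$normalizer)
    tte <- te_counts(ann, bundle, config$max_mismatches, sf)
    tiv <- feature_counts(ann, bundle, scale_factor = sf)
    write_tsv_det(as.data.frame(tte),
                  file.path(out_dir, paste0(sc$name, ".te_counts.tsv")))
    write_tsv_det(as.data.frame(tiv),
                  file.path(out_dir, paste0(sc$name, ".feature_counts.tsv")))
    for (fid in config$profile_features) {
      trk <- profile_feature(ann, bundle, fid, scale_factor = sf,
                             max_mismatches = config$max_mismatches)
      export_profile(trk, file.path(out_dir,
                                    paste0(sc$name, ".profile.", fid, ".tsv")))
    }
    breakdowns[[sc$name]] <- bd
    tables_te[[sc$name]] <- tte
    tables_iv[[sc$name]] <- tiv
  }

  control <- scen_names[1]
  comparisons <- list()
  for (nm in scen_names[-1]) {
    cmp <- compare_libraries(tables_te[[nm]], tables_te[[control]])
    write_tsv_det(cmp$pairs,
                  file.path(out_dir, paste0(nm, "_vs_", control,
                                            ".scatter.tsv")))
    fc_te <- fold_changes(tables_te[[nm]], tables_te[[control]],
                          config$pseudocount)
    fc_iv <- fold_changes(tables_iv[[nm]], tables_iv[[control]],
                          config$pseudocount)
    fc <- rbind(fc_te, fc_iv)
    write_tsv_det(fc, file.path(out_dir, paste0(nm, "_vs_", control,
                                                ".fold_changes.tsv")))
    soma <- log2(fc_te$ratio[fc_te$class == "soma_dominant"])
    germ <- log2(fc_te$ratio[fc_te$class == "germline_dominant"])
    tst <- compare_two_samples(soma, germ, config$gate_alpha)
    summ <- data.frame(
      comparison = paste0(nm, "_vs_", control),
      pearson_r = cmp$pearson_r,
      r_flagged = cmp$flagged,
      soma_vs_germline_test = tst$test_used,
      soma_vs_germline_p = tst$p_value,
      stringsAsFactors = FALSE)
    write_tsv_det(summ, file.path(out_dir, paste0(nm, "_vs_", control,
                                                  ".summary.tsv")))
    comparisons[[nm]] <- list(pearson = cmp, fold_changes = fc, test = tst)
  }

  manifest <- list(
    normalizer = config$normalizer,
    n_reads = config$n_reads,
    max_mismatches = config$max_mismatches,
    pirna_range = config$pirna_range,
    sirna_len = config$sirna_len,
    pseudocount = config$pseudocount,
    gate_alpha = config$gate_alpha,
    seed = config$seed,
    scenarios = scen_names,
    control = control
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(bundle = bundle, breakdowns = breakdowns,
                 te_tables = tables_te, interval_tables = tables_iv,
                 comparisons = comparisons, out_dir = out_dir))
}
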