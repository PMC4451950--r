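#' Default per-class read-length model
#'
#' Probability vectors over read length (nt) per source class. piRNA classes
#' are supported on 23-29 nt with a mode at 26 nt, as in ovarian somatic
#' libraries; ncRNA degradation fragments are uniform over the 18-29 nt
#' window retained by size selection. miRNA reads take the exact length of
#' the sampled mature miRNA, so that class has no entry.
#'
#' @return named list of named probability vectors.
#' @export
default_length_model <- function() {
  pirna <- stats::setNames(c(0.08, 0.14, 0.22, 0.24, 0.18, 0.09, 0.05), 23:29)
  list(
    germline_cluster_piRNA = pirna,
    somatic_cluster_piRNA  = pirna,
    soma_TE_piRNA          = pirna,
    germline_TE_piRNA      = pirna,
    utr_piRNA              = pirna,
    ncRNA_fragment         = stats::setNames(rep(1 / 12, 12), 18:29)
  )
}

#' Construct a simulation scenario
#'
#' A scenario fixes the mixture of read sources (class weights), a
#' multiplicative depletion factor per class, the length model, the piRNA
#' 1U (5'-uridine) bias, and the per-read probability that a TE-derived read
#' carries 1-4 substitutions against its consensus. Reads are drawn with
#' class probability proportional to weight x depletion.
#'
#' @param name scenario label, used as default library id.
#' @param source_weights non-negative weights, one per source class.
#' @param depletion multiplicative factors (> 0), one per source class.
#' @param length_model list as from [default_length_model()].
#' @param u1_bias expected fraction of piRNA-class reads whose 5' base is
#'   T (the DNA stand-in for U); in `[0, 1]`.
#' @param mismatch_rate per-read probability that a TE-derived read carries
#'   1-4 substitutions relative to its consensus.
#' @param te_antisense_frac named fractions of TE-derived reads drawn
#'   antisense to the consensus, per TE class.
#' @param seed default seed used by [simulate_library()].
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(name,
                            source_weights,
                            depletion = stats::setNames(rep(1, 7), SOURCE_CLASSES),
                            length_model = default_length_model(),
                            u1_bias = 0.75,
                            mismatch_rate = 0.1,
                            te_antisense_frac = c(soma_TE_piRNA = 0.9,
                                                  germline_TE_piRNA = 0.6),
                            seed = 1L) {
  sc <- structure(list(name = name,
                       source_weights = source_weights[SOURCE_CLASSES],
                       depletion = depletion[SOURCE_CLASSES],
                       length_model = length_model,
                       u1_bias = u1_bias,
                       mismatch_rate = mismatch_rate,
                       te_antisense_frac = te_antisense_frac,
                       seed = as.integer(seed)),
                  class = "scenario_config")
  names(sc$source_weights) <- SOURCE_CLASSES
  names(sc$depletion) <- SOURCE_CLASSES
  validate_scenario(sc)
  sc
}

#' @rdname scenario_config
#' @param x a `scenario_config` to validate.
#' @export
validate_scenario <- function(x) {
  stopifnot(inherits(x, "scenario_config"))
  w <- x$source_weights; d <- x$depletion
  if (anyNA(w) || any(w < 0) || sum(w) <= 0) {
    stop("source_weights must be non-negative with positive sum")
  }
  if (anyNA(d) || any(d <= 0)) stop("depletion factors must be > 0")
  if (is.na(x$u1_bias) || x$u1_bias < 0 || x$u1_bias > 1) {
    stop("u1_bias must be in [0, 1]")
  }
  if (x$mismatch_rate < 0 || x$mismatch_rate > 1) {
    stop("mismatch_rate must be in [0, 1]")
  }
  pirna_classes <- grep("piRNA$", SOURCE_CLASSES, value = TRUE)
  for (cl in pirna_classes) {
    lens <- as.integer(names(x$length_model[[cl]]))
    if (any(lens < 23L | lens > 29L)) {
      stop("piRNA-class lengths must lie in [23, 29] (", cl, ")")
    }
  }
  if (!is.null(x$length_model$ncRNA_fragment)) {
    lens <- as.integer(names(x$length_model$ncRNA_fragment))
    if (any(lens < 18L | lens > 29L)) stop("read lengths must lie in [18, 29]")
  }
  invisible(x)
}

# study-condition class mixture for a total-ovary library with a strong
# somatic compartment: germline cluster piRNAs dominate, follicle-cell
# sources (flamenco-like cluster, soma TEs, 3'UTR genes) together comparable
default_source_weights <- function() {
  stats::setNames(c(0.25, 0.20, 0.15, 0.10, 0.10, 0.12, 0.08), SOURCE_CLASSES)
}

#' Named perturbation scenarios
#'
#' `scenario_control()` is the unperturbed condition (WT-Drosha-like).
#' `scenario_tn_drosha()` depletes the somatic cluster and soma-dominant TE
#' piRNA classes by `depletion_factor` (default 4, the fold loss of
#' flamenco piRNAs under trans-dominant negative Drosha) and miRNAs by ~3x,
#' leaving germline classes and 3'UTR piRNAs untouched.
#' `scenario_yb()` reduces all ovarian somatic piRNA classes (somatic
#' cluster, soma TE and 3'UTR piRNAs) tenfold, the signature of a Yb mutant.
#' `scenario_piwi_kd()` similarly depletes all Piwi-loaded somatic classes.
#'
#' @param seed default simulation seed.
#' @param depletion_factor fold depletion applied to the targeted classes.
#' @param name scenario label.
#' @return a `scenario_config`.
#' @export
scenario_control <- function(seed = 1L, name = "WT_Drosha_like") {
  scenario_config(name, default_source_weights(), seed = seed)
}

#' @rdname scenario_control
#' @export
scenario_tn_drosha <- function(depletion_factor = 4, seed = 1L,
                               name = "TN_Drosha_like") {
  d <- stats::setNames(rep(1, 7), SOURCE_CLASSES)
  d[c("somatic_cluster_piRNA", "soma_TE_piRNA")] <- 1 / depletion_factor
  d["miRNA"] <- 0.3
  scenario_config(name, default_source_weights(), depletion = d, seed = seed)
}

#' @rdname scenario_control
#' @export
scenario_yb <- function(seed = 1L, name = "Yb_mutant_like") {
  d <- stats::setNames(rep(1, 7), SOURCE_CLASSES)
  d[c("somatic_cluster_piRNA", "soma_TE_piRNA", "utr_piRNA")] <- 0.1
  scenario_config(name, default_source_weights(), depletion = d, seed = seed)
}

#' @rdname scenario_control
#' @export
scenario_piwi_kd <- function(seed = 1L, name = "piwi_KD_like") {
  d <- stats::setNames(rep(1, 7), SOURCE_CLASSES)
  d[c("somatic_cluster_piRNA", "soma_TE_piRNA", "utr_piRNA")] <- 0.15
  scenario_config(name, default_source_weights(), depletion = d, seed = seed)
}
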