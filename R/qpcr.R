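#' Construct a qPCR measurement
#'
#' Ct replicate sets for a target and a reference amplicon, each under a
#' condition and a control, plus primer-pair efficiencies (per-cycle
#' amplification factor, 2 = perfect doubling).
#'
#' @param target,reference amplicon labels.
#' @param ct_target_condition,ct_target_control,ct_reference_condition,ct_reference_control
#'   numeric Ct replicate vectors (all > 0, non-empty).
#' @param e_target,e_reference primer efficiencies in (1, 2].
#' @return an object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(target, reference,
                             ct_target_condition, ct_target_control,
                             ct_reference_condition, ct_reference_control,
                             e_target = 2, e_reference = 2) {
  m <- structure(list(target = target, reference = reference,
                      ct = list(target_condition = ct_target_condition,
                                target_control = ct_target_control,
                                reference_condition = ct_reference_condition,
                                reference_control = ct_reference_control),
                      efficiency = c(target = e_target,
                                     reference = e_reference)),
                 class = "qpcr_measurement")
  for (nm in names(m$ct)) {
    v <- m$ct[[nm]]
    if (length(v) == 0) stop("empty Ct replicate set: ", nm)
    if (anyNA(v) || any(v <= 0)) stop("Ct values must be > 0 (", nm, ")")
  }
  if (any(m$efficiency <= 1 | m$efficiency > 2)) {
    stop("primer efficiencies must lie in (1, 2]")
  }
  m
}

#' Relative RNA level by the 2^(-ddCt) method
#'
#' dCt = mean Ct(target) - mean Ct(reference) within each of condition and
#' control; ddCt = dCt(condition) - dCt(control); the fold change of the
#' target in the condition relative to the control is 2^(-ddCt).
#' The replicate SD is obtained by recomputing the statistic over every
#' combination of one Ct per replicate set.
#'
#' @param m a `qpcr_measurement`.
#' @return list with `estimate` (the fold change), `sd` (across replicate
#'   combinations; NA with single replicates), `ddct`, and `assay`.
#' @export
ddct_fold_change <- function(m) {
  stopifnot(inherits(m, "qpcr_measurement"))
  mu <- vapply(m$ct, mean, numeric(1))
  ddct <- (mu[["target_condition"]] - mu[["reference_condition"]]) -
    (mu[["target_control"]] - mu[["reference_control"]])
  combos <- expand.grid(m$ct, KEEP.OUT.ATTRS = FALSE)
  per <- 2^(-((combos$target_condition - combos$reference_condition) -
                (combos$target_control - combos$reference_control)))
  list(estimate = unname(2^(-ddct)),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       ddct = unname(ddct), assay = "rna_ddct")
}

#' Relative small-RNA level (poly(A)-tailed RT-qPCR)
#'
#' Identical arithmetic to [ddct_fold_change()], quantified relative to a
#' reference small-RNA species (e.g. an abundant germline cluster piRNA);
#' kept as a named operation so reports label the assay type.
#'
#' @inheritParams ddct_fold_change
#' @return as [ddct_fold_change()], with `assay = "small_rna_ddct"`.
#' @export
small_rna_fold_change <- function(m) {
  out <- ddct_fold_change(m)
  out$assay <- "small_rna_ddct"
  out
}

#' Construct a ChIP-qPCR sample
#'
#' Ct values (replicates allowed) for a target and a reference (positive
#' control) amplicon in the IP and input fractions, with primer
#' efficiencies.
#'
#' @param target,reference amplicon labels.
#' @param ct_ip_target,ct_input_target,ct_ip_reference,ct_input_reference
#'   numeric Ct vectors (all > 0, non-empty).
#' @param e_target,e_reference primer efficiencies in (1, 2].
#' @return an object of class `chip_sample`.
#' @export
chip_sample <- function(target, reference,
                        ct_ip_target, ct_input_target,
                        ct_ip_reference, ct_input_reference,
                        e_target = 2, e_reference = 2) {
  s <- structure(list(target = target, reference = reference,
                      ct = list(ip_target = ct_ip_target,
                                input_target = ct_input_target,
                                ip_reference = ct_ip_reference,
                                input_reference = ct_input_reference),
                      efficiency = c(target = e_target,
                                     reference = e_reference)),
                 class = "chip_sample")
  for (nm in names(s$ct)) {
    v <- s$ct[[nm]]
    if (length(v) == 0) stop("missing Ct: ", nm)
    if (anyNA(v) || any(v <= 0)) stop("Ct values must be > 0 (", nm, ")")
  }
  if (any(s$efficiency <= 1 | s$efficiency > 2)) {
    stop("primer efficiencies must lie in (1, 2]")
  }
  s
}

#' Efficiency-corrected ChIP relative DNA level
#'
#' Computes, exactly as printed in the source protocol,
#' `E_t^Ct_IP(target) * E_r^Ct_input(ref) / (E_r^Ct_IP(ref) *
#' E_t^Ct_input(target))` with the two right-hand factors grouped in the
#' denominator. Note this orientation is the reciprocal of the common
#' Pfaffl-style ratio (an enriched target, i.e. lower Ct_IP(target), gives
#' a smaller value); `pfaffl_orientation = TRUE` returns the reciprocal.
#'
#' @param s a `chip_sample`.
#' @param pfaffl_orientation return the reciprocal (conventional
#'   orientation) instead of the formula as printed.
#' @return list with `estimate`, `sd` (across replicate combinations) and
#'   `assay`.
#' @export
chip_relative_level <- function(s, pfaffl_orientation = FALSE) {
  stopifnot(inherits(s, "chip_sample"))
  et <- s$efficiency[["target"]]; er <- s$efficiency[["reference"]]
  level <- function(ip_t, in_t, ip_r, in_r) {
    et^ip_t * er^in_r / (er^ip_r * et^in_t)
  }
  mu <- vapply(s$ct, mean, numeric(1))
  est <- level(mu[["ip_target"]], mu[["input_target"]],
               mu[["ip_reference"]], mu[["input_reference"]])
  combos <- expand.grid(s$ct, KEEP.OUT.ATTRS = FALSE)
  per <- level(combos$ip_target, combos$input_target,
               combos$ip_reference, combos$input_reference)
  if (pfaffl_orientation) { est <- 1 / est; per <- 1 / per }
  list(estimate = unname(est),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       assay = if (pfaffl_orientation) "chip_pfaffl" else "chip_as_printed")
}

#' Read a Ct table
#'
#' Expected columns: assay, condition (or fraction for ChIP), amplicon,
#' role ("target"/"reference"), replicate, ct, and optionally efficiency
#' (defaults to 2 where absent).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  tbl <- read_tsv_plain(path)
  need <- c("assay", "condition", "amplicon", "role", "replicate", "ct")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    stop("Ct table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(tbl$efficiency)) tbl$efficiency <- 2
  tbl$efficiency[is.na(tbl$efficiency)] <- 2
  tbl
}

#' Fold-change / relative-level report from a Ct table
#'
#' For RNA and small-RNA assays, `condition` must contain a condition and a
#' control level; for ChIP assays the two levels are the IP and input
#' fractions. One row per assay, with mean and replicate-propagated SD.
#'
#' @param tbl data.frame as from [read_ct_table()].
#' @param control label of the control condition (RNA assays).
#' @param input label of the input fraction (ChIP assays).
#' @param pfaffl_orientation passed to [chip_relative_level()].
#' @return data.frame assay, target, reference, estimate, sd, method.
#' @export
qpcr_report <- function(tbl, control = "control", input = "input",
                        pfaffl_orientation = FALSE) {
  out <- list()
  for (a in unique(tbl$assay)) {
    sub <- tbl[tbl$assay == a, ]
    tgt <- unique(sub$amplicon[sub$role == "target"])
    ref <- unique(sub$amplicon[sub$role == "reference"])
    if (length(tgt) != 1 || length(ref) != 1) {
      stop("assay ", a, " must have exactly one target and one reference")
    }
    grab <- function(role, cond) sub$ct[sub$role == role & sub$condition == cond]
    eff <- function(role) sub$efficiency[sub$role == role][1]
    conds <- unique(sub$condition)
    is_chip <- input %in% conds
    if (is_chip) {
      ip <- setdiff(conds, input)
      if (length(ip) != 1) stop("assay ", a, ": need one IP fraction")
      r <- chip_relative_level(chip_sample(
        tgt, ref, grab("target", ip), grab("target", input),
        grab("reference", ip), grab("reference", input),
        e_target = eff("target"), e_reference = eff("reference")),
        pfaffl_orientation = pfaffl_orientation)
    } else {
      cond <- setdiff(conds, control)
      if (!(control %in% conds) || length(cond) != 1) {
        stop("assay ", a, ": need one condition and the control '",
             control, "'")
      }
      r <- ddct_fold_change(qpcr_measurement(
        tgt, ref, grab("target", cond), grab("target", control),
        grab("reference", cond), grab("reference", control),
        e_target = eff("target"), e_reference = eff("reference")))
    }
    out[[a]] <- data.frame(assay = a, target = tgt, reference = ref,
                           estimate = r$estimate, sd = r$sd,
                           method = r$assay, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
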