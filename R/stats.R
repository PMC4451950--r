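#' Normality-gated two-sample comparison
#'
#' The decision procedure used throughout for pairwise comparisons of
#' replicate measurements: Shapiro-Wilk on each series at `gate_alpha`;
#' when both pass, Levene's test (classic, mean-centered) decides between
#' the pooled-variance two-tailed Student's t-test and Welch's t-test; when
#' either series is non-normal, the two-tailed Mann-Whitney rank-sum test
#' (midranks for ties; normal approximation with continuity correction for
#' larger samples, exact distribution for small tie-free samples). Series
#' too short or constant for Shapiro-Wilk fall through to Mann-Whitney with
#' a recorded warning.
#'
#' @param a,b numeric series (each of length >= 3 for the full gate).
#' @param gate_alpha alpha used for the normality/homogeneity gates.
#' @return an object of class `two_sample_test`: list with test_used
#'   ("student_t", "welch_t" or "mann_whitney"), statistic, p_value,
#'   shapiro_p (length-2), levene_p (NA unless reached), alpha, warning.
#' @export
compare_two_samples <- function(a, b, gate_alpha = 0.05) {
  stopifnot(is.numeric(a), is.numeric(b))
  warn <- NA_character_
  shap <- c(a = NA_real_, b = NA_real_)
  lev <- NA_real_

  shapiro_p <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  shap["a"] <- shapiro_p(a)
  shap["b"] <- shapiro_p(b)

  if (anyNA(shap)) {
    warn <- "Shapiro-Wilk undefined (short or constant series); falling back to Mann-Whitney"
    test_used <- "mann_whitney"
  } else if (all(shap > gate_alpha)) {
    vals <- c(a, b)
    grp <- factor(rep(c("a", "b"), c(length(a), length(b))))
    lev <- car::leveneTest(vals, grp, center = mean)[1, "Pr(>F)"]
    test_used <- if (lev > gate_alpha) "student_t" else "welch_t"
  } else {
    test_used <- "mann_whitney"
  }

  if (test_used == "mann_whitney") {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && max(length(a), length(b)) <= 8
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE))
  } else {
    ht <- stats::t.test(a, b, alternative = "two.sided",
                        var.equal = test_used == "student_t")
  }

  structure(list(test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 shapiro_p = shap,
                 levene_p = lev,
                 alpha = gate_alpha,
                 warning = warn),
            class = "two_sample_test")
}

#' @export
print.two_sample_test <- function(x, ...) {
  cat("two_sample_test:", x$test_used, " statistic =",
      signif(x$statistic, 4), " p =", signif(x$p_value, 4), "\n")
  if (!is.na(x$warning)) cat("note:", x$warning, "\n")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (with the monotone
#' envelope), validating that inputs are probabilities.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
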