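.NESTING <- list(
  standard    = c("a_priori", "ga", "synrev", "synrevcodon"),
  a_priori    = "synrevcodon",
  ga          = "synrevcodon",
  synrev      = "synrevcodon",
  synrevcodon = character(0)
)

#' Likelihood ratio test between nested MSS fits
#'
#' The statistic is `2 (logL_alt - logL_null)` and the degrees of freedom
#' equal the difference in free-parameter counts (e.g. 17 for MG94 vs
#' SynREV, 66 for MG94 vs SynREVCodon under the universal code). The
#' p-value is the chi-squared upper tail.
#'
#' @param null,alt `gene_fit` (or `joint_fit`) objects with `null` nested
#'   in `alt`.
#' @return An object of class `mss_comparison`: `lrt`, `df`, `p_value`,
#'   plus per-model AIC/BIC from [information_criteria()].
#' @export
lrt <- function(null, alt) {
  fam_n <- null$family; fam_a <- alt$family
  if (!(fam_a %in% .NESTING[[fam_n]])) {
    stop("model '", fam_n, "' is not nested in '", fam_a, "'")
  }
  df <- alt$k - null$k
  if (df <= 0) stop("alternative must have more free parameters")
  stat <- 2 * (alt$logL - null$logL)
  ic_n <- information_criteria(null)
  ic_a <- information_criteria(alt)
  structure(list(
    lrt = stat, df = df,
    p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
    aic = c(null = ic_n$aic, alt = ic_a$aic),
    bic = c(null = ic_n$bic, alt = ic_a$bic),
    n = ic_n$n, families = c(fam_n, fam_a)
  ), class = "mss_comparison")
}

#' @export
print.mss_comparison <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: stat = %.3f, df = %d, p = %.3g\n",
              x$families[1], x$families[2], x$lrt, x$df, x$p_value))
  invisible(x)
}

#' Information criteria for a fit
#'
#' `AIC = 2k - 2 logL`; `BIC = k ln(n) - 2 logL` with the sample size n
#' defined as the total number of characters: sequences x sites summed over
#' all alignments in the fit. `sites` counts codon columns by default;
#' `"nucleotides"` multiplies by 3.
#'
#' @param fit A `gene_fit` or `joint_fit`.
#' @param sites `"codons"` (default) or `"nucleotides"`.
#' @return List with `aic`, `bic`, `k`, `n`.
#' @export
information_criteria <- function(fit, sites = c("codons", "nucleotides")) {
  sites <- match.arg(sites)
  n <- fit$n * if (sites == "nucleotides") 3L else 1L
  list(aic = 2 * fit$k - 2 * fit$logL,
       bic = fit$k * log(n) - 2 * fit$logL,
       k = fit$k, n = n)
}

#' Multiple-testing adjustment of p-values
#'
#' Step-down Holm-Bonferroni (family-wise error rate) or step-up
#' Benjamini-Hochberg (false discovery rate), via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method `"holm_bonferroni"` or `"benjamini_hochberg"`.
#' @return Adjusted p-values (q-values for BH).
#' @export
adjust_pvalues <- function(p, method = c("holm_bonferroni",
                                         "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, holm_bonferroni = "holm",
                                     benjamini_hochberg = "BH"))
}
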