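#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of observed genotype counts against the
#' Hardy-Weinberg expectations `(p^2, 2pq, q^2) * n`, where `p` is the
#' estimated G-allele frequency `(2*n_GG + n_GA) / (2n)`. The statistic is
#' summed over the three genotype cells and referred to a chi-square
#' distribution with 1 degree of freedom (3 cells - 1 - 1 estimated allele
#' frequency). A monomorphic sample (`p` of 0 or 1) has nothing to test and
#' returns chi-square 0, p-value 1.
#'
#' Deviation from HWE in control arms is the standard genotyping-quality
#' flag in association meta-analysis; studies failing it are flagged by
#' [hwe_table()] but never excluded from pooling.
#'
#' @param counts A [genotype_counts()] object.
#' @return An object of class `hwe_result`: `chi_square`, `p_value`,
#'   `allele_freq_G`.
#' @examples
#' hwe_test(genotype_counts(25, 50, 25)) # exact HWE proportions
#' @export
hwe_test <- function(counts) {
  if (!inherits(counts, "genotype_counts")) {
    stop_validation("counts must be a genotype_counts object")
  }
  obs <- gt_vec(counts)
  n <- counts$total
  p <- (2 * obs[["GG"]] + obs[["GA"]]) / (2 * n)
  if (p == 0 || p == 1) {
    return(structure(list(chi_square = 0, p_value = 1, allele_freq_G = p),
                     class = "hwe_result"))
  }
  q <- 1 - p
  expected <- c(p^2, 2 * p * q, q^2) * n
  chi_square <- sum((obs - expected)^2 / expected)
  structure(
    list(chi_square = chi_square,
         p_value = stats::pchisq(chi_square, df = 1, lower.tail = FALSE),
         allele_freq_G = p),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> chi-square = %.4f (1 df), p = %.4f, freq(G) = %.3f\n",
              x$chi_square, x$p_value, x$allele_freq_G))
  invisible(x)
}

#' HWE QC table over the control arms of a collection
#'
#' @param collection A [study_collection()].
#' @param alpha Flagging level for HWE deviation (default 0.05).
#' @return A data.frame with one row per study: allele frequency,
#'   chi-square, p-value and an `hwe_ok` flag.
#' @export
hwe_table <- function(collection, alpha = 0.05) {
  if (!inherits(collection, "study_collection")) {
    stop_validation("collection must be a study_collection")
  }
  rows <- lapply(collection$studies, function(s) {
    h <- hwe_test(s$controls)
    data.frame(study = s$label, n_control = s$controls$total,
               allele_freq_G = h$allele_freq_G,
               chi_square = h$chi_square, p_value = h$p_value,
               hwe_ok = h$p_value >= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
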