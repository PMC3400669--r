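#' Genotype counts for one study arm
#'
#' Container for the three genotype counts (GG, GA, AA) of a biallelic SNP in
#' one arm (cases or controls) of a case-control study.
#'
#' @param n_GG,n_GA,n_AA Non-negative integer counts of G/G homozygotes, G/A
#'   heterozygotes and A/A homozygotes.
#' @return An object of class `genotype_counts` with fields `n_GG`, `n_GA`,
#'   `n_AA` and `total`.
#' @examples
#' genotype_counts(25, 50, 25)
#' @export
genotype_counts <- function(n_GG, n_GA, n_AA) {
  for (x in list(n_GG, n_GA, n_AA)) {
    if (!is_count(x)) stop_validation("genotype counts must be non-negative integers")
  }
  total <- n_GG + n_GA + n_AA
  if (total < 1) stop_validation("genotype counts must sum to at least 1")
  structure(
    list(n_GG = as.integer(n_GG), n_GA = as.integer(n_GA),
         n_AA = as.integer(n_AA), total = as.integer(total)),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> GG=%d GA=%d AA=%d (n=%d)\n",
              x$n_GG, x$n_GA, x$n_AA, x$total))
  invisible(x)
}

# counts as a named numeric vector in GG, GA, AA order
gt_vec <- function(x) c(GG = x$n_GG, GA = x$n_GA, AA = x$n_AA)

#' Reconstruct integer genotype counts from printed proportions
#'
#' Published study tables often report genotype frequencies as rounded
#' proportions together with the arm sample size. This reconstructs integer
#' counts that sum exactly to `n` while staying as close as possible to
#' `n * freqs`: each cell is rounded, and when the rounded cells do not sum
#' to `n` a largest-remainder repair adds or removes units from the cells
#' whose rounding moved them furthest from their exact value.
#'
#' @param n Arm sample size (positive integer).
#' @param freqs Numeric vector of three genotype proportions (GG, GA, AA).
#'   Must sum to 1 within `tol` (printed proportions are typically rounded to
#'   3 decimals, so small drifts such as 1.001 are accepted).
#' @param label Optional row label used in error messages.
#' @param tol Tolerance on `sum(freqs) - 1`; default 0.02.
#' @return A [genotype_counts()] object summing exactly to `n`.
#' @examples
#' reconstruct_counts(100, c(0.25, 0.50, 0.25))
#' reconstruct_counts(693, c(0.528, 0.398, 0.074)) # Wang 2010 control arm
#' @export
reconstruct_counts <- function(n, freqs, label = NULL, tol = 0.02) {
  who <- if (is.null(label)) "" else sprintf(" in row '%s'", label)
  if (!is_count(n) || n < 1) {
    stop_validation(sprintf("arm sample size must be a positive integer%s", who))
  }
  freqs <- as.numeric(freqs)
  if (length(freqs) != 3L || any(!is.finite(freqs)) ||
      any(freqs < 0) || any(freqs > 1)) {
    stop_validation(sprintf("freqs must be three proportions in [0,1]%s", who))
  }
  if (abs(sum(freqs) - 1) > tol) {
    stop_validation(sprintf(
      "genotype proportions sum to %.3f (outside 1 +/- %.2f)%s",
      sum(freqs), tol, who))
  }
  target <- n * freqs
  counts <- round(target)
  excess <- as.integer(sum(counts) - n)
  if (excess != 0L) {
    # repair the cells whose rounding created the largest signed deviation
    dev <- counts - target
    ord <- order(dev, decreasing = excess > 0L)
    for (i in ord[seq_len(abs(excess))]) {
      counts[i] <- counts[i] - sign(excess)
    }
  }
  if (any(counts < 0)) stop_validation(sprintf("reconstruction produced a negative count%s", who))
  genotype_counts(counts[1], counts[2], counts[3])
}
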