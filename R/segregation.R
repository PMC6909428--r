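#' Chi-square test of a Mendelian segregation ratio
#'
#' Pearson goodness-of-fit test of observed phenotype-class counts against
#' an expected segregation ratio (e.g. 3:1 wild type : mutant for a
#' monogenic recessive F2). No continuity correction is applied; for the
#' two-class case the corrected statistic would noticeably inflate p at
#' moderate counts.
#'
#' @param observed non-negative integer counts, one per class.
#' @param ratio positive expected weights, same length (e.g. `c(3, 1)`).
#' @return A `segregation_test` object: `observed`, `expected`, `ratio`,
#'   `statistic`, `df`, `p_value`.
#' @examples
#' chisq_segregation(c(221, 59), c(3, 1))
#' @export
chisq_segregation <- function(observed, ratio) {
  if (!is.numeric(observed) || any(observed < 0)) stop("counts must be >= 0")
  if (sum(observed) <= 0) stop("total count must be positive")
  if (!is.numeric(ratio) || length(ratio) != length(observed))
    stop("ratio must be numeric, same length as observed")
  if (any(ratio <= 0)) stop("ratio weights must be positive")
  p <- ratio / sum(ratio)
  expected <- sum(observed) * p
  if (any(expected == 0)) stop("an expected class count is zero")
  ht <- suppressWarnings(chisq.test(x = observed, p = p, correct = FALSE))
  structure(
    list(observed = observed, expected = as.numeric(expected), ratio = ratio,
         statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value)),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, digits = 4, ...) {
  cat("Mendelian segregation test (Pearson chi-square goodness of fit)\n")
  cat("  observed: ", paste(x$observed, collapse = " : "),
      "   expected ratio: ", paste(x$ratio, collapse = " : "), "\n", sep = "")
  cat(sprintf("  X-squared = %.*g, df = %d, p = %.*g\n",
              digits, x$statistic, x$df, digits, x$p_value))
  invisible(x)
}
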