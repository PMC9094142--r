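# Goodness-of-fit tests of phenotype segregation ratios.

#' Chi-square goodness of fit to a Mendelian ratio
#'
#' Tests observed phenotype class counts against an expected ratio (3:1 by
#' default; any positive ratio such as 15:1 or 9:7 is accepted so digenic
#' models can be tested). No continuity correction is applied by default.
#'
#' @param observed non-negative integer counts per class.
#' @param ratio positive expected ratio terms, same length as `observed`.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return an object of class `segregation_test` with fields `observed`,
#'   `expected`, `ratio`, `chi2`, `df` and `p_value`.
#' @examples
#' chi_square_gof(c(88, 32), c(3, 1))
#' @export
chi_square_gof <- function(observed, ratio = c(3, 1), correct = FALSE) {
  observed <- as.numeric(observed)
  ratio <- as.numeric(ratio)
  if (length(observed) != length(ratio))
    stopf("'observed' and 'ratio' must have the same length")
  if (any(observed < 0) || any(observed != floor(observed)))
    stopf("'observed' must be non-negative integer counts")
  if (any(ratio <= 0)) stopf("'ratio' terms must be positive")
  total <- sum(observed)
  if (total == 0) stopf("total observed count is zero")
  expected <- total * ratio / sum(ratio)
  if (any(expected < 1))
    warnf("expected count below 1 in some class; chi-square approximation is poor")
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 chi2 = chi2, df = df, p_value = p, correct = correct),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf("Segregation chi-square test (ratio %s%s)\n",
              paste(x$ratio, collapse = ":"),
              if (x$correct) ", Yates-corrected" else ""))
  cat(sprintf("  observed: %s   expected: %s\n",
              paste(x$observed, collapse = ", "),
              paste(sprintf("%.2f", x$expected), collapse = ", ")))
  cat(sprintf("  chi2 = %.4f, df = %d, p = %.4f\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.segregation_test <- function(x, ...) {
  data.frame(observed = paste(x$observed, collapse = ","),
             ratio = paste(x$ratio, collapse = ":"),
             chi2 = x$chi2, df = x$df, p_value = x$p_value,
             stringsAsFactors = FALSE)
}
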