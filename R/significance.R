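#' One-sided exact binomial site p-value
#'
#' P(X >= k | c, p0) for an observed count k (mismatches or arrest
#' starts) at coverage c under a background rate p0.
#'
#' @param k Observed count(s), 0 <= k <= c.
#' @param c Coverage(s).
#' @param p0 Background rate, 0 < p0 < 1.
#' @return Upper-tail probabilities in \[0,1\].
#' @export
site_pvalue <- function(k, c, p0) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)")
  bad <- !is.na(k) & !is.na(c) & (k < 0 | k > c)
  if (any(bad)) stop("k must satisfy 0 <= k <= c")
  stats::pbinom(k - 1, c, p0, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p*m)`) or Benjamini-Hochberg step-up FDR
#' adjustment, m being the number of tested positions; values are
#' returned in input order.
#'
#' @param p Numeric vector of raw p-values in \[0,1\].
#' @param method `"bh"` (default) or `"bonferroni"`; `"none"` returns `p`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(tolower(method[1L]),
                      c("bh", "bonferroni", "none"))
  if (length(p) == 0L) return(numeric(0))
  switch(method,
         none = p,
         bh = stats::p.adjust(p, method = "BH"),
         bonferroni = stats::p.adjust(p, method = "bonferroni"))
}
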