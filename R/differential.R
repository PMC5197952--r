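#' Pair two profiles of the same reference
#'
#' Position-wise join of two profiles (e.g. untreated versus chemically
#' treated, or wild type versus knockout) with per-position deltas.
#' Sign convention: sample 2 minus sample 1, sample 2 being the treated
#' sample.  A delta is defined only when both sample metrics are.
#'
#' @param profile1,profile2 Profile data frames covering the same
#'   reference (equal length, equal reference bases).
#' @param csa_r,csa_pseudocount CSA parameters applied to both samples.
#' @return Data frame of differential rows: `pos`, `ref`, per-sample
#'   metrics (`cov1`, `mism1`, `A1`, `CSA1`, `mm1`, ... and the same for
#'   sample 2, plus the arrest count/denominator pairs used by the
#'   Fisher test), and deltas `d_mism`, `d_A`, `d_CSA`.
#' @export
pair_profiles <- function(profile1, profile2, csa_r = 5L,
                          csa_pseudocount = 0.001) {
  n1 <- nrow(profile1); n2 <- nrow(profile2)
  if (n1 != n2) {
    stop("reference length mismatch between samples: ", n1, " vs ", n2)
  }
  if (!identical(toupper(profile1$ref_base), toupper(profile2$ref_base))) {
    stop("profiles disagree on reference bases; not the same reference")
  }
  cov_next1 <- c(profile1$coverage[-1L], NA_real_)
  cov_next2 <- c(profile2$coverage[-1L], NA_real_)
  df <- data.frame(
    pos = profile1$pos,
    ref = toupper(profile1$ref_base),
    cov1 = profile1$coverage,
    mism1 = profile1$mismatch_rate,
    A1 = profile1$arrest_rate,
    CSA1 = csa(profile1$arrest_rate, csa_r, csa_pseudocount),
    mm1 = mismatch_count(profile1),
    ak1 = as.integer(round(profile1$arrest_rate * cov_next1)),
    ac1 = cov_next1,
    cov2 = profile2$coverage,
    mism2 = profile2$mismatch_rate,
    A2 = profile2$arrest_rate,
    CSA2 = csa(profile2$arrest_rate, csa_r, csa_pseudocount),
    mm2 = mismatch_count(profile2),
    ak2 = as.integer(round(profile2$arrest_rate * cov_next2)),
    ac2 = cov_next2,
    stringsAsFactors = FALSE
  )
  df$d_mism <- df$mism2 - df$mism1
  df$d_A <- df$A2 - df$A1
  df$d_CSA <- df$CSA2 - df$CSA1
  df
}

#' Two-sided Fisher exact test on paired counts
#'
#' Per position, the 2x2 table (count, coverage - count) x (sample 1,
#' sample 2) is tested; `metric = "mismatch"` uses mismatch counts
#' against coverage, `metric = "arrest"` the arrest-start counts against
#' the downstream coverage.  Undefined (`NA`) where either sample has
#' zero coverage.
#'
#' @param diff Differential rows from [pair_profiles()].
#' @param metric `"mismatch"` (default) or `"arrest"`.
#' @return Numeric vector of two-sided p-values.
#' @export
differential_test <- function(diff, metric = c("mismatch", "arrest")) {
  metric <- match.arg(metric)
  if (metric == "mismatch") {
    k1 <- diff$mm1; c1 <- diff$cov1
    k2 <- diff$mm2; c2 <- diff$cov2
  } else {
    k1 <- diff$ak1; c1 <- diff$ac1
    k2 <- diff$ak2; c2 <- diff$ac2
  }
  n <- nrow(diff)
  p <- rep(NA_real_, n)
  ok <- which(!is.na(c1) & !is.na(c2) & c1 > 0 & c2 > 0 &
                !is.na(k1) & !is.na(k2))
  for (i in ok) {
    tab <- matrix(c(k1[i], c1[i] - k1[i], k2[i], c2[i] - k2[i]),
                  nrow = 2L)
    p[i] <- stats::fisher.test(tab)$p.value
  }
  p
}

#' Flag differential sites with a threshold formula
#'
#' Same screening engine as [call_candidates()], evaluated on
#' differential rows: formulas may use `d_mism`, `d_A`, `d_CSA` and the
#' per-sample variables, e.g.
#' `"d_mism <= -0.2 AND cov1 >= 20 AND cov2 >= 20"` for a
#' deamination-style signature loss.  Raw-threshold screening is the
#' default; `test = "fisher"` attaches per-position Fisher p-values with
#' multiple-testing correction over the gated positions.
#'
#' @param diff Differential rows from [pair_profiles()].
#' @param formula Formula text or parsed `rtsig_formula`.
#' @param min_coverage Both samples must reach this coverage (default 20).
#' @param test `"none"` (default) or `"fisher"`.
#' @param metric Metric for the Fisher test (default `"mismatch"`).
#' @param method Correction for the Fisher p-values (default `"bh"`).
#' @param ref_index Reference number recorded in the output.
#' @return Data frame of flagged differential rows with `p_raw`, `p_adj`
#'   and `passed` columns.
#' @export
flag_differential_sites <- function(diff, formula, min_coverage = 20,
                                    test = c("none", "fisher"),
                                    metric = c("mismatch", "arrest"),
                                    method = c("bh", "bonferroni", "none"),
                                    ref_index = 1L) {
  test <- match.arg(test)
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (is.character(formula)) formula <- parse_formula(formula)

  diff <- diff[order(diff$pos), , drop = FALSE]
  gated <- diff[diff$cov1 >= min_coverage & diff$cov2 >= min_coverage, ,
                drop = FALSE]
  if (test == "fisher") {
    gated$p <- differential_test(gated, metric)
    gated$p_adj <- adjust_pvalues(gated$p, method)
  } else {
    gated$p <- NA_real_
    gated$p_adj <- NA_real_
  }
  pass <- evaluate_formula(formula, gated)
  out <- gated[pass, , drop = FALSE]
  names(out)[names(out) == "p"] <- "p_raw"
  out$passed <- rep(TRUE, nrow(out))
  out <- cbind(ref_index = rep(as.integer(ref_index), nrow(out)), out)
  rownames(out) <- NULL
  out
}
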