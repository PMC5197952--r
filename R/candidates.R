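`%||%` <- function(a, b) if (is.null(a)) b else a

# Metric snapshot exposing every single-profile formula variable.
profile_snapshot <- function(profile, csa_r = 5L, csa_pseudocount = 0.001) {
  cov <- profile$coverage
  f <- function(x) ifelse(cov > 0, x / cov, NA_real_)
  data.frame(
    pos = profile$pos,
    ref = toupper(profile$ref_base),
    cov = cov,
    mism = profile$mismatch_rate,
    A = profile$arrest_rate,
    CSA = csa(profile$arrest_rate, r = csa_r,
              pseudocount = csa_pseudocount),
    fA = f(profile$n_A), fC = f(profile$n_C),
    fG = f(profile$n_G), fT = f(profile$n_T),
    nA = profile$n_A, nC = profile$n_C,
    nG = profile$n_G, nT = profile$n_T,
    stringsAsFactors = FALSE
  )
}

# Background rate default: genome-wide median of the metric's rate over
# the tested positions, floored at 0.001 so the binomial null is defined
# on clean data.
.default_p0 <- function(rate) {
  max(stats::median(rate, na.rm = TRUE), 0.001, na.rm = TRUE)
}

# Median arrest rate of each position's +-r neighbourhood (focal
# position excluded, NA treated as 0) -- the same context window CSA
# uses.
.local_median <- function(x, r = 5L) {
  n <- length(x)
  a <- ifelse(is.na(x), 0, x)
  vapply(seq_len(n), function(i) stats::median(a[csa_window(i, n, r)]),
         numeric(1))
}

# Per-position binomial p-values for one metric over a gated snapshot.
# The mismatch null is a single background rate (default: genome-wide
# median mismatch rate).  The arrest null is context-sensitive by
# default: each position is tested against the median arrest rate of
# its +-r neighbourhood (floored at the genome-wide median), because
# the raw arrest rate is structurally elevated near reference 5' ends,
# where every covering read started nearby -- the same artifact the CSA
# normalisation addresses.
.metric_pvalues <- function(profile, tested, metric, p0, csa_r = 5L) {
  if (metric == "mismatch") {
    k <- mismatch_count(profile)[tested]
    cc <- profile$coverage[tested]
  } else {
    cov_next <- c(profile$coverage[-1L], NA_real_)
    k <- as.integer(round(profile$arrest_rate * cov_next))[tested]
    cc <- cov_next[tested]
  }
  ok <- !is.na(k) & !is.na(cc) & cc > 0
  if (is.null(p0)) {
    floor0 <- .default_p0((k / cc)[ok])
    p0 <- if (metric == "arrest") {
      pmax(.local_median(profile$arrest_rate, csa_r)[tested], floor0)
    } else {
      floor0
    }
  }
  if (length(p0) > 1L) p0 <- p0[ok]
  p <- rep(NA_real_, length(k))
  p[ok] <- site_pvalue(k[ok], cc[ok], p0)
  p
}

#' Screen a profile for modification candidates
#'
#' Positions passing a minimum-coverage gate are tested; each gets a raw
#' site p-value (exact binomial tail of its mismatch and/or arrest count
#' against a background rate) and an adjusted p-value with m equal to the
#' number of tested positions.  The user formula is then evaluated over
#' the metric snapshot — `p` and `p_adj` are available as formula
#' variables, so `"p_adj <= 0.05 AND mism >= 0.1"` works — and one
#' candidate record is emitted per passing position.
#'
#' @param profile Profile data frame (positions 1..n).
#' @param formula Formula text or parsed `rtsig_formula`.
#' @param min_coverage Coverage gate; only positions with coverage at
#'   least this are tested (default 20).
#' @param sig_metric Which count the site test uses: `"mismatch"`
#'   (default), `"arrest"`, `"both"` (the two tests combined per site by
#'   Bonferroni: `p = min(1, 2 * min(p_mism, p_arrest))`), or `"none"`
#'   (pure threshold screening; `p`/`p_adj` are `NA`).
#' @param p0 Background rate of the binomial null.  Default for the
#'   mismatch test: the genome-wide median mismatch rate over tested
#'   positions (floored at 0.001).  Default for the arrest test: the
#'   median arrest rate of each position's own +-`csa_r` neighbourhood,
#'   floored at the genome-wide median — a context-sensitive null that
#'   keeps the structurally elevated arrest rates near reference 5'
#'   ends (where every covering read started nearby) from being called.
#'   For `sig_metric = "both"` a list `list(mismatch =, arrest =)` is
#'   accepted.
#' @param method Multiple-testing correction: `"bh"` (default),
#'   `"bonferroni"` or `"none"`.
#' @param csa_r,csa_pseudocount CSA parameters (defaults 5 and 0.001).
#' @param ref_index Reference number recorded in the output (default 1).
#' @return Data frame of candidate records, sorted by position: the full
#'   metric snapshot plus `p_raw`, `p_adj` and `passed` (always `TRUE`).
#' @export
call_candidates <- function(profile, formula, min_coverage = 20,
                            sig_metric = c("mismatch", "arrest", "both",
                                           "none"),
                            p0 = NULL,
                            method = c("bh", "bonferroni", "none"),
                            csa_r = 5L, csa_pseudocount = 0.001,
                            ref_index = 1L) {
  sig_metric <- match.arg(sig_metric)
  method <- match.arg(method)
  if (is.character(formula)) formula <- parse_formula(formula)
  used <- formula_ast_variables(formula)
  dv <- intersect(used, .differential_only_variables())
  if (length(dv) > 0L) {
    stop("differential formula variable(s) on a single profile: ",
         paste(dv, collapse = ", "),
         "; use flag_differential_sites() for paired samples")
  }

  profile <- profile[order(profile$pos), , drop = FALSE]
  snap <- profile_snapshot(profile, csa_r, csa_pseudocount)
  tested <- which(snap$cov >= min_coverage)
  snap <- snap[tested, , drop = FALSE]

  if (sig_metric == "none" || length(tested) == 0L) {
    p_raw <- rep(NA_real_, length(tested))
  } else if (sig_metric == "both") {
    p0m <- if (is.list(p0)) p0$mismatch else p0
    p0a <- if (is.list(p0)) p0$arrest else p0
    pm <- .metric_pvalues(profile, tested, "mismatch", p0m, csa_r)
    pa <- .metric_pvalues(profile, tested, "arrest", p0a, csa_r)
    pmat <- cbind(pm, pa)
    k_tests <- rowSums(!is.na(pmat))
    p_raw <- ifelse(k_tests == 0L, NA_real_,
                    pmin(1, k_tests * apply(pmat, 1L, min, na.rm = TRUE)))
  } else {
    p_raw <- .metric_pvalues(profile, tested, sig_metric,
                             if (is.list(p0)) p0[[sig_metric]] else p0,
                             csa_r)
  }

  snap$p <- p_raw
  snap$p_adj <- if (sig_metric == "none") p_raw else
    adjust_pvalues(p_raw, method)

  pass <- evaluate_formula(formula, snap)
  out <- snap[pass, , drop = FALSE]
  names(out)[names(out) == "p"] <- "p_raw"
  out$passed <- rep(TRUE, nrow(out))
  out <- cbind(ref_index = rep(as.integer(ref_index), nrow(out)), out)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate records to a TSV file
#'
#' Always writes the header line, also for an empty candidate set; the
#' file is accepted back by [plot_candidate_batch()].
#'
#' @param candidates Candidate data frame from [call_candidates()] or
#'   [flag_differential_sites()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidates TSV file
#'
#' @param path Path written by [write_candidates()].
#' @return Candidate data frame.
#' @export
read_candidates <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
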