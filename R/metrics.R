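#' Arrest rate from downstream read starts
#'
#' The arrest rate of position i is the quotient of read starts
#' (pileup circumflexes) at i+1 and coverage at i+1: a reverse
#' transcriptase that stalls at a modified nucleotide i releases a cDNA
#' whose 5' end maps to i+1.
#'
#' @param n_start_next Read-start counts at position i+1 (vectorised).
#' @param coverage_next Coverage at position i+1.
#' @return Fractions in \[0,1\]; `NA` where coverage is 0.
#' @export
arrest_rate <- function(n_start_next, coverage_next) {
  if (any(n_start_next < 0, na.rm = TRUE) ||
      any(coverage_next < 0, na.rm = TRUE)) {
    stop("negative counts passed to arrest_rate()")
  }
  out <- n_start_next / coverage_next
  out[!is.na(coverage_next) & coverage_next == 0] <- NA_real_
  out
}

#' Mismatch rate at a position
#'
#' M = (number of base calls differing from the reference base, over
#' A/C/G/T only) / coverage.  Deletions and N calls are not mismatches.
#' Undefined (`NA`) when coverage is 0 or the reference base is N.
#'
#' @param n_A,n_C,n_G,n_T Observed base-call counts (matches included).
#' @param coverage Total depth at the position.
#' @param ref_base Reference base, one of A/C/G/T/N.
#' @return Fractions in \[0,1\] or `NA`.
#' @export
mismatch_rate <- function(n_A, n_C, n_G, n_T, coverage, ref_base) {
  counts <- cbind(A = n_A, C = n_C, G = n_G, T = n_T)
  total <- rowSums(counts)
  ref_base <- toupper(ref_base)
  ri <- match(ref_base, colnames(counts))
  n_ref <- ifelse(is.na(ri), 0, counts[cbind(seq_along(ri), ri)])
  mm <- total - n_ref
  out <- mm / coverage
  out[coverage == 0 | !(ref_base %in% c("A", "C", "G", "T"))] <- NA_real_
  out
}

# Mismatch counts (non-reference A/C/G/T calls) for a profile data frame.
mismatch_count <- function(profile) {
  counts <- cbind(A = profile$n_A, C = profile$n_C,
                  G = profile$n_G, T = profile$n_T)
  ri <- match(toupper(profile$ref_base), colnames(counts))
  n_ref <- ifelse(is.na(ri), 0L, counts[cbind(seq_len(nrow(counts)), ri)])
  as.integer(rowSums(counts) - n_ref)
}

#' Neighbourhood indices of the CSA window
#'
#' Up to r positions on each side of i, i itself excluded, truncated at
#' the sequence ends (2r = 10 neighbours at interior sites for the
#' default r = 5).
#'
#' @param i Position of interest (1-based).
#' @param n Sequence length.
#' @param r Window radius (default 5).
#' @return Integer vector of neighbour indices.
#' @export
csa_window <- function(i, n, r = 5L) {
  w <- max(1L, i - r):min(n, i + r)
  w[w != i]
}

#' Context-sensitive arrest rate (CSA)
#'
#' CSA_r(i) is the fold change of the arrest rate at i over the median
#' arrest rate of its sequence environment of r bases up- and r bases
#' downstream (i excluded).  A pseudocount p is added to numerator and
#' denominator, so flat profiles always give CSA = 1 and zero-median
#' windows stay finite: CSA = (A_i + p) / (median(window) + p).
#' Undefined arrest values (`NA`) are treated as 0.
#'
#' @param arrest Numeric vector of per-position arrest rates.
#' @param r Window radius (default 5).
#' @param pseudocount Pseudocount p (default 0.001; p = 0 recovers the
#'   literal fold change, infinite or undefined over zero-median windows).
#' @return Numeric vector of CSA values; `NA` for a length-1 profile.
#' @export
csa <- function(arrest, r = 5L, pseudocount = 0.001) {
  n <- length(arrest)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(NA_real_)
  a <- ifelse(is.na(arrest), 0, arrest)
  out <- numeric(n)
  for (i in seq_len(n)) {
    med <- stats::median(a[csa_window(i, n, r)])
    out[i] <- (a[i] + pseudocount) / (med + pseudocount)
  }
  out
}

#' Append a CSA column to a profile
#'
#' @param profile Profile data frame (see [profile_from_columns()]).
#' @param r,pseudocount Passed to [csa()].
#' @return The profile with a `csa` column added.
#' @export
add_csa <- function(profile, r = 5L, pseudocount = 0.001) {
  profile$csa <- csa(profile$arrest_rate, r = r, pseudocount = pseudocount)
  profile
}

# Per-row logical: does the position qualify as a heterogeneous-mismatch
# site?  Gate: coverage >= min_coverage and reference base in A/C/G/T;
# then the median of the three non-reference base frequencies must reach
# min_rate, i.e. two or more mismatch types at >= min_rate.
is_heterogeneous_site <- function(profile, min_coverage = 20,
                                  min_rate = 0.1) {
  n <- nrow(profile)
  out <- logical(n)
  counts <- cbind(A = profile$n_A, C = profile$n_C,
                  G = profile$n_G, T = profile$n_T)
  ref <- toupper(profile$ref_base)
  idx <- which(profile$coverage >= min_coverage &
                 ref %in% c("A", "C", "G", "T"))
  for (i in idx) {
    mf <- counts[i, setdiff(c("A", "C", "G", "T"), ref[i])] /
      profile$coverage[i]
    out[i] <- stats::median(mf) >= min_rate
  }
  out
}

#' Count heterogeneous-mismatch sites (S_H)
#'
#' A position contributes if its coverage is at least `min_coverage`
#' (default 20) and the median of its three mismatch-type frequencies
#' (non-reference base calls over coverage) is at least `min_rate`
#' (default 0.1) — equivalently, two or more mismatch types each reach
#' the minimum rate.  Positions with reference base N never count.
#'
#' @param profile Profile data frame.
#' @param min_coverage Coverage gate (default 20 reads).
#' @param min_rate Minimum mismatch-type frequency (default 0.1).
#' @return Integer count S_H.
#' @export
heterogeneous_sites <- function(profile, min_coverage = 20, min_rate = 0.1) {
  sum(is_heterogeneous_site(profile, min_coverage, min_rate))
}

# Logical vector behind high_rate_sites().
is_high_rate_site <- function(profile, which = c("arrest", "mismatch"),
                              p0 = 0.05, alpha = 0.001,
                              mode = c("binomial", "threshold"),
                              threshold = 0.1) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  n <- nrow(profile)
  if (which == "mismatch") {
    k <- mismatch_count(profile)
    cc <- profile$coverage
  } else {
    cov_next <- c(profile$coverage[-1L], NA_real_)
    k <- as.integer(round(profile$arrest_rate * cov_next))
    cc <- cov_next
  }
  ok <- !is.na(k) & !is.na(cc) & cc > 0
  out <- logical(n)
  if (mode == "binomial") {
    out[ok] <- k[ok] > 0 &
      stats::pbinom(k[ok] - 1, cc[ok], p0, lower.tail = FALSE) <= alpha
  } else {
    out[ok] <- (k[ok] / cc[ok]) >= threshold
  }
  out
}

#' Count high-arrest (S_A) or high-mismatch (S_M) sites
#'
#' A coverage-normalised threshold: a position counts when the one-sided
#' exact binomial tail P(X >= k | c, p0) is at most `alpha`, with k the
#' arrest-start or mismatch count and c the relevant coverage (coverage at
#' i+1 for arrest).  Low rates are insignificant at low coverage but
#' captured when coverage is high.  A flat rate threshold is available as
#' `mode = "threshold"`.
#'
#' @param profile Profile data frame.
#' @param which `"arrest"` (S_A) or `"mismatch"` (S_M).
#' @param p0 Background rate of the binomial null (default 0.05).
#' @param alpha Tail-probability cutoff (default 0.001).
#' @param mode `"binomial"` (default) or `"threshold"`.
#' @param threshold Flat rate cutoff used by `mode = "threshold"`.
#' @return Integer site count.
#' @export
high_rate_sites <- function(profile, which = c("arrest", "mismatch"),
                            p0 = 0.05, alpha = 0.001,
                            mode = c("binomial", "threshold"),
                            threshold = 0.1) {
  sum(is_high_rate_site(profile, which, p0, alpha, mode, threshold))
}

#' Per-reference summary statistics
#'
#' One row of the reference summary table: ID, file path, length, the
#' first 100 nt of sequence, coverage peak, S_A, S_M, S_H and the number
#' of mapped reads.
#'
#' @param profile Profile data frame for the reference.
#' @param id Reference (FASTA) ID.
#' @param path File path recorded in the table (default `""`).
#' @param sequence Reference sequence (character; optional — the head is
#'   reconstructed from profile reference bases when missing).
#' @param mapped_reads Number of primary mapped reads (default 0).
#' @param ... Passed on to [high_rate_sites()] (`p0`, `alpha`, ...).
#' @return One-row data frame with columns `id`, `path`, `length`,
#'   `sequence_head`, `coverage_peak`, `S_A`, `S_M`, `S_H`,
#'   `mapped_reads`.
#' @export
reference_summary <- function(profile, id, path = "", sequence = NULL,
                              mapped_reads = 0L, ...) {
  if (is.null(sequence)) {
    sequence <- paste0(profile$ref_base, collapse = "")
  }
  data.frame(
    id = id,
    path = path,
    length = nrow(profile),
    sequence_head = substr(sequence, 1L, 100L),
    coverage_peak = if (nrow(profile)) max(profile$coverage) else 0L,
    S_A = high_rate_sites(profile, "arrest", ...),
    S_M = high_rate_sites(profile, "mismatch", ...),
    S_H = heterogeneous_sites(profile),
    mapped_reads = mapped_reads,
    stringsAsFactors = FALSE
  )
}
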