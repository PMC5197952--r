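.BASES <- c("A", "C", "G", "T")

#' Specify a planted-signature read simulation
#'
#' The simulator emulates an abortive-cDNA RNA-Seq experiment: uniformly
#' placed forward-strand reads over a random reference, an i.i.d.
#' per-base sequencing-error rate, and planted modification sites that
#' carry (a) an elevated mismatch fraction with a chosen miscall base and
#' (b) an elevated read-start fraction at the position downstream —
#' reads crossing into pos+1 are truncated so their leftmost aligned
#' base is pos+1, which is exactly what the arrest-rate estimator
#' (starts at i+1 over coverage at i+1) measures.
#'
#' @param reference_length Reference length(s) in nt (recycled over
#'   `n_references`; default 10000).
#' @param n_references Number of reference sequences (default 1).
#' @param coverage Target mean depth (default 500).
#' @param read_length Read length in nt (default 50).
#' @param error_rate Per-base miscall probability (default 0.005).
#' @param sites Data frame of planted sites with columns `pos`,
#'   `mismatch_fraction`, `arrest_fraction` and optionally `ref` (target
#'   reference, default 1), `mismatch_to` (miscalled base; `NA` draws a
#'   uniform non-reference base) and `label`.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   SAM output.
#' @return An object of class `rtsig_sim_spec`.
#' @export
simulation_spec <- function(reference_length = 10000L, n_references = 1L,
                            coverage = 500, read_length = 50L,
                            error_rate = 0.005, sites = NULL,
                            seed = 1L) {
  if (is.null(sites)) {
    sites <- data.frame(pos = integer(), mismatch_fraction = numeric(),
                        arrest_fraction = numeric(),
                        stringsAsFactors = FALSE)
  }
  if (!("ref" %in% names(sites))) sites$ref <- rep(1L, nrow(sites))
  if (!("mismatch_to" %in% names(sites))) {
    sites$mismatch_to <- rep(NA_character_, nrow(sites))
  }
  if (!("label" %in% names(sites))) {
    sites$label <- rep("site", nrow(sites))
  }
  if (anyDuplicated(sites[c("ref", "pos")])) {
    stop("planted sites must be unique by position")
  }
  lens <- as.integer(rep_len(reference_length, n_references))
  if (any(lens < read_length)) {
    stop("reference length must be at least the read length")
  }
  structure(list(reference_length = lens, n_references = n_references,
                 coverage = coverage, read_length = as.integer(read_length),
                 error_rate = error_rate, sites = sites,
                 seed = as.integer(seed)),
            class = "rtsig_sim_spec")
}

#' Generate random reference sequences
#'
#' Uniform i.i.d. sequences over A/C/G/T, seeded from the spec.
#'
#' @param spec An `rtsig_sim_spec`.
#' @return A [Biostrings::DNAStringSet] named `ref_1`, `ref_2`, ...
#' @export
generate_reference <- function(spec) {
  seqs <- withr::with_seed(spec$seed, {
    vapply(spec$reference_length, function(L) {
      paste0(sample(.BASES, L, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("ref_", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# Simulate reads for one reference; returns starts, lens, seqs.
.simulate_one <- function(L, refchars, coverage, rl, error_rate, sites) {
  n_reads <- max(1L, as.integer(round(coverage * L / rl)))
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  lens <- rep.int(rl, n_reads)

  # arrest: truncate crossing reads so they start at pos + 1
  for (s in seq_len(nrow(sites))) {
    af <- sites$arrest_fraction[s]
    if (is.na(af) || af <= 0) next
    pos <- sites$pos[s]
    if (pos + 1L > L) stop("arrest site beyond reference: ", pos)
    cross <- which(starts <= pos & starts + lens - 1L >= pos + 1L)
    hit <- cross[stats::runif(length(cross)) < af]
    lens[hit] <- lens[hit] - (pos + 1L - starts[hit])
    starts[hit] <- pos + 1L
  }
  o <- order(starts)
  starts <- starts[o]; lens <- lens[o]

  idx <- sequence(lens, from = starts)
  chars <- refchars[idx]

  # background sequencing errors
  if (error_rate > 0) {
    err <- which(stats::runif(length(chars)) < error_rate)
    if (length(err) > 0L) {
      shift <- sample.int(3L, length(err), replace = TRUE)
      chars[err] <- .BASES[((match(chars[err], .BASES) - 1L + shift) %% 4L)
                           + 1L]
    }
  }

  # planted mismatches
  cum <- cumsum(c(0L, lens))
  for (s in seq_len(nrow(sites))) {
    mf <- sites$mismatch_fraction[s]
    if (is.na(mf) || mf <= 0) next
    pos <- sites$pos[s]
    if (pos > L) stop("mismatch site beyond reference: ", pos)
    covering <- which(starts <= pos & starts + lens - 1L >= pos)
    mis <- covering[stats::runif(length(covering)) < mf]
    if (length(mis) == 0L) next
    ci <- cum[mis] + (pos - starts[mis] + 1L)
    to <- sites$mismatch_to[s]
    if (is.na(to)) {
      alt <- setdiff(.BASES, refchars[pos])
      chars[ci] <- alt[sample.int(length(alt), length(ci), replace = TRUE)]
    } else {
      chars[ci] <- to
    }
  }

  big <- paste0(chars, collapse = "")
  seqs <- substring(big, cum[-length(cum)] + 1L, cum[-1L])
  list(starts = starts, lens = lens, seqs = seqs, n_reads = n_reads)
}

#' Simulate reads with planted RT signatures
#'
#' Writes a valid, position-sorted SAM file (with header) and a truth
#' table of the planted sites.  Deterministic: identical spec and seed
#' give byte-identical SAM output.
#'
#' @param spec An `rtsig_sim_spec`.
#' @param reference References from [generate_reference()] (a
#'   `DNAStringSet` or named character vector).
#' @param sam_path Output SAM path.
#' @param truth_path Optional output path for the truth TSV
#'   (`ref`, `pos`, `mismatch_fraction`, `arrest_fraction`, `label`).
#' @return Invisibly, a list with `sam`, `truth` (data frame) and
#'   `n_reads` (per-reference read counts).
#' @export
simulate_reads <- function(spec, reference, sam_path, truth_path = NULL) {
  refseqs <- as.character(reference)
  refnames <- names(refseqs)
  if (is.null(refnames)) refnames <- paste0("ref_", seq_along(refseqs))
  bad <- spec$sites$ref < 1L | spec$sites$ref > length(refseqs)
  if (any(bad)) stop("planted site on unknown reference index")

  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", refnames, nchar(refseqs)))
  n_reads <- integer(length(refseqs))

  withr::with_seed(spec$seed + 1L, {
    for (r in seq_along(refseqs)) {
      L <- nchar(refseqs[r])
      refchars <- strsplit(refseqs[r], "", fixed = TRUE)[[1L]]
      sites <- spec$sites[spec$sites$ref == r, , drop = FALSE]
      if (any(sites$pos > L)) {
        stop("planted site beyond reference ", refnames[r])
      }
      sim <- .simulate_one(L, refchars, spec$coverage, spec$read_length,
                           spec$error_rate, sites)
      n_reads[r] <- sim$n_reads
      lines <- c(lines, sprintf(
        "%s_read_%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
        refnames[r], seq_along(sim$starts), refnames[r], sim$starts,
        sim$lens, sim$seqs, strrep("I", sim$lens)))
    }
  })

  con <- file(sam_path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)

  truth <- spec$sites[, c("ref", "pos", "mismatch_fraction",
                          "arrest_fraction", "label")]
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(sam = sam_path, truth = truth, n_reads = n_reads))
}

#' Write references to a FASTA file
#'
#' @param reference A `DNAStringSet` (or named character vector).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(reference, path) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}
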