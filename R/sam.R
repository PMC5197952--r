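#' Read a SAM file into an alignment table
#'
#' Parses the mandatory 11 columns of SAM text (header lines are skipped)
#' into a data frame of aligned-read views.  No alignment is performed;
#' reads are expected to be mapped already.
#'
#' @param path Path to a SAM text file.
#' @return A data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`, one row per alignment line.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(ln, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) {
    stop("malformed SAM line ", which(nf < 11L)[1L], ": fewer than 11 fields")
  }
  fld <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(
    qname = fld(1L),
    flag  = as.integer(fld(2L)),
    rname = fld(3L),
    pos   = as.integer(fld(4L)),
    mapq  = as.integer(fld(5L)),
    cigar = fld(6L),
    seq   = fld(10L),
    qual  = fld(11L),
    stringsAsFactors = FALSE
  )
}

.is_mapped <- function(flag) bitwAnd(flag, 4L) == 0L
.is_primary <- function(flag) {
  bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
}
.is_reverse <- function(flag) bitwAnd(flag, 16L) != 0L

#' Count primary mapped alignments to one reference
#'
#' Secondary (0x100) and supplementary (0x800) alignments and reads with
#' the unmapped flag (0x4) are excluded.
#'
#' @param reads Alignment table as returned by [read_sam()].
#' @param reference_id Reference sequence name to count against.
#' @return Integer count of primary mapped alignments.
#' @export
count_mapped_reads <- function(reads, reference_id) {
  if (nrow(reads) == 0L) return(0L)
  sum(reads$rname == reference_id & .is_mapped(reads$flag) &
        .is_primary(reads$flag))
}

# Parse a CIGAR string into op/length vectors; errors identify the read.
parse_cigar <- function(cigar, qname = "?") {
  if (is.na(cigar) || cigar == "*" || cigar == "") {
    stop("malformed CIGAR for read ", qname, ": '", cigar, "'")
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop("malformed CIGAR for read ", qname, ": '", cigar, "'")
  }
  list(op  = sub("^[0-9]+", "", toks),
       len = as.integer(sub("[MIDNSHP=X]$", "", toks)))
}
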