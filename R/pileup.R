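#' Build a per-position pileup from mapped reads
#'
#' Walks the CIGAR of every primary mapped alignment against one reference
#' and tallies, for each reference position 1..n: observed base calls
#' (`n_A`, `n_C`, `n_G`, `n_T`), deletions (`n_del`), read starts
#' (`n_start`, the pileup circumflexes: one per read at its leftmost
#' aligned base), read ends (`n_end`) and total depth.  Insertions and
#' soft/hard clips contribute to no column; `D` ops count as deletions and
#' depth; `N` (reference skip) ops count toward neither.  `N` base calls
#' count toward depth only.
#'
#' @param reads Alignment table from [read_sam()] (or any data frame with
#'   columns `qname`, `flag`, `rname`, `pos`, `cigar`, `seq`, `qual`).
#' @param reference_id Name of the reference to pile up.
#' @param reference_seq Reference sequence as a single character string.
#' @param min_base_quality Minimum Phred base quality for a base call to be
#'   tallied (default 0, i.e. no filtering).  Filtered calls are excluded
#'   from both the base tallies and depth; read starts/ends still count.
#' @param start_policy How read starts are counted: `"leftmost"` (default;
#'   every read once at its leftmost aligned base, strand-agnostic, exactly
#'   as pileup `^` marks), `"forward-strand"` (only forward-strand reads)
#'   or `"rightmost"` (use the rightmost aligned base, for library
#'   protocols with opposite read orientation).
#' @return A data frame of pileup columns with one row per reference
#'   position: `reference_id`, `pos`, `ref_base`, `depth`, `n_A`, `n_C`,
#'   `n_G`, `n_T`, `n_del`, `n_start`, `n_end`.
#' @export
pileup_from_sam <- function(reads, reference_id, reference_seq,
                            min_base_quality = 0,
                            start_policy = c("leftmost", "forward-strand",
                                             "rightmost")) {
  start_policy <- match.arg(start_policy)
  n <- nchar(reference_seq)
  refchars <- strsplit(toupper(reference_seq), "", fixed = TRUE)[[1L]]

  keep <- reads$rname == reference_id & .is_mapped(reads$flag) &
    .is_primary(reads$flag)
  reads <- reads[keep, , drop = FALSE]

  call_pos <- integer(0)   # reference position of each base call
  call_chr <- character(0) # the called base
  call_q   <- integer(0)   # its Phred quality
  del_pos  <- integer(0)
  starts   <- integer(0)
  ends     <- integer(0)
  start_rev <- logical(0)  # strand of the read owning each start/end

  if (nrow(reads) > 0L) {
    pure <- grepl("^[0-9]+M$", reads$cigar)

    # --- fast path: ungapped all-match CIGARs, fully vectorised ---------
    if (any(pure)) {
      p <- reads[pure, , drop = FALSE]
      len <- as.integer(sub("M$", "", p$cigar))
      bad_len <- len != nchar(p$seq)
      if (any(bad_len)) {
        stop("malformed CIGAR for read ", p$qname[which(bad_len)[1L]],
             ": query length does not match CIGAR")
      }
      over <- p$pos + len - 1L > n | p$pos < 1L
      if (any(over)) {
        warning(sum(over), " read(s) extend past the reference end of ",
                reference_id, "; skipped (first: ", p$qname[which(over)[1L]],
                ")")
        p <- p[!over, , drop = FALSE]
        len <- len[!over]
      }
      if (nrow(p) > 0L) {
        idx <- sequence(len, from = p$pos)
        chr <- unlist(strsplit(toupper(p$seq), "", fixed = TRUE),
                      use.names = FALSE)
        if (min_base_quality > 0) {
          qv <- as.integer(charToRaw(paste0(p$qual, collapse = ""))) - 33L
        } else {
          qv <- rep.int(93L, length(idx))
        }
        call_pos <- c(call_pos, idx)
        call_chr <- c(call_chr, chr)
        call_q   <- c(call_q, qv)
        starts   <- c(starts, p$pos)
        ends     <- c(ends, p$pos + len - 1L)
        start_rev <- c(start_rev, .is_reverse(p$flag))
      }
    }

    # --- general path: full CIGAR walk per read -------------------------
    gen <- which(!pure)
    for (i in gen) {
      cig <- parse_cigar(reads$cigar[i], reads$qname[i])
      qlen <- sum(cig$len[cig$op %in% c("M", "=", "X", "I", "S")])
      if (qlen != nchar(reads$seq[i])) {
        stop("malformed CIGAR for read ", reads$qname[i],
             ": query length does not match CIGAR")
      }
      ref_len <- sum(cig$len[cig$op %in% c("M", "=", "X", "D", "N")])
      rp <- reads$pos[i]
      if (rp < 1L || rp + ref_len - 1L > n) {
        warning("read ", reads$qname[i],
                " extends past the reference end of ", reference_id,
                "; skipped")
        next
      }
      qchars <- strsplit(toupper(reads$seq[i]), "", fixed = TRUE)[[1L]]
      if (min_base_quality > 0) {
        qquals <- as.integer(charToRaw(reads$qual[i])) - 33L
      } else {
        qquals <- rep.int(93L, qlen)
      }
      qp <- 1L
      for (j in seq_along(cig$op)) {
        o <- cig$op[j]; l <- cig$len[j]
        if (o %in% c("M", "=", "X")) {
          call_pos <- c(call_pos, rp:(rp + l - 1L))
          call_chr <- c(call_chr, qchars[qp:(qp + l - 1L)])
          call_q   <- c(call_q, qquals[qp:(qp + l - 1L)])
          rp <- rp + l; qp <- qp + l
        } else if (o == "I" || o == "S") {
          qp <- qp + l
        } else if (o == "D") {
          del_pos <- c(del_pos, rp:(rp + l - 1L))
          rp <- rp + l
        } else if (o == "N") {
          rp <- rp + l
        } # H, P: consume nothing
      }
      starts <- c(starts, reads$pos[i])
      ends <- c(ends, reads$pos[i] + ref_len - 1L)
      start_rev <- c(start_rev, .is_reverse(reads$flag[i]))
    }
  }

  if (min_base_quality > 0) {
    ok <- call_q >= min_base_quality
    call_pos <- call_pos[ok]
    call_chr <- call_chr[ok]
  }

  start_at <- switch(start_policy,
    "leftmost" = starts,
    "forward-strand" = starts[!start_rev],
    "rightmost" = ends)

  tab <- function(x) tabulate(x, nbins = n)
  data.frame(
    reference_id = rep.int(reference_id, n),
    pos = seq_len(n),
    ref_base = refchars,
    depth = tab(call_pos) + tab(del_pos),
    n_A = tab(call_pos[call_chr == "A"]),
    n_C = tab(call_pos[call_chr == "C"]),
    n_G = tab(call_pos[call_chr == "G"]),
    n_T = tab(call_pos[call_chr == "T"]),
    n_del = tab(del_pos),
    n_start = tab(start_at),
    n_end = tab(ends),
    stringsAsFactors = FALSE
  )
}

#' Parse one line of samtools pileup text
#'
#' Understands the 6-column samtools pileup dialect: `.`/`,` are matches
#' (counted toward the reference base), upper/lowercase `ACGT` are
#' mismatches on the forward/reverse strand, `*` is a deletion, `^X` marks
#' a read start (the following mapping-quality character is consumed),
#' `$` marks a read end, and `+n`/`-n` insertion/deletion blobs are
#' skipped without contributing calls.
#'
#' @param line One pileup text line (tab-separated).
#' @param line_number Optional line number used in error messages.
#' @return A one-row data frame in the same shape as [pileup_from_sam()].
#' @export
parse_pileup_line <- function(line, line_number = NA) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  where <- if (is.na(line_number)) "" else paste0(" (line ", line_number, ")")
  if (length(f) < 5L) {
    # depth-0 lines may legitimately have no base/quality columns
    if (length(f) >= 4L && as.integer(f[4L]) == 0L) f <- c(f, "*", "*")
    else stop("pileup line has fewer than 5 fields", where)
  }
  ref <- f[1L]
  pos <- as.integer(f[2L])
  ref_base <- toupper(f[3L])
  depth <- as.integer(f[4L])
  bases <- f[5L]

  cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  matches <- 0L; n_del <- 0L; n_n <- 0L; n_start <- 0L; n_end <- 0L

  if (depth > 0L || !(bases %in% c("*", ""))) {
    ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
    i <- 1L; m <- length(ch)
    while (i <= m) {
      c0 <- ch[i]
      if (c0 == "^") {
        n_start <- n_start + 1L
        i <- i + 2L              # skip the mapping-quality character
      } else if (c0 == "$") {
        n_end <- n_end + 1L
        i <- i + 1L
      } else if (c0 == "+" || c0 == "-") {
        j <- i + 1L
        while (j <= m && grepl("[0-9]", ch[j])) j <- j + 1L
        nlen <- as.integer(paste0(ch[(i + 1L):(j - 1L)], collapse = ""))
        i <- j + nlen            # skip the inserted/deleted sequence
      } else if (c0 == "." || c0 == ",") {
        matches <- matches + 1L
        i <- i + 1L
      } else if (toupper(c0) %in% c("A", "C", "G", "T")) {
        b <- toupper(c0)
        cnt[b] <- cnt[b] + 1L
        i <- i + 1L
      } else if (c0 == "*") {
        n_del <- n_del + 1L
        i <- i + 1L
      } else if (toupper(c0) == "N") {
        n_n <- n_n + 1L
        i <- i + 1L
      } else {
        stop("unknown pileup character '", c0, "'", where)
      }
    }
    parsed <- matches + sum(cnt) + n_del + n_n
    if (depth > 0L && parsed != depth) {
      stop("declared depth ", depth, " but parsed ", parsed,
           " base calls", where)
    }
  }
  if (ref_base %in% c("A", "C", "G", "T")) {
    cnt[ref_base] <- cnt[ref_base] + matches
  }
  data.frame(reference_id = ref, pos = pos, ref_base = ref_base,
             depth = depth, n_A = unname(cnt["A"]), n_C = unname(cnt["C"]),
             n_G = unname(cnt["G"]), n_T = unname(cnt["T"]),
             n_del = n_del, n_start = n_start, n_end = n_end,
             stringsAsFactors = FALSE)
}

#' Parse a samtools pileup file
#'
#' @param path Path to pileup text (one reference, positions in order).
#' @return Data frame of pileup columns, one row per line.
#' @export
read_pileup <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  out <- vector("list", length(ln))
  for (i in seq_along(ln)) out[[i]] <- parse_pileup_line(ln[i], i)
  do.call(rbind, out)
}
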