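#' Profile column order
#'
#' Column order of the tabular profile: position, reference base,
#' coverage, mismatch rate M, counts of As, Gs, Ts, Cs, arrest rate A.
#' @return Character vector of column names.
#' @export
profile_columns <- function() {
  c("pos", "ref_base", "coverage", "mismatch_rate",
    "n_A", "n_G", "n_T", "n_C", "arrest_rate")
}

#' Convert pileup columns to a profile
#'
#' Row i carries the counts of pileup column i; the mismatch rate is
#' computed per row and the arrest rate of row i is the quotient of read
#' starts at i+1 and coverage at i+1.  The final position has no i+1 and
#' its arrest rate is stored as 0 (documented in the block-file header);
#' an interior position whose i+1 has zero coverage gets `NA`.
#'
#' @param columns Pileup data frame from [pileup_from_sam()] or
#'   [read_pileup()], ordered, one row per position 1..n.
#' @return Profile data frame with the columns of [profile_columns()].
#' @export
profile_from_columns <- function(columns) {
  n <- nrow(columns)
  if (n == 0L) {
    out <- data.frame(pos = integer(), ref_base = character(),
                      coverage = integer(), mismatch_rate = numeric(),
                      n_A = integer(), n_G = integer(), n_T = integer(),
                      n_C = integer(), arrest_rate = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (!identical(as.integer(columns$pos), seq_len(n))) {
    stop("gap in pileup positions: expected contiguous 1..", n)
  }
  mr <- mismatch_rate(columns$n_A, columns$n_C, columns$n_G, columns$n_T,
                      columns$depth, columns$ref_base)
  ar <- c(arrest_rate(columns$n_start[-1L], columns$depth[-1L]), 0)
  data.frame(
    pos = columns$pos,
    ref_base = columns$ref_base,
    coverage = columns$depth,
    mismatch_rate = mr,
    n_A = columns$n_A,
    n_G = columns$n_G,
    n_T = columns$n_T,
    n_C = columns$n_C,
    arrest_rate = ar,
    stringsAsFactors = FALSE
  )
}

#' Block address of a position
#'
#' Profiles are divided into subfiles of `block_size` positions named
#' `x_y.txt`, x the reference number and y the block number; block y spans
#' positions (y-1)*block_size+1 .. min(y*block_size, reference length).
#' For a third reference of 6430 nt, position 6430 lives in file
#' `3_7.txt`, which spans 6001–6430.
#'
#' @param pos 1-based position.
#' @param reference_length Reference length in nt.
#' @param block_size Block size (default 1000).
#' @return List with `block` (y), `offset` (1-based position within the
#'   block), `start` and `end` (positions spanned by the block).
#' @export
block_for_position <- function(pos, reference_length, block_size = 1000L) {
  if (pos < 1L || pos > reference_length) {
    stop("position ", pos, " outside reference of length ", reference_length)
  }
  y <- ceiling(pos / block_size)
  list(block = as.integer(y),
       offset = as.integer(pos - (y - 1L) * block_size),
       start = as.integer((y - 1L) * block_size + 1L),
       end = as.integer(min(y * block_size, reference_length)))
}

.block_header <- function() {
  paste0("#", paste(profile_columns(), collapse = "\t"))
}

.block_path <- function(dir, ref_index, block) {
  file.path(dir, sprintf("%d_%d.txt", ref_index, block))
}

.format_profile_lines <- function(rows) {
  num <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 15,
                                                    format = "g"))
  paste(rows$pos, rows$ref_base, rows$coverage, num(rows$mismatch_rate),
        rows$n_A, rows$n_G, rows$n_T, rows$n_C, num(rows$arrest_rate),
        sep = "\t")
}

#' Write a profile to x_y.txt block files
#'
#' Tab-separated text, one `#`-prefixed header line naming the columns,
#' undefined rates serialised as `NA`.  The final block may be partial.
#'
#' @param profile Profile data frame covering positions 1..n contiguously.
#' @param ref_index 1-based reference number (x of `x_y.txt`), in FASTA
#'   order.
#' @param out_dir Output directory (created if missing).
#' @param block_size Positions per block (default 1000).
#' @return Invisibly, the written file paths.
#' @export
write_profile_blocks <- function(profile, ref_index, out_dir,
                                 block_size = 1000L) {
  n <- nrow(profile)
  if (n > 0L && !identical(as.integer(profile$pos), seq_len(n))) {
    stop("profile rows must cover positions 1..n contiguously")
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  n_blocks <- max(1L, ceiling(n / block_size))
  paths <- character(n_blocks)
  for (y in seq_len(n_blocks)) {
    lo <- (y - 1L) * block_size + 1L
    hi <- min(y * block_size, n)
    path <- .block_path(out_dir, ref_index, y)
    con <- file(path, open = "wb")
    writeLines(c(.block_header(),
                 if (hi >= lo) .format_profile_lines(profile[lo:hi, ])),
               con, sep = "\n")
    close(con)
    paths[y] <- path
  }
  invisible(paths)
}

.read_block <- function(path) {
  if (!file.exists(path)) {
    stop("missing profile block file: ", path)
  }
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = profile_columns(),
                          colClasses = c("integer", "character", "integer",
                                         "numeric", "integer", "integer",
                                         "integer", "integer", "numeric"),
                          stringsAsFactors = FALSE)
  df
}

#' Read a profile region from block files
#'
#' Opens only the block files overlapping `[start, end]` — region access
#' is O(region), not O(reference).
#'
#' @param ref_index Reference number.
#' @param start,end 1-based inclusive region bounds.
#' @param profile_dir Directory holding the `x_y.txt` files.
#' @param block_size Block size the files were written with (default 1000).
#' @return Profile data frame restricted to exactly `start..end`.
#' @export
read_region <- function(ref_index, start, end, profile_dir,
                        block_size = 1000L) {
  if (start < 1L || end < start) stop("invalid region ", start, "-", end)
  blocks <- ceiling(start / block_size):ceiling(end / block_size)
  parts <- lapply(blocks, function(y) {
    .read_block(.block_path(profile_dir, ref_index, y))
  })
  df <- do.call(rbind, parts)
  df <- df[df$pos >= start & df$pos <= end, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a complete profile from block files
#'
#' @param ref_index Reference number.
#' @param profile_dir Directory holding the block files.
#' @param block_size Block size (default 1000).
#' @return Profile data frame for all positions, blocks concatenated in
#'   y-order.
#' @export
read_profile <- function(ref_index, profile_dir, block_size = 1000L) {
  files <- list.files(profile_dir,
                      pattern = sprintf("^%d_[0-9]+\\.txt$", ref_index))
  if (length(files) == 0L) {
    stop("no profile block files for reference ", ref_index,
         " in ", profile_dir)
  }
  y <- as.integer(sub("^[0-9]+_([0-9]+)\\.txt$", "\\1", files))
  files <- files[order(y)]
  df <- do.call(rbind, lapply(file.path(profile_dir, files), .read_block))
  rownames(df) <- NULL
  df
}

#' Write the per-reference index file
#'
#' Maps reference numbers to FASTA IDs, lengths and block counts; written
#' as `index.tsv` in the profile directory.
#'
#' @param index Data frame with columns `ref_index`, `id`, `length`,
#'   `n_blocks`.
#' @param profile_dir Profile directory.
#' @return Invisibly, the index file path.
#' @export
write_profile_index <- function(index, profile_dir) {
  path <- file.path(profile_dir, "index.tsv")
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the per-reference index file
#'
#' @param profile_dir Profile directory.
#' @return Index data frame (see [write_profile_index()]).
#' @export
read_profile_index <- function(profile_dir) {
  path <- file.path(profile_dir, "index.tsv")
  if (!file.exists(path)) stop("missing profile index: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
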