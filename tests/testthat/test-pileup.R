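test_that("identity alignment fills columns with matches, one start and one end", {
  ref <- "ACGTA"
  reads <- sam_df("r1", 1L, "5M", ref)
  cols <- pileup_from_sam(reads, "ref1", ref)
  expect_equal(cols$depth, rep(1L, 5))
  expect_equal(cols$n_A, c(1L, 0L, 0L, 0L, 1L))
  expect_equal(cols$n_C, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(cols$n_start, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(cols$n_end, c(0L, 0L, 0L, 0L, 1L))
  expect_equal(mismatch_rate(cols$n_A, cols$n_C, cols$n_G, cols$n_T,
                             cols$depth, cols$ref_base), rep(0, 5))
})

test_that("a single mismatching call lands on the CIGAR-walked column", {
  ref <- strrep("A", 20)
  # read of 10M starting at pos 3; its 4th base (ref pos 6) is a G
  seq <- paste0("AAA", "G", "AAAAAA")
  cols <- pileup_from_sam(sam_df("r1", 3L, "10M", seq), "ref1", ref)
  expect_equal(cols$n_G[6], 1L)
  expect_equal(cols$n_G[-6], rep(0L, 19))
  expect_equal(cols$n_A[6], 0L)
  expect_equal(sum(cols$depth), 10L)
})

test_that("CIGAR ops follow pileup semantics: S and I contribute nothing, D counts as deletion+depth, N as neither", {
  ref <- strrep("A", 30)
  # 2S3M2I2M -> 2 clipped, 3 aligned, 2 inserted, 2 aligned (7 ref..)
  cols <- pileup_from_sam(sam_df("r1", 5L, "2S3M2I2M", "CCAAAGGAA"),
                          "ref1", ref)
  expect_equal(which(cols$depth > 0), 5:9)
  expect_equal(cols$n_start[5], 1L)   # leftmost aligned base, not the clip
  expect_equal(cols$n_end[9], 1L)
  # 3M2D3M: deletion positions get n_del and depth
  cols <- pileup_from_sam(sam_df("r2", 1L, "3M2D3M", "AAAAAA"),
                          "ref1", ref)
  expect_equal(cols$n_del[4:5], c(1L, 1L))
  expect_equal(cols$depth[1:8], rep(1L, 8))
  expect_equal(cols$n_end[8], 1L)
  # 3M5N3M: skipped region has no depth
  cols <- pileup_from_sam(sam_df("r3", 1L, "3M5N3M", "AAAAAA"),
                          "ref1", ref)
  expect_equal(cols$depth[1:11], c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_equal(cols$n_del, rep(0L, 30))
})

test_that("reads past the reference end are skipped with a warning; malformed CIGARs name the read", {
  ref <- strrep("A", 10)
  reads <- rbind(sam_df("ok", 1L, "5M", "AAAAA"),
                 sam_df("runaway", 8L, "5M", "AAAAA"))
  expect_warning(cols <- pileup_from_sam(reads, "ref1", ref),
                 "past the reference end")
  expect_equal(sum(cols$depth), 5L)
  expect_error(
    pileup_from_sam(sam_df("badcigar", 1L, "5M1", "AAAAA"), "ref1", ref),
    "badcigar")
  expect_error(
    pileup_from_sam(sam_df("shortseq", 1L, "6M", "AAAAA"), "ref1", ref),
    "shortseq")
})

test_that("depth equals an independent interval-stabbing count over 200 simulated reads", {
  set.seed(11)
  n <- 200L; L <- 400L; rl <- 25L
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  ref <- paste0(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  seqs <- substring(ref, starts, starts + rl - 1L)
  reads <- sam_df(paste0("r", 1:n), starts, sprintf("%dM", rl), seqs)
  cols <- pileup_from_sam(reads, "ref1", ref)
  stab <- vapply(1:L, function(p) {
    sum(starts <= p & starts + rl - 1L >= p)
  }, integer(1))
  expect_equal(cols$depth, stab)
  # every read contributes exactly one start and one end
  expect_equal(sum(cols$n_start), n)
  expect_equal(sum(cols$n_end), n)
  # base+deletion calls conserve the aligned length (no N ops here)
  expect_equal(sum(cols$n_A + cols$n_C + cols$n_G + cols$n_T + cols$n_del),
               n * rl)
})

test_that("count_mapped_reads excludes unmapped, secondary and supplementary alignments", {
  header_only <- withr::local_tempfile(fileext = ".sam")
  writeLines("@HD\tVN:1.6", header_only)
  expect_equal(count_mapped_reads(read_sam(header_only), "ref1"), 0L)
  reads <- rbind(sam_df("a", 1L, "5M", "AAAAA"),
                 sam_df("b", 1L, "5M", "AAAAA"),
                 sam_df("c", 1L, "5M", "AAAAA"),
                 sam_df("u", 1L, "5M", "AAAAA", flag = 4L),
                 sam_df("s", 1L, "5M", "AAAAA", flag = 256L),
                 sam_df("p", 1L, "5M", "AAAAA", flag = 2048L))
  expect_equal(count_mapped_reads(reads, "ref1"), 3L)
  expect_equal(count_mapped_reads(reads, "other"), 0L)
})

test_that("pileup dialect: starts, ends, indel blobs, deletions and case are parsed", {
  col <- parse_pileup_line("ref1\t10\tA\t5\t..,^].,\tIIIII")
  expect_equal(col$depth, 5L)
  expect_equal(col$n_A, 5L)        # matches count toward the ref base
  expect_equal(col$n_start, 1L)
  expect_equal(col$n_end, 0L)

  col <- parse_pileup_line("ref1\t11\tA\t4\t..TT\tIIII")
  expect_equal(col$n_A, 2L)
  expect_equal(col$n_T, 2L)

  col <- parse_pileup_line("ref1\t12\tC\t3\t.+2AG.,$\tIII")
  expect_equal(col$n_C, 3L)        # insertion blob contributes no calls
  expect_equal(col$n_end, 1L)

  col <- parse_pileup_line("ref1\t13\tG\t6\t.,*aA-1t.\tIIIIII")
  expect_equal(col$n_G, 3L)
  expect_equal(col$n_del, 1L)
  expect_equal(col$n_A, 2L)        # case encodes strand, both tallied

  expect_error(parse_pileup_line("ref1\t14\tA\t9\t..\tII", 14),
               "line 14")
  expect_error(parse_pileup_line("ref1\t15\tA\t2\t.!\tII"),
               "unknown pileup character")
})

test_that("internal pileup engine agrees with samtools mpileup on a fixture", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(reference_length = 500, coverage = 40,
                          read_length = 30, error_rate = 0.01,
                          sites = data.frame(pos = 250,
                                             mismatch_fraction = 0.3,
                                             arrest_fraction = 0.2),
                          seed = 5)
  ref <- generate_reference(spec)
  fa <- file.path(dir, "ref.fa"); sam <- file.path(dir, "reads.sam")
  write_reference_fasta(ref, fa)
  simulate_reads(spec, ref, sam)

  bam <- file.path(dir, "reads.bam")
  system2("samtools", c("sort", "-o", bam, sam), stdout = FALSE,
          stderr = FALSE)
  system2("samtools", c("faidx", fa), stdout = FALSE, stderr = FALSE)
  plp <- file.path(dir, "reads.pileup")
  system2("samtools", c("mpileup", "-B", "-Q", "0", "-d", "0", "-A",
                        "-a", "-f", fa, bam),
          stdout = plp, stderr = FALSE)

  ours <- pileup_from_sam(read_sam(sam), "ref_1", as.character(ref[[1]]))
  theirs <- read_pileup(plp)
  expect_equal(nrow(theirs), nrow(ours))
  expect_equal(theirs$depth, ours$depth)
  expect_equal(theirs$n_start, ours$n_start)
  expect_equal(theirs$n_end, ours$n_end)
  for (b in c("n_A", "n_C", "n_G", "n_T")) {
    expect_equal(theirs[[b]], ours[[b]], info = b)
  }
})
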