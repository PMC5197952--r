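test_that("profile rows reproduce an independent per-position recomputation", {
  set.seed(21)
  n <- 300L
  cols <- data.frame(
    reference_id = "ref1", pos = 1:n,
    ref_base = sample(c("A", "C", "G", "T"), n, TRUE),
    depth = sample(0:60, n, TRUE), stringsAsFactors = FALSE)
  cnt <- t(vapply(cols$depth, function(d) {
    if (d == 0) return(c(0L, 0L, 0L, 0L, 0L))
    x <- as.integer(stats::rmultinom(1, d, c(4, 1, 1, 1, 0.5)))
    x
  }, integer(5)))
  cols$n_A <- cnt[, 1]; cols$n_C <- cnt[, 2]; cols$n_G <- cnt[, 3]
  cols$n_T <- cnt[, 4]; cols$n_del <- cnt[, 5]
  cols$n_start <- pmin(cols$depth, sample(0:5, n, TRUE))
  cols$n_end <- pmin(cols$depth, sample(0:5, n, TRUE))

  prof <- profile_from_columns(cols)
  for (i in sample(1:(n - 1), 40)) {
    counts <- c(A = cols$n_A[i], C = cols$n_C[i], G = cols$n_G[i],
                T = cols$n_T[i])
    mm <- sum(counts) - counts[cols$ref_base[i]]
    want_m <- if (cols$depth[i] == 0) NA_real_ else mm / cols$depth[i]
    expect_equal(prof$mismatch_rate[i], unname(want_m))
    want_a <- if (cols$depth[i + 1] == 0) NA_real_ else
      cols$n_start[i + 1] / cols$depth[i + 1]
    expect_equal(prof$arrest_rate[i], want_a)
  }
  expect_equal(prof$arrest_rate[n], 0)   # final position: no i+1
  expect_error(profile_from_columns(cols[-5, ]), "gap")
})

test_that("a mismatch fraction of 8 G calls over 40 reads is 0.2", {
  cols <- data.frame(reference_id = "r", pos = 1:2,
                     ref_base = c("A", "A"), depth = c(40L, 10L),
                     n_A = c(32L, 10L), n_C = 0L, n_G = c(8L, 0L),
                     n_T = 0L, n_del = 0L, n_start = 0L, n_end = 0L,
                     stringsAsFactors = FALSE)
  prof <- profile_from_columns(cols)
  expect_equal(prof$mismatch_rate[1], 0.2)
})

test_that("block addressing matches the 1-kb x_y.txt layout", {
  b <- block_for_position(6430, 6430)
  expect_equal(b$block, 7L)
  expect_equal(b$start, 6001L)
  expect_equal(b$end, 6430L)
  expect_equal(block_for_position(1000, 6430)$block, 1L)
  expect_equal(block_for_position(1001, 6430)$block, 2L)
  expect_error(block_for_position(6431, 6430), "outside reference")

  # scan oracle on random (pos, length) pairs
  set.seed(3)
  for (i in 1:50) {
    len <- sample(1:9000, 1)
    pos <- sample(1:len, 1)
    b <- block_for_position(pos, len)
    starts <- seq(1L, len, by = 1000L)
    y <- max(which(starts <= pos))
    expect_equal(b$block, y)
    expect_equal(b$offset, pos - starts[y] + 1L)
  }
})

test_that("a 6430-row profile splits into 7 block files and round-trips", {
  prof <- random_profile(6430, seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_profile_blocks(prof, 3L, dir)
  expect_length(paths, 7L)
  expect_true(file.exists(file.path(dir, "3_7.txt")))
  last <- readLines(file.path(dir, "3_7.txt"))
  expect_length(last, 431L)                 # header + 430 data lines
  expect_match(last[1], "^#")
  expect_equal(as.integer(sub("\t.*", "", last[2])), 6001L)
  expect_equal(as.integer(sub("\t.*", "", last[431])), 6430L)

  back <- read_profile(3L, dir)
  expect_equal(back$pos, prof$pos)
  expect_equal(back$ref_base, prof$ref_base)
  expect_equal(back$coverage, prof$coverage)
  expect_equal(back$mismatch_rate, prof$mismatch_rate)
  expect_equal(back$arrest_rate, prof$arrest_rate)

  # concatenating blocks in y-order reproduces the serialized profile
  whole <- unlist(lapply(1:7, function(y) {
    ln <- readLines(file.path(dir, sprintf("3_%d.txt", y)))
    ln[-1]
  }))
  single <- withr::local_tempdir()
  write_profile_blocks(prof, 3L, single, block_size = 10000L)
  expect_identical(whole, readLines(file.path(single, "3_1.txt"))[-1])
})

test_that("read_region touches only overlapping blocks and returns exact positions", {
  prof <- random_profile(2500, seed = 5)
  dir <- withr::local_tempdir()
  write_profile_blocks(prof, 1L, dir)

  rows <- read_region(1L, 999, 1001, dir)
  expect_equal(rows$pos, 999:1001)
  expect_equal(rows$coverage, prof$coverage[999:1001])

  # delete every block except block 2: a block-2-only region still reads
  file.remove(file.path(dir, c("1_1.txt", "1_3.txt")))
  rows <- read_region(1L, 1500, 1600, dir)
  expect_equal(rows$pos, 1500:1600)
  expect_error(read_region(1L, 999, 1001, dir), "1_1\\.txt")
})
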