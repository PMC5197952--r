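test_that("arrest rate is downstream starts over downstream coverage", {
  expect_equal(arrest_rate(5, 50), 0.1)
  expect_equal(arrest_rate(0, 30), 0)
  expect_true(is.na(arrest_rate(0, 0)))
  expect_error(arrest_rate(-1, 10), "negative")
})

test_that("mismatch rate counts only non-reference A/C/G/T calls", {
  expect_equal(mismatch_rate(18, 0, 2, 0, 20, "A"), 0.1)
  expect_equal(mismatch_rate(20, 0, 0, 0, 20, "A"), 0)
  expect_true(is.na(mismatch_rate(0, 0, 0, 0, 0, "A")))
  expect_true(is.na(mismatch_rate(5, 5, 5, 5, 20, "N")))

  # identity oracle: M = 1 - F_ref - F_del - F_N on random rows
  set.seed(8)
  for (i in 1:100) {
    cov <- sample(1:80, 1)
    x <- as.integer(stats::rmultinom(1, cov, runif(6)))  # A C G T del N
    ref <- sample(c("A", "C", "G", "T"), 1)
    m <- mismatch_rate(x[1], x[2], x[3], x[4], cov, ref)
    f_ref <- x[match(ref, c("A", "C", "G", "T"))] / cov
    expect_equal(m, 1 - f_ref - x[5] / cov - x[6] / cov)
  }
})

test_that("CSA is the fold change over the truncated-window median", {
  # flat profile: fold change of equals is 1 (pseudocount 0)
  expect_equal(csa(rep(0.1, 30), pseudocount = 0), rep(1, 30))
  # spike over flat neighbours
  a <- rep(0.1, 21); a[11] <- 0.5
  expect_equal(csa(a, pseudocount = 0)[11], 5)
  # interior window has 2r neighbours, i excluded
  expect_length(csa_window(11L, 21L, 5L), 10L)
  expect_false(11L %in% csa_window(11L, 21L, 5L))
  expect_equal(csa_window(1L, 21L, 5L), 2:6)

  # literal re-evaluation oracle, including truncated ends
  set.seed(9)
  a <- runif(200, 0.01, 0.5)
  got <- csa(a, pseudocount = 0)
  for (i in c(1:7, sample(8:193, 30), 194:200)) {
    w <- setdiff(max(1, i - 5):min(200, i + 5), i)
    expect_equal(got[i], a[i] / median(a[w]))
  }

  # scale invariance at pseudocount 0
  expect_equal(csa(3.7 * a, pseudocount = 0), got)
  expect_true(is.na(csa(0.5)))
})

test_that("undefined arrest values enter CSA windows as zero", {
  a <- c(0.1, NA, 0.1, 0.1, 0.1, 0.1, 0.6)
  got <- csa(a, r = 5, pseudocount = 0)
  w <- c(0.1, 0, 0.1, 0.1, 0.1, 0.1)      # window of i = 7
  expect_equal(got[7], 0.6 / median(w))
})

test_that("heterogeneous sites require coverage >= 20 and a median mismatch-type frequency >= 0.1", {
  # ref A, cov 25, calls 10A 8G 5T 2C: mF = {0.32, 0.20, 0.08}
  row <- make_profile("A", 25L, n_A = 10L, n_G = 8L, n_T = 5L, n_C = 2L)
  expect_equal(heterogeneous_sites(row), 1L)
  # same composition below the coverage gate
  row19 <- make_profile("A", 19L, n_A = 4L, n_G = 8L, n_T = 5L, n_C = 2L)
  expect_equal(heterogeneous_sites(row19), 0L)
  # single dominant mismatch type is excluded (median 0.02)
  one <- make_profile("A", 100L, n_A = 67L, n_G = 30L, n_T = 2L, n_C = 1L)
  expect_equal(heterogeneous_sites(one), 0L)
  # N reference rows never count
  nref <- make_profile("N", 100L, n_A = 30L, n_G = 30L, n_T = 40L)
  expect_equal(heterogeneous_sites(nref), 0L)
})

test_that("S_H is monotone under raising a mismatch count at fixed gate status", {
  base <- make_profile("A", 40L, n_A = 30L, n_G = 5L, n_T = 4L, n_C = 1L)
  expect_equal(heterogeneous_sites(base), 1L)  # mF {.125,.1,.025} med .1
  for (extra in 1:5) {
    up <- base
    up$n_C <- up$n_C + extra
    up$n_A <- up$n_A - extra
    expect_gte(heterogeneous_sites(up), heterogeneous_sites(base))
  }
})

test_that("high-rate sites capture a fixed rate only once coverage is large", {
  # k = 0 never counts
  zero <- make_profile(rep("A", 5), 100L, n_A = 100L)
  expect_equal(high_rate_sites(zero, "mismatch"), 0L)
  # rate 0.10 against p0 = 0.05: insignificant at c = 20, captured at 1000
  lo <- make_profile("A", 20L, n_A = 18L, n_G = 2L)
  hi <- make_profile("A", 1000L, n_A = 900L, n_G = 100L)
  expect_equal(high_rate_sites(lo, "mismatch", p0 = 0.05, alpha = 0.001), 0L)
  expect_equal(high_rate_sites(hi, "mismatch", p0 = 0.05, alpha = 0.001), 1L)
  # membership is monotone non-decreasing in coverage at fixed rate
  tails <- vapply(c(20, 50, 100, 200, 500, 1000), function(cc) {
    stats::pbinom(0.1 * cc - 1, cc, 0.05, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(tails) < 0))
})

test_that("high-rate and heterogeneous counts equal naive per-row loops on random profiles", {
  prof <- random_profile(1000, seed = 10)
  # naive S_M
  want_sm <- 0L
  for (i in seq_len(nrow(prof))) {
    cc <- prof$coverage[i]
    if (cc == 0) next
    counts <- c(A = prof$n_A[i], C = prof$n_C[i], G = prof$n_G[i],
                T = prof$n_T[i])
    ref <- prof$ref_base[i]
    k <- sum(counts) - if (ref %in% names(counts)) counts[ref] else 0
    if (k > 0 && sum(stats::dbinom(k:cc, cc, 0.05)) <= 0.001) {
      want_sm <- want_sm + 1L
    }
  }
  expect_equal(high_rate_sites(prof, "mismatch"), want_sm)

  # naive S_A (arrest count reconstructed from rate x downstream coverage)
  want_sa <- 0L
  for (i in seq_len(nrow(prof) - 1L)) {
    cc <- prof$coverage[i + 1]
    if (cc == 0 || is.na(prof$arrest_rate[i])) next
    k <- round(prof$arrest_rate[i] * cc)
    if (k > 0 && k <= cc && sum(stats::dbinom(k:cc, cc, 0.05)) <= 0.001) {
      want_sa <- want_sa + 1L
    }
  }
  expect_equal(high_rate_sites(prof, "arrest"), want_sa)

  # naive S_H
  want_sh <- 0L
  for (i in seq_len(nrow(prof))) {
    if (prof$coverage[i] < 20 ||
        !(prof$ref_base[i] %in% c("A", "C", "G", "T"))) next
    counts <- c(A = prof$n_A[i], C = prof$n_C[i], G = prof$n_G[i],
                T = prof$n_T[i])
    mf <- counts[setdiff(c("A", "C", "G", "T"), prof$ref_base[i])] /
      prof$coverage[i]
    if (sort(mf)[2] >= 0.1) want_sh <- want_sh + 1L
  }
  expect_equal(heterogeneous_sites(prof), want_sh)
})

test_that("reference summary gathers peak, site counts and read count", {
  empty <- make_profile(rep("A", 10), 0L)
  s <- reference_summary(empty, "tRNA-Ala")
  expect_equal(s$coverage_peak, 0L)
  expect_equal(s$S_A + s$S_M + s$S_H, 0L)

  prof <- make_profile(rep("A", 150), 30L, n_A = 30L)
  prof$coverage[77] <- 77L
  prof$n_A[77] <- 77L
  s <- reference_summary(prof, "rRNA-18S", path = "x.fa",
                         mapped_reads = 123L)
  expect_equal(s$coverage_peak, 77L)
  expect_equal(s$mapped_reads, 123L)
  expect_equal(s$length, 150L)
  expect_equal(nchar(s$sequence_head), 100L)
})
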