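# Shared fixtures: all built in code, no files shipped.

# Minimal SAM text for hand-specified reads against a reference.
make_sam <- function(reads, ref_name, ref_len) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len),
    vapply(seq_along(reads$pos), function(i) {
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
              reads$qname[i], reads$flag[i], ref_name, reads$pos[i],
              reads$cigar[i], reads$seq[i],
              strrep("I", nchar(reads$seq[i])))
    }, character(1)))
}

sam_df <- function(qname, pos, cigar, seq, flag = 0L) {
  data.frame(qname = qname, flag = flag, rname = "ref1", pos = pos,
             mapq = 60L, cigar = cigar, seq = seq,
             qual = strrep("I", nchar(seq)), stringsAsFactors = FALSE)
}

# A profile data frame from raw vectors (counts include matching calls).
make_profile <- function(ref_base, coverage, n_A = 0L, n_G = 0L,
                         n_T = 0L, n_C = 0L, arrest = 0) {
  n <- length(ref_base)
  rec <- function(x) rep_len(x, n)
  data.frame(pos = seq_len(n), ref_base = ref_base,
             coverage = rec(coverage),
             mismatch_rate = mismatch_rate(rec(n_A), rec(n_C), rec(n_G),
                                           rec(n_T), rec(coverage),
                                           ref_base),
             n_A = rec(n_A), n_G = rec(n_G), n_T = rec(n_T),
             n_C = rec(n_C), arrest_rate = rec(arrest),
             stringsAsFactors = FALSE)
}

# Random profile rows for oracle checks (counts consistent by design).
random_profile <- function(n, seed = NULL, max_cov = 60L) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(c(bases, "N"), n, replace = TRUE,
                prob = c(rep(0.24, 4), 0.04))
  cov <- sample(0:max_cov, n, replace = TRUE)
  cnt <- matrix(0L, n, 4, dimnames = list(NULL, bases))
  for (i in seq_len(n)) {
    if (cov[i] == 0L) next
    pr <- stats::runif(4)^3
    cnt[i, ] <- as.integer(stats::rmultinom(1, cov[i], pr))
  }
  arrest <- round(stats::runif(n, 0, 0.5) *
                    sample(c(0, 1), n, replace = TRUE, prob = c(0.3, 0.7)),
                  4)
  data.frame(pos = seq_len(n), ref_base = ref, coverage = cov,
             mismatch_rate = mismatch_rate(cnt[, "A"], cnt[, "C"],
                                           cnt[, "G"], cnt[, "T"],
                                           cov, ref),
             n_A = cnt[, "A"], n_G = cnt[, "G"], n_T = cnt[, "T"],
             n_C = cnt[, "C"], arrest_rate = arrest,
             stringsAsFactors = FALSE)
}

# Random formula ASTs over numeric variables, for round-trip and
# evaluation oracles.
random_ast <- function(depth = 3L,
                       vars = c("pos", "cov", "mism", "A", "CSA",
                                "fA", "fG", "nT", "p_adj")) {
  ops <- c("<", "<=", ">", ">=", "==", "!=")
  atom <- function() {
    list(type = "cmp", var = sample(vars, 1),
         op = sample(ops, 1),
         value = round(stats::runif(1, -1, 30), 3))
  }
  build <- function(d) {
    if (d <= 0L || stats::runif(1) < 0.35) return(atom())
    kind <- sample(c("logic", "not"), 1, prob = c(0.8, 0.2))
    if (kind == "not") return(list(type = "not", child = build(d - 1L)))
    op <- sample(c("AND", "OR", "XOR"), 1)
    nk <- sample(2:3, 1)
    kids <- lapply(seq_len(nk), function(i) {
      repeat {
        k <- build(d - 1L)
        # keep the AST canonical: no same-op child of an n-ary node
        if (!(k$type == "logic" && k$op == op)) return(k)
      }
    })
    list(type = "logic", op = op, children = kids)
  }
  build(depth)
}

# Independent recursive evaluator used as the truth-table oracle: atoms
# evaluated with plain base R comparisons, logic combined separately.
oracle_eval <- function(node, row) {
  if (node$type == "cmp") {
    x <- row[[node$var]]
    r <- do.call(node$op, list(x, node$value))
    if (is.na(r)) FALSE else r
  } else if (node$type == "not") {
    !oracle_eval(node$child, row)
  } else {
    vals <- vapply(node$children, oracle_eval, logical(1), row = row)
    switch(node$op,
           AND = all(vals),
           OR = any(vals),
           XOR = Reduce(xor, vals))
  }
}
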