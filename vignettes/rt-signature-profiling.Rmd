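---
title: "Profiling reverse-transcription signatures of RNA modifications"
author: "rtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling reverse-transcription signatures of RNA modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsig)
```

## The model

Many RNA modifications perturb reverse transcription in two measurable
ways: the polymerase misreads the modified nucleotide (producing
non-reference base calls with a composition characteristic of the
modification), and it stalls, releasing a truncated cDNA whose 5' end
maps one position downstream of the block.  When the library protocol
captures abortive cDNAs, both effects are visible in a mapped RNA-Seq
dataset, and `rtsig` turns them into per-position metrics:

* **Coverage** c(i): reads whose alignment covers position i
  (deletions included, reference skips excluded).
* **Mismatch rate** M(i): non-reference A/C/G/T calls over coverage.
  Deletions and N calls are not mismatches.  Undefined when c = 0 or
  the reference base is N.
* **Arrest rate** A(i): read starts at i+1 divided by coverage at i+1
  — the pileup circumflex count downstream over its coverage.  The
  final position of a reference has no downstream neighbour; its A is
  stored as 0 so every profile row stays numeric for screening.
* **Context-sensitive arrest rate** CSA_r(i): the fold change of A(i)
  over the median arrest rate of the r positions on either side
  (default r = 5, i.e. 10 neighbours at interior sites, i itself
  excluded).  With a pseudocount p added to numerator and denominator,

  CSA_r(i) = (A(i) + p) / (median of neighbour A + p).

Per reference, summary statistics are gathered for sorting and
filtering: ID, path, length, the first 100 nt, the coverage peak, the
number of mapped reads, and three site counts — S_A (high-arrest),
S_M (high-mismatch) and S_H (heterogeneous-mismatch).  S_H counts
positions with coverage at least 20 whose median mismatch-type
frequency (over the three non-reference bases) reaches 0.1, i.e. two
or more mismatch types at a minimum rate of 0.1.

## Numerical choices

**CSA pseudocount.** The raw fold change is undefined wherever the
window median is 0, which is the common case in low-arrest regions.
The default p = 0.001 (configurable, p = 0 supported) keeps CSA = 1 on
flat profiles of any level, preserves scale invariance in the
well-covered regime, and bounds CSA at roughly A/p for spikes over
silent neighbourhoods.  At sequence ends the window is truncated
rather than returning NA, so every position remains screenable; the
interior window is the documented 2r-neighbour form.  Undefined arrest
values inside a window are treated as 0.  Medians of even-sized sets
use the midpoint convention.

**S_A / S_M.** These counts use a coverage-normalised threshold: a
position counts when the one-sided exact binomial tail
P(X >= k | c, p0) falls at or below alpha (defaults p0 = 0.05,
alpha = 0.001), with k the mismatch or arrest-start count and c the
relevant coverage.  A rate of 0.10 is therefore ignored at coverage 20
but captured at coverage 1000.  A flat rate threshold is available as
an alternative mode.

**Candidate screening.** Positions passing a minimum-coverage gate
(default 20) are tested; the correction multiplicity m is the number
of tested positions, not the reference length.  The site test is the
exact binomial upper tail of the observed count against a background
rate.  Defaults:

* mismatch test: background = genome-wide median mismatch rate over
  tested positions, floored at 0.001 (a median of exactly 0, common in
  clean data, would make the binomial null degenerate);
* arrest test: background = the median arrest rate of the position's
  own ±r neighbourhood, floored at the genome-wide median.  A global
  background is wrong for arrest: within one read length of a
  reference 5' end every covering read started nearby, so the arrest
  rate is structurally elevated there and a global null flags the
  whole ramp.  Testing against the local median is the same
  context-sensitivity idea CSA encodes, and an explicit `p0` restores
  the global behaviour;
* `sig_metric = "both"` combines the two one-sided tests per site by
  Bonferroni, `p = min(1, 2 min(p_mism, p_arrest))`, before the
  across-site correction.

Screening formulas are Boolean combinations of comparisons over the
profile variables (`mism >= 0.1 AND (A >= 0.2 OR CSA >= 10)`), with
precedence NOT > AND > XOR > OR, left-associative, parentheses
overriding.  Comparisons on undefined metrics are false, so uncovered
positions can never be flagged.  `p` and `p_adj` are ordinary formula
variables.  There are no built-in thresholds: what counts as
conspicuous is the user's decision, and the raw-threshold mode (no
test at all) is the plainest form of that philosophy.

**Differential comparison.** Two profiles of the same reference are
joined position-wise; deltas are sample 2 minus sample 1 (sample 2
treated), defined only where both metrics are.  The optional per-site
test is the two-sided Fisher exact test on the 2x2 count table; the
default remains pure threshold screening on the deltas.  No
cross-sample coverage normalisation is applied — all compared metrics
are already rates.

## Storage layout

Profiles are tab-separated text with one `#`-prefixed header line and
columns position, reference base, coverage, M, #A, #G, #T, #C, A;
undefined rates are serialised as `NA`.  Files are split into blocks
of 1000 positions named `x_y.txt` (x = reference number in FASTA
order, 1-based; y = block number), so block y holds positions
(y-1)·1000+1 .. min(y·1000, n) — for a third reference of 6430 nt,
`3_7.txt` holds 6001–6430.  Region queries open only the overlapping
blocks, which keeps access to the far end of a chromosome-sized
reference cheap.  The delimiter, header and NA token are this
package's own dialect; the column content is fixed, the serialisation
was not.

## The simulator

`simulation_spec()` / `simulate_reads()` emulate an abortive-cDNA
capture experiment: forward-strand reads of fixed length (default
50 nt, typical of such protocols) placed uniformly on a uniform random
reference, i.i.d. per-base miscalls at `error_rate`, and planted sites
where covering reads miscall with a chosen fraction and composition,
and/or reads crossing into pos+1 are truncated to start exactly at
pos+1 with probability `arrest_fraction`.  Truncation (rather than
splitting) mirrors protocols in which each aborted cDNA yields one
sequenced fragment, and it makes the arrest-rate estimator target the
planted fraction directly.  Two deliberate simplifications matter for
interpreting tests: reads naturally starting at pos+1 add a small
positive bias of about (1-a)/read_length (≈ 0.012 at a = 0.4), well
inside the three-binomial-SE tolerance used in validation, and uniform
placement means no 3' bias, no PCR duplicates, no splicing and no
quality-score structure.  Passing tests therefore demonstrate
estimator and screening correctness under a clean generative model,
not robustness to the coverage heterogeneity of real libraries.

Determinism is part of the contract: identical spec and seed give
byte-identical SAM output.

## Problem sizes used in validation

The shipped tests run the full pipeline on a 10-kb reference at
coverage 500 (100,000 reads, error rate 0.005) with 20 planted sites
(mismatch fraction 0.3 or arrest fraction 0.4), check profile metrics
at planted sites within three binomial standard errors, and require
`p_adj <= 0.05` screening (BH, combined metric) to recover exactly the
planted set.  Oracle-equivalence suites use 10^4-position CSA
profiles, 10^3-row heterogeneous-site tables and 500 random formulas
against truth-table brute force.

## Known limitations

* Reverse-strand starts are counted at the leftmost aligned base,
  literally matching the pileup circumflex; for protocols where the
  biological 5' end is the rightmost base, use
  `start_policy = "rightmost"` (or `"forward-strand"` to ignore
  reverse reads).
* The binomial site test assumes independent calls at a position; UMI
  collapsing or duplicate removal must happen upstream.
* The package nominates candidates; it does not predict which chemical
  modification produced a signature, and candidates deserve
  independent biochemical validation before stronger claims.
* XOR shares a single precedence level below AND; formulas mixing XOR
  and OR are clearest fully parenthesised.
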