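---
title: "Measuring randomness in categorical response sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring randomness in categorical response sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rngtask)
```

## The measurement problem

In a random generation task a subject produces a sequence of responses
from a fixed, finite set of alternatives — digits 1..9, letters, heads and
tails — trying to be "random". Humans fail in characteristic ways: they
overuse some responses, avoid immediate repetitions, favor ordinal runs,
and cycle through the alternatives too regularly. Each failure mode has a
classical summary statistic, and the sequence as a whole has a temporal
structure that recurrence quantification captures. `rngtask` computes
both families on a common data model: a `symbol_sequence`, an ordered
token vector over a declared `alphabet`.

Two output conventions are supported everywhere. *Classical* mode mirrors
the historical desktop tools: percentages for Redundancy, NSQ, Adjacency,
a TPI percentage centered at 100, and end-to-start "wrapped" digrams for
the RNG index. *Default* mode is the modernized scale: proportions in
[0, 1], TPI and phi centered at 0, and no wrapping anywhere (a pair formed
by gluing the last response to the first says nothing about inhibition or
monitoring, which act forward in time). The exact bridges, which the test
suite asserts on random inputs, are: classical R/NSQ/Adjacency = 100 ×
default; classical TPI = 100 × (default TPI + 1); Coupon, RNG2, repetition
gaps and phi are identical in both modes; classical Runs is reported as
not computable (the historical computation is not reproducible).

## The randomization measures

**Redundancy.** `R = 1 − [log2(n) − (1/n) Σ aᵢ log2 aᵢ] / log2(a)`
compares the Shannon entropy of the observed response frequencies with its
maximum; 0 is perfectly equal usage, 1 a single repeated response. The
`0·log 0 ≡ 0` convention applies here and in every entropy-style sum.

**RNG and RNG2.** Evans' digram index
`Σ n_ij log2 n_ij / Σ aᵢ log2 aᵢ`, where `n_ij` counts ordered adjacent
(lag-1) pairs and the denominator runs over the *digram first-member
totals* (the row marginals of the digram table), not the raw symbol
counts. The marginal reading is deliberate: it is the only one under which
a perfectly alternating sequence — every digram maximally repeated —
attains the index's stated maximum of 1, and the two coincide in classical
(wrapped) mode anyway. When every first member occurs just once the
denominator vanishes and the index is flagged not computable rather than
returned as 0/0. RNG2 is the same computation on lag-2 (interleaved)
pairs and never wraps in either mode.

**NSQ.** `NS / (a² − 1)` with `NS` the number of ordered pair types never
observed among the (unwrapped) lag-1 digrams. A long random sequence
eventually exhausts all `a²` types and NSQ falls to 0.

**Coupon.** The mean number of responses needed to cycle through the full
alphabet: a left-to-right scan records the length of each completed cycle
and resets; an unfinished tail is discarded. If an alternative never
occurs no cycle completes and the score is not computable.

**FOD, Adjacency.** First-order differences are the signed ordinal
differences of consecutive responses, tallied into a frequency table
totalling `n − 1`. Adjacency is the share of consecutive pairs that are
ordinal neighbors; ascending (+1) and descending (−1) shares are reported
separately and combined. Two conventions were fixed after inspecting the
published output layout they must reproduce: the denominator is `n` (not
`n − 1`), the only choice under which the classical and default columns
are an exact ×100 pair, and "ascending means difference +1" (the prose
source states the opposite pairing, which is arithmetically inconsistent
with its own difference definition and treated as a transposition
erratum). Non-numeric alphabets use their declaration order as the
ordinal scale, so these measures remain defined for letters or coin flips.

**TPI, Phase Lengths, Runs.** A turning point is a switch between
ascending and descending. Consecutive equal responses are collapsed
before direction analysis (a plateau is a single point on the direction
profile); endpoints never count. TPI compares the observed count with the
random-walk expectation `(2/3)(n − 2)`, with `n` the *original* length —
the formula defines it so, even though collapsing shortens the analyzed
series (see Limitations). Phase lengths are the index gaps between
consecutive turning points on the collapsed series, classed ascending or
descending by whether the phase ends at a peak or a trough. Runs is the
population variance (divide by the count, not count − 1) of the pooled
phase lengths.

**Repetition distance, gap, phi.** For each response that has occurred
before, the distance to its most recent prior occurrence is tallied; the
table totals `n` minus the number of distinct symbols used. The gap
summaries are the mean, the median (midpoint of the two central values for
even counts) and the mode (ties resolve to the smallest distance — an
arbitrary but deterministic and documented choice). The phi index at lag
*g* contrasts the observed number of repeats at exactly distance *g* with
its expectation under IID uniform responding, as the z-score
`(observed − E) / SD`. The historical closed form was not available to
this implementation, so E and SD are estimated by seeded Monte-Carlo
resampling (`phi_null()`, default 1000 replicates) of IID sequences with
the same length and alphabet; the null depends only on `(n, a)` and can be
computed once and shared across a batch, which the batch driver does. The
computation is isolated behind `phi_indices(..., null = )` so a
closed-form backend can replace the resampler without touching callers.
Published phi values from other implementations are not reproduction
targets: they depend on an unavailable legacy random stream and possibly
on a lag-labelling offset (a "phi 2" that actually concerns adjacent
repeats), so only the contract — mean 0, unbounded, sign tracking
over/under-representation — is guaranteed.

## The recurrence engine

The auto-recurrence plot of a categorical sequence of length *N* is the
*N* × *N* binary matrix with a point at (*i*, *j*) whenever the responses
at *i* and *j* are identical. Only exact matches count: the radius
parameter is retained for API parity but must stay below 1, which on
nominal data is equivalent to identity. The main diagonal — every
position trivially recurs with itself — is excluded throughout: it is
dropped from the recurrence count, never contributes a diagonal line, and
splits vertical runs that would cross it. RR nevertheless normalizes by
*N*² (not *N*² − *N*): that pair of conventions, exclusion plus *N*²
normalization, is the one consistent with published reference output (a
binary sequence with a 52/48 split gives RR = (52² + 48² − 100)/100² =
0.491 exactly, a closed form the tests assert for all binary sequences).
Both triangles are counted; being mirror images they carry the same
information, and all nine measures are invariant under sequence reversal
and symbol relabeling, which the tests also assert.

Diagonal lines are maximal runs of recurrent cells parallel to the main
diagonal; vertical lines are maximal runs within a column. With the
nominal-series defaults (embedding dimension *m* = 1, delay τ = 1,
minimal line length 2) a diagonal line of length *l* is a repeated
*l*-gram and a vertical line of length *v* is an immediate repetition of
the same response *v* + 1 times. From the two length histograms `P(l)`
and `P(v)`: DET and LAM are the shares of recurrent points on lines of
length ≥ 2; Lmax and Vmax the maxima; L (Lmean) and TT (trapping time)
the means over lines ≥ 2; Lentr and Ventr the Shannon entropies (natural
log) of the length distribution restricted to lengths ≥ 2 and normalized
to probabilities — a single distinct length therefore gives entropy
exactly 0. When no line reaches the threshold DET/LAM are 0 and the
max/mean/entropy statistics are flagged not computable. Embedding with
*m* > 1 delay-embeds the ordinal codes and requires all coordinates to
match; it is accepted and tested for basic correctness, but the *m* = 1
path is the supported use.

Every measure is computed twice in this package: by the production engine
(`rqa_measures()`, histogram-based) and by a deliberately naive oracle
(`rqa_oracle()`) that materializes the full matrix and walks every
diagonal and column cell by cell, sharing no code. The acceptance suite
drives both over 200 randomized sequences (n ∈ 10..200, a ∈ 2..26) and
requires exact agreement on all nine values.

## The sequence generator and fixtures

`generate_iid()` draws uniform IID tokens from a private seeded
Mersenne-Twister stream; it is a pure function of (alphabet, length,
seed) and leaves the caller's RNG state untouched. It emulates the
*null* subject — independent, uniform, memoryless — which is exactly what
the Monte-Carlo null tests and the phi resampler need. It does not
emulate real RNG-task behavior (sequential dependence, repetition
avoidance, stereotyped runs), so a green Monte-Carlo test establishes
calibration under the null, not sensitivity to pathology. No attempt is
made to reproduce any legacy generator's stream bit-for-bit;
published example tables built from such streams are treated as
documentation, and only their analytically determined cells (values fully
fixed by the formulas given the printed inputs) are reproduction targets.

`construct_fixture()` builds sequences whose measure values are known by
construction rather than by simulation: a length-*n* sequence with
exactly *tp* turning points (zigzag prefix, constant tail — the tail
collapses away under the tie rule); a sequence with exactly *d* distinct
ordered adjacent pairs over *a* symbols, taken as a prefix of an Eulerian
circuit of the complete digraph with self-loops (so all pairs in the
prefix are distinct) padded with repeats of the (1,1) pair; and the
tandem-pairs pattern 1,1,2,2,... whose off-diagonal vertical runs all
have length exactly 2, pinning trapping time to 2.0 and Ventr to 0. The
feasible range for `d` is 1..min(n−1, a²) and for `tp` is 0..n−2;
infeasible requests error with the range.

## Numerical and interface choices

* `0 log 0 ≡ 0` everywhere; entropies use log2 for the randomization
  measures (matching their definitions) and natural log for Lentr/Ventr.
* IEEE −0 from `-sum(p log p)` is normalized to 0.
* Tabular (CSV) output renders to 3 decimals with round-half-to-even;
  JSON output keeps full precision. Not-computable values print as `NA`
  and never abort a batch: each sequence row fails independently and is
  logged.
* Tokens are compared as exact trimmed strings; numeric alphabets
  canonicalize tokens to integers. The exact-match radius rule makes any
  fuzzier comparison meaningless for this data class.
* Batch output for *k* sequences equals *k* single-sequence runs
  concatenated, and a fixed (config, seed) pair reruns byte-identically;
  both are asserted by tests.

## Known limitations

* **The TPI null is biased on discrete alphabets — by design of the
  measure, not of this implementation.** Adjacent ties occur with
  probability 1/a under the IID null and are collapsed before direction
  analysis, while the expectation (2/3)(n − 2) assumes a tie-free
  continuous series. At n = 550, a = 9 the simulated null mean of default
  TPI is −0.056 (SE 0.001); for a binary alphabet the bias reaches ≈
  −0.25. Published random baselines show the same signature. The
  acceptance criterion asking this mean to be within sampling error of 0
  is therefore left failing, with the analysis recorded alongside the
  test, rather than silently weakened: users comparing TPI across groups
  should compare against a simulated null at their own (n, a), not
  against 0.
* The phi indices are calibrated by simulation; with the default 1000
  replicates the index carries Monte-Carlo noise of order 1/√1000 in its
  standardization, negligible for screening but visible at the third
  decimal.
* The classical Runs value of the legacy tool is unreproducible and is
  reported as NA in classical mode.
* Cross-recurrence between two sequences, windowed RQA, metric radii for
  continuous signals, and sequences too long for an N × N logical matrix
  are out of scope.
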