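#' Redundancy of response usage
#'
#' Shannon-entropy measure of unequal use of the response alternatives:
#' `R = 1 - (log2(n) - (1/n) * sum(a_i * log2(a_i))) / log2(a)`, where `a_i`
#' counts the i-th alternative. 0 means every alternative is used in equal
#' proportion; 1 means a single response is given throughout. Classical mode
#' reports a percentage (x100).
#'
#' @param seq A `symbol_sequence`.
#' @param mode `"default"` (proportion in 0..1) or `"classical"` (percent).
#' @return Numeric score.
#' @export
redundancy <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  a <- seq$alphabet$size
  counts <- tabulate(seq$ordinals, nbins = a)
  r <- 1 - (log2(seq$n) - sum(xlog2x(counts)) / seq$n) / log2(a)
  if (mode == "classical") 100 * r else r
}

#' RNG index (digram inequality at lag 1)
#'
#' Inequality of response usage at the level of ordered adjacent pairs:
#' `RNG = sum(n_ij log2 n_ij) / sum(a_i log2 a_i)` with `n_ij` the lag-1
#' digram counts and `a_i` the digram first-member totals. 0 means every
#' observed digram is unique; 1 means digrams repeat maximally. Classical
#' mode follows the legacy convention of pairing the last response back to
#' the first (wrapped digrams); default mode never wraps. Both modes are on
#' the proportion scale.
#'
#' @inheritParams redundancy
#' @return Numeric score in 0..1, or a not-computable marker when no digram
#'   first member repeats.
#' @export
rng_index <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  if (seq$n < 3L) stop("RNG needs n >= 3")
  digram_inequality(digram_counts(seq, lag = 1L, wrap = mode == "classical"))
}

#' RNG2 index (digram inequality at lag 2)
#'
#' The RNG computation applied to interleaved pairs (lag 2). Never wraps in
#' either mode, so classical and default output are identical.
#'
#' @inheritParams redundancy
#' @return Numeric score in 0..1, or a not-computable marker.
#' @export
rng2_index <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); match.arg(mode)
  if (seq$n < 4L) stop("RNG2 needs n >= 4")
  digram_inequality(digram_counts(seq, lag = 2L, wrap = FALSE))
}

#' Null-Score Quotient
#'
#' Proportion of possible ordered pair types that never appear among the
#' lag-1 digrams (no end-to-start wrapping in either mode):
#' `NSQ = NS / (a^2 - 1)` with `NS` the number of unobserved digram types.
#' Classical mode reports a percentage.
#'
#' @inheritParams redundancy
#' @return Numeric score.
#' @export
nsq <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  if (seq$n < 2L) stop("NSQ needs n >= 2")
  dt <- digram_counts(seq, lag = 1L, wrap = FALSE)
  a <- seq$alphabet$size
  ns <- a * a - length(dt$counts)
  q <- ns / (a * a - 1)
  if (mode == "classical") 100 * q else q
}

#' Coupon score
#'
#' Mean number of responses needed to cycle through every response
#' alternative once: the sequence is scanned left to right, each completed
#' cycle's length is recorded and the running set reset; an unfinished
#' trailing segment is discarded. Identical in both modes. When one or more
#' alternatives are never used (or no cycle completes) the score cannot be
#' calculated.
#'
#' @inheritParams redundancy
#' @return Mean cycle length, or a not-computable marker.
#' @export
coupon <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); match.arg(mode)
  a <- seq$alphabet$size
  if (seq$n < a)
    return(not_computable("sequence shorter than the alphabet"))
  if (length(unique(seq$ordinals)) < a)
    return(not_computable("one or more response alternatives never used"))
  seen <- logical(a); missing <- a; len <- 0L
  lens <- integer(0)
  for (o in seq$ordinals) {
    len <- len + 1L
    if (!seen[o]) { seen[o] <- TRUE; missing <- missing - 1L }
    if (missing == 0L) {
      lens <- c(lens, len)
      seen[] <- FALSE; missing <- a; len <- 0L
    }
  }
  if (length(lens) == 0L)
    return(not_computable("no complete cycle through the alternatives"))
  mean(lens)
}

#' First-order difference table
#'
#' Frequency table of the arithmetic differences between consecutive
#' responses on the alphabet's ordinal scale (`ordinal[i] - ordinal[i-1]`),
#' no wrapping; the total is `n - 1`.
#'
#' @param seq A `symbol_sequence`.
#' @return A [freq_table()] keyed by signed difference.
#' @export
fod_table <- function(seq) {
  seq <- as_seq(seq)
  if (seq$n < 2L) stop("first-order differences need n >= 2")
  d <- diff(seq$ordinals)
  ft <- freq_table(d)
  # reorder numerically, keeping class/total
  idx <- order(as.integer(names(ft)))
  structure(stats::setNames(as.integer(ft)[idx], names(ft)[idx]),
            total = attr(ft, "total"), class = "freq_table")
}

#' Adjacency
#'
#' Proportion of adjacent (lag-1) pairs whose members are ordinal neighbors:
#' ascending pairs have first-order difference +1, descending pairs -1. Each
#' count is divided by the sequence length `n`; the combined score uses the
#' summed counts over the same denominator. Classical mode reports
#' percentages.
#'
#' @inheritParams redundancy
#' @return Named numeric vector `c(ascending, descending, combined)`.
#' @export
adjacency <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  if (seq$n < 2L) stop("adjacency needs n >= 2")
  d <- diff(seq$ordinals)
  asc <- sum(d == 1L); desc <- sum(d == -1L)
  out <- c(ascending = asc, descending = desc, combined = asc + desc) / seq$n
  if (mode == "classical") 100 * out else out
}

# collapse consecutive duplicate ordinals before any direction analysis
collapse_ties <- function(ordinals) rle(ordinals)$values

#' Count turning points
#'
#' Number of positions where the sequence changes numerical direction
#' (ascending to descending or vice versa) on the ordinal scale. Consecutive
#' equal values are collapsed first, so plateaus count as a single point;
#' endpoints are never turning points.
#'
#' @param seq A `symbol_sequence`.
#' @return Integer count (`TP_observed`).
#' @export
turning_points <- function(seq) {
  seq <- as_seq(seq)
  if (seq$n < 3L) stop("turning points need n >= 3")
  y <- collapse_ties(seq$ordinals)
  if (length(y) < 3L) return(0L)
  s <- sign(diff(y))
  sum(s[-length(s)] != s[-1L])
}

#' Turning Point Index
#'
#' Compares the observed number of turning points with the expectation
#' `(2/3) * (n - 2)` for a random sequence (the original sequence length `n`
#' is used even when ties collapse). Default mode is centered at 0:
#' `TP / ((2/3)(n-2)) - 1`; classical mode is the percentage
#' `100 * TP / ((2/3)(n-2))`.
#'
#' @inheritParams redundancy
#' @return Numeric score.
#' @export
tpi <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  if (seq$n < 3L) stop("TPI needs n >= 3")
  r <- turning_points(seq) / ((2 / 3) * (seq$n - 2))
  if (mode == "classical") 100 * r else r - 1
}

#' Phase lengths
#'
#' The intervals between consecutive turning points, measured on the
#' tie-collapsed series. A phase that ends at a peak was ascending; one that
#' ends at a trough was descending. Fewer than two turning points yield
#' empty tables.
#'
#' @param seq A `symbol_sequence`.
#' @return List with [freq_table()]s `ascending` and `descending`, plus
#'   `lengths` (the pooled phase-length vector in sequence order).
#' @export
phase_lengths <- function(seq) {
  seq <- as_seq(seq)
  if (seq$n < 3L) stop("phase lengths need n >= 3")
  y <- collapse_ties(seq$ordinals)
  empty <- list(ascending = freq_table(), descending = freq_table(),
                lengths = integer(0))
  if (length(y) < 3L) return(empty)
  s <- sign(diff(y))
  turn <- which(s[-length(s)] != s[-1L]) + 1L  # positions in collapsed series
  if (length(turn) < 2L) return(empty)
  gaps <- diff(turn)
  # the phase ending at turning point k is ascending iff k is a peak,
  # i.e. the step into it was upward
  peak_end <- s[turn[-1L] - 1L] > 0
  list(
    ascending = freq_table(gaps[peak_end]),
    descending = freq_table(gaps[!peak_end]),
    lengths = gaps
  )
}

#' Runs (phase-length variability)
#'
#' Population variance of the pooled ascending and descending phase lengths.
#' The legacy classical computation is not reproducible, so classical mode
#' reports a not-computable marker.
#'
#' @inheritParams redundancy
#' @return Numeric variance, or a not-computable marker (fewer than two
#'   phase lengths, or classical mode).
#' @export
runs <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  if (mode == "classical")
    return(not_computable("classical Runs is not reproducible"))
  g <- phase_lengths(seq)$lengths
  if (length(g) < 2L)
    return(not_computable("fewer than two phase lengths"))
  mean((g - mean(g))^2)
}

#' Repetition distances
#'
#' For every response whose symbol has occurred before, the distance to its
#' most recent prior occurrence. The total count is `n` minus the number of
#' distinct symbols observed.
#'
#' @param seq A `symbol_sequence`.
#' @return A [freq_table()] keyed by distance; empty when nothing repeats.
#' @export
repetition_distances <- function(seq) {
  seq <- as_seq(seq)
  if (seq$n < 2L) stop("repetition distances need n >= 2")
  idx <- split(seq_len(seq$n), seq$ordinals)
  gaps <- unlist(lapply(idx, function(i) if (length(i) > 1L) diff(i)),
                 use.names = FALSE)
  if (is.null(gaps)) gaps <- integer(0)
  ft <- freq_table(gaps)
  idx2 <- order(as.integer(names(ft)))
  structure(stats::setNames(as.integer(ft)[idx2], names(ft)[idx2]),
            total = attr(ft, "total"), class = "freq_table")
}

#' Repetition gap summaries
#'
#' Mean, median and modal gap of the repetition-distance multiset. The
#' median of an even count is the midpoint average; modal ties resolve to
#' the smallest distance. Identical in both modes.
#'
#' @inheritParams redundancy
#' @return Named numeric vector `c(mean, median, mode)`, or a not-computable
#'   marker when nothing repeats.
#' @export
repetition_gap <- function(seq, mode = c("default", "classical")) {
  seq <- as_seq(seq); match.arg(mode)
  ft <- repetition_distances(seq)
  if (length(ft) == 0L)
    return(not_computable("no symbol repeats"))
  dists <- as.integer(names(ft))
  counts <- as.integer(ft)
  x <- rep(dists, counts)
  c(mean = mean(x), median = stats::median(x),
    mode = dists[which.max(counts)])  # which.max takes the first = smallest
}

#' Per-symbol response frequencies
#'
#' Count of each response alternative, including zeros for unused ones.
#'
#' @param seq A `symbol_sequence`.
#' @return A [freq_table()] over the full alphabet; total `n`.
#' @export
response_frequencies <- function(seq) {
  seq <- as_seq(seq)
  freq_table(as.character(seq$alphabet$alternatives)[seq$ordinals],
             levels = as.character(seq$alphabet$alternatives))
}
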