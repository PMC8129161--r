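#' Count ordered response pairs (digrams)
#'
#' Tallies ordered pairs `(token[i - lag], token[i])` at the given lag. With
#' `wrap = TRUE` the final `lag` pairs wrap cyclically from the end of the
#' sequence to its start (the legacy RGcalc convention for the RNG index);
#' with `wrap = FALSE` no end-to-start pairing occurs and the total is
#' `n - lag`.
#'
#' @param seq A `symbol_sequence`.
#' @param lag Positive integer lag (1 = adjacent, 2 = interleaved).
#' @param wrap Pair the sequence end back to its start?
#' @return A list of class `digram_table`: `counts` (a [freq_table()] keyed
#'   by `"first>second"`), `row_totals` (a [freq_table()] over first members,
#'   zero-padded to the alphabet), `lag`, `wrap`, and `pairs` (a 2-column
#'   matrix of ordinal pairs).
#' @export
digram_counts <- function(seq, lag = 1L, wrap = FALSE) {
  seq <- as_seq(seq)
  lag <- canonical_int(lag, "lag")
  if (lag < 1L) stop("`lag` must be >= 1")
  if (seq$n <= lag)
    stop(sprintf("sequence length %d is too short for lag %d", seq$n, lag))
  o <- seq$ordinals
  n <- seq$n
  first <- o[seq_len(n - lag)]
  second <- o[(lag + 1L):n]
  if (wrap) {
    first <- c(first, o[(n - lag + 1L):n])
    second <- c(second, o[seq_len(lag)])
  }
  alts <- as.character(seq$alphabet$alternatives)
  key <- paste(alts[first], alts[second], sep = ">")
  structure(
    list(
      counts = freq_table(key),
      row_totals = freq_table(alts[first], levels = alts),
      lag = lag, wrap = wrap,
      pairs = cbind(first = first, second = second)
    ),
    class = "digram_table"
  )
}

#' @export
print.digram_table <- function(x, ...) {
  cat(sprintf("<digram table: lag %d, %s, %d pairs, %d distinct>\n",
              x$lag, if (x$wrap) "wrapped" else "no wrap",
              attr(x$counts, "total"), length(x$counts)))
  invisible(x)
}

# Evans' RNG-style digram inequality index: sum n_ij log2 n_ij over digram
# counts divided by the same sum over the digram first-member totals.
digram_inequality <- function(dt) {
  num <- sum(xlog2x(as.numeric(dt$counts)))
  den <- sum(xlog2x(as.numeric(dt$row_totals)))
  if (den == 0)
    return(not_computable("all digram first members occur at most once"))
  num / den
}
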