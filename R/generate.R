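#' Generate a seeded IID uniform sequence
#'
#' Draws `length` tokens independently and uniformly from the alphabet using
#' a private Mersenne-Twister stream: the same `(alphabet, length, seed)`
#' triple always yields the same sequence, and the caller's RNG state is left
#' untouched. No attempt is made to reproduce any other software's sampling
#' stream.
#'
#' @param alph An [alphabet()].
#' @param length Number of tokens to draw (>= 1).
#' @param seed Integer seed.
#' @return A `symbol_sequence`.
#' @export
generate_iid <- function(alph, length, seed) {
  stopifnot(inherits(alph, "rng_alphabet"))
  length <- canonical_int(length, "length")
  if (length < 1L) stop("`length` must be >= 1")
  toks <- with_seed(seed, sample(alph$alternatives, length, replace = TRUE))
  make_sequence(toks, alphabet = alph)
}

#' Construct sequences with known measure values
#'
#' Deterministic constructions used to pin down measure behavior exactly:
#'
#' * `constant`: one symbol repeated `n` times (maximum redundancy).
#' * `alternating`: the first two alternatives strictly alternated.
#' * `tandem_pairs`: the pattern 1,1,2,2,1,1,2,2,... in which every
#'   off-diagonal vertical recurrence run has length exactly 2.
#' * `turning_points`: a numeric sequence of length `n` with exactly `tp`
#'   turning points (a two-symbol zigzag prefix followed by a constant tail,
#'   which collapses away under the tie rule).
#' * `digram_count`: a sequence of length `n` over `a` symbols with exactly
#'   `d` distinct ordered adjacent pairs, built from an Eulerian circuit of
#'   the complete digraph (self-loops included) padded with repeats of the
#'   1,1 pair.
#'
#' @param kind Fixture kind.
#' @param n Sequence length.
#' @param tp Exact number of turning points (`turning_points` kind);
#'   0 <= tp <= n - 2.
#' @param a Alphabet size (`digram_count` kind).
#' @param d Exact number of distinct ordered adjacent pairs
#'   (`digram_count` kind); 1 <= d <= min(n - 1, a^2).
#' @param alph Alphabet for `constant`/`alternating`/`tandem_pairs`/
#'   `turning_points`; defaults to the 1..9 digit scale.
#' @return A `symbol_sequence` satisfying the declared constraint exactly.
#' @export
construct_fixture <- function(kind = c("constant", "alternating", "tandem_pairs",
                                       "turning_points", "digram_count"),
                              n = 8L, tp = NULL, a = NULL, d = NULL,
                              alph = alphabet(min_scale = 1, max_scale = 9)) {
  kind <- match.arg(kind)
  n <- canonical_int(n, "n")
  if (n < 1L) stop("`n` must be positive")

  switch(kind,
    constant = make_sequence(rep(alph$alternatives[1L], n), alphabet = alph),
    alternating = make_sequence(
      rep_len(alph$alternatives[1:2], n), alphabet = alph),
    tandem_pairs = {
      if (n %% 4L != 0L) stop("tandem_pairs needs `n` divisible by 4")
      make_sequence(rep(alph$alternatives[c(1L, 1L, 2L, 2L)], n / 4L),
                    alphabet = alph)
    },
    turning_points = {
      if (is.null(tp)) stop("turning_points needs `tp`")
      tp <- canonical_int(tp, "tp")
      if (tp < 0L || tp > n - 2L)
        stop(sprintf("infeasible: `tp` must be in [0, %d] for n = %d", n - 2L, n))
      zig <- rep_len(alph$alternatives[1:2], tp + 2L)
      make_sequence(c(zig, rep(zig[tp + 2L], n - tp - 2L)), alphabet = alph)
    },
    digram_count = {
      if (is.null(a) || is.null(d)) stop("digram_count needs `a` and `d`")
      a <- canonical_int(a, "a"); d <- canonical_int(d, "d")
      if (a < 2L) stop("`a` must be >= 2")
      hi <- min(n - 1L, a * a)
      if (d < 1L || d > hi)
        stop(sprintf("infeasible: `d` must be in [1, %d] for n = %d, a = %d",
                     hi, n, a))
      circuit <- eulerian_circuit(a)          # a^2 + 1 nodes, first edge (1,1)
      walk <- circuit[seq_len(d + 1L)]        # d distinct ordered pairs
      toks <- c(rep(1L, n - d - 1L), walk)    # padding reuses the (1,1) pair
      make_sequence(toks, min_scale = 1, max_scale = a)
    }
  )
}

# Hierholzer's algorithm on the complete digraph over 1..a with self-loops
# (in-degree == out-degree == a at every node, so an Eulerian circuit exists).
# The self-loop is listed first at every node, so the circuit starts 1,1,...
eulerian_circuit <- function(a) {
  nbrs <- lapply(seq_len(a), function(i) c(i, setdiff(seq_len(a), i)))
  ptr <- rep(1L, a)
  stack <- 1L
  path <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (ptr[v] <= a) {
      u <- nbrs[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      stack <- c(stack, u)
    } else {
      path <- c(path, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(path)
}
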