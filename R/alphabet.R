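#' Construct a response alphabet
#'
#' An alphabet is the ordered set of response alternatives a subject may
#' produce in a random generation task. It can be declared either as a
#' numeric scale (`min_scale`..`max_scale`, every integer in between is an
#' alternative) or as an explicit ordered vector of tokens (e.g.
#' `c("head", "tail")`, or `letters`). Non-numeric tokens receive ordinal
#' codes 1..a in declaration order; all difference-based measures (first-order
#' differences, adjacency, turning points) operate on these ordinals.
#'
#' @param alternatives Ordered vector of distinct tokens, or `NULL`.
#' @param min_scale,max_scale Integer bounds of a numeric scale, or `NULL`.
#'   Exactly one of `alternatives` or the `min_scale`/`max_scale` pair must be
#'   given.
#' @return An object of class `rng_alphabet` with fields `alternatives`,
#'   `size`, `numeric`, `min_scale`, `max_scale`.
#' @examples
#' alphabet(min_scale = 1, max_scale = 9)
#' alphabet(alternatives = c("head", "tail"))
#' @export
alphabet <- function(alternatives = NULL, min_scale = NULL, max_scale = NULL) {
  has_scale <- !is.null(min_scale) || !is.null(max_scale)
  has_alts <- !is.null(alternatives)
  if (has_scale && has_alts)
    stop("give either `alternatives` or `min_scale`/`max_scale`, not both")
  if (!has_scale && !has_alts)
    stop("one of `alternatives` or `min_scale`/`max_scale` is required")

  if (has_alts) {
    alts <- if (is.numeric(alternatives)) canonical_int(alternatives, "alternatives")
            else trimws(as.character(alternatives))
    if (anyDuplicated(alts))
      stop("duplicate response alternatives: ",
           paste(unique(alts[duplicated(alts)]), collapse = ", "))
    if (length(alts) < 2L) stop("an alphabet needs at least 2 alternatives")
    numeric_flag <- is.integer(alts) &&
      identical(alts, seq.int(min(alts), max(alts)))
    out <- list(
      alternatives = alts,
      size = length(alts),
      numeric = numeric_flag,
      min_scale = 1L,
      max_scale = length(alts)
    )
    if (numeric_flag) {
      out$min_scale <- min(alts)
      out$max_scale <- max(alts)
    }
  } else {
    if (is.null(min_scale) || is.null(max_scale))
      stop("both `min_scale` and `max_scale` are required for a numeric scale")
    lo <- canonical_int(min_scale, "min_scale")
    hi <- canonical_int(max_scale, "max_scale")
    if (length(lo) != 1L || length(hi) != 1L)
      stop("`min_scale` and `max_scale` must be single integers")
    if (lo >= hi) stop("`min_scale` must be strictly below `max_scale`")
    out <- list(
      alternatives = seq.int(lo, hi),
      size = hi - lo + 1L,
      numeric = TRUE,
      min_scale = lo,
      max_scale = hi
    )
  }
  structure(out, class = "rng_alphabet")
}

#' Named preset alphabets
#'
#' `"letters"` is the 26 lowercase letters in alphabetical order.
#'
#' @param name Preset name.
#' @return An `rng_alphabet`.
#' @export
alphabet_preset <- function(name = c("letters")) {
  name <- match.arg(name)
  switch(name, letters = alphabet(alternatives = letters))
}

#' Ordinal codes of tokens under an alphabet
#'
#' Maps each token to its 1-based position in the ordered alternatives; the
#' mapping is a bijection alternatives -> 1..a.
#'
#' @param tokens Token vector.
#' @param alph An `rng_alphabet`.
#' @return Integer vector of ordinals (NA for foreign tokens).
#' @export
ordinal <- function(tokens, alph) {
  stopifnot(inherits(alph, "rng_alphabet"))
  if (alph$numeric && !is.numeric(tokens))
    tokens <- suppressWarnings(as.integer(trimws(as.character(tokens))))
  match(if (is.numeric(tokens)) as.integer(tokens) else trimws(as.character(tokens)),
        alph$alternatives)
}

#' @export
print.rng_alphabet <- function(x, ...) {
  kind <- if (x$numeric) sprintf("numeric scale %d..%d", x$min_scale, x$max_scale)
          else "categorical"
  cat(sprintf("<alphabet: %d alternatives, %s>\n", x$size, kind))
  n_show <- min(x$size, 12L)
  shown <- paste(x$alternatives[seq_len(n_show)], collapse = " ")
  if (x$size > n_show) shown <- paste(shown, "...")
  cat(" ", shown, "\n")
  invisible(x)
}

# coerce to integer, rejecting non-integral or non-finite values
canonical_int <- function(x, what) {
  if (is.character(x)) {
    xi <- suppressWarnings(as.integer(trimws(x)))
    if (anyNA(xi)) stop("`", what, "` must be integer-valued")
    return(xi)
  }
  if (!is.numeric(x)) stop("`", what, "` must be numeric")
  if (any(!is.finite(x)) || any(x != round(x)))
    stop("`", what, "` must be integer-valued")
  as.integer(x)
}
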