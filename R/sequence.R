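#' Build a validated symbol sequence
#'
#' The single input object for every measure in the package: an ordered vector
#' of tokens over a declared finite alphabet. The alphabet is declared either
#' by a numeric scale (`min_scale`/`max_scale`) or by an explicit ordered set
#' of `alternatives`; exactly one of the two must be given. Numeric tokens are
#' canonicalized to integers; string tokens are trimmed and compared exactly.
#'
#' @param tokens Non-empty vector of responses.
#' @param min_scale,max_scale Integer scale bounds (numeric alphabets).
#' @param alternatives Ordered vector of allowed tokens (categorical
#'   alphabets).
#' @param alphabet An already-built [alphabet()] object (alternative to the
#'   previous three arguments).
#' @return An object of class `symbol_sequence` with fields `tokens`,
#'   `alphabet`, `n` and precomputed integer `ordinals`.
#' @examples
#' make_sequence(c(1, 2, 3), min_scale = 1, max_scale = 9)
#' make_sequence(c("head", "tail", "head"), alternatives = c("head", "tail"))
#' @export
make_sequence <- function(tokens, min_scale = NULL, max_scale = NULL,
                          alternatives = NULL, alphabet = NULL) {
  if (is.null(alphabet)) {
    alphabet <- alphabet(alternatives = alternatives,
                         min_scale = min_scale, max_scale = max_scale)
  } else {
    stopifnot(inherits(alphabet, "rng_alphabet"))
    if (!is.null(min_scale) || !is.null(max_scale) || !is.null(alternatives))
      stop("give either `alphabet` or a scale/alternatives spec, not both")
  }
  if (length(tokens) == 0L) stop("`tokens` must be non-empty")

  toks <- if (alphabet$numeric) {
    xi <- suppressWarnings(as.integer(trimws(as.character(tokens))))
    bad <- which(is.na(xi))
    if (length(bad))
      stop(sprintf("token '%s' at position %d is not a valid integer response",
                   as.character(tokens)[bad[1L]], bad[1L]))
    xi
  } else {
    trimws(as.character(tokens))
  }

  ords <- match(toks, alphabet$alternatives)
  bad <- which(is.na(ords))
  if (length(bad))
    stop(sprintf("token '%s' at position %d is outside the alphabet",
                 as.character(toks)[bad[1L]], bad[1L]))

  structure(
    list(tokens = toks, alphabet = alphabet, n = length(toks),
         ordinals = as.integer(ords)),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol sequence: n = %d over %d alternatives>\n",
              x$n, x$alphabet$size))
  n_show <- min(x$n, 20L)
  shown <- paste(x$tokens[seq_len(n_show)], collapse = " ")
  if (x$n > n_show) shown <- paste(shown, "...")
  cat(" ", shown, "\n")
  invisible(x)
}

#' Read raw sequences from a text or CSV file
#'
#' Each non-empty line holds one sequence; tokens are separated by commas or
#' whitespace. Returns raw token lists: pass each to [make_sequence()]
#' together with an alphabet to validate and canonicalize.
#'
#' @param path Path to a UTF-8 text file.
#' @param delimiter `"comma"`, `"whitespace"`, or `"auto"` (comma if the line
#'   contains one, whitespace otherwise).
#' @return List of character vectors, one per non-empty line, in file order.
#' @export
read_sequences <- function(path, delimiter = c("auto", "comma", "whitespace")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file contains no sequences: ", path)
  lapply(lines, function(ln) {
    sep <- switch(delimiter,
      comma = ",",
      whitespace = "[[:space:]]+",
      auto = if (grepl(",", ln, fixed = TRUE)) "," else "[[:space:]]+")
    toks <- trimws(strsplit(trimws(ln), sep)[[1L]])
    toks[nzchar(toks)]
  })
}
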