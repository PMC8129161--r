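# run expr with a private RNG state seeded by `seed`; the caller's
# .Random.seed is untouched, making seeded generators pure functions
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Build a frequency table
#'
#' A mapping key -> non-negative count, the common currency for digram
#' counts, first-order differences, phase lengths, repetition distances and
#' line-length histograms.
#'
#' @param keys Vector of observed keys (one entry per observation), or `NULL`
#'   for an empty table.
#' @param levels Optional full key set; keys absent from the observations get
#'   a zero count.
#' @return Named integer vector of class `freq_table` with attribute `total`.
#' @export
freq_table <- function(keys = NULL, levels = NULL) {
  if (is.null(keys) || length(keys) == 0L) {
    counts <- if (is.null(levels)) integer(0)
              else structure(integer(length(levels)), names = as.character(levels))
  } else {
    tab <- table(factor(as.character(keys),
                        levels = if (is.null(levels)) sort(unique(as.character(keys)))
                                 else as.character(levels)))
    counts <- structure(as.integer(tab), names = names(tab))
  }
  structure(counts, total = sum(counts), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<frequency table: %d keys, total %d>\n",
              length(x), attr(x, "total")))
  if (length(x)) print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# 0 * log2(0) == 0 convention used by every entropy-style sum
xlog2x <- function(x) ifelse(x > 0, x * log2(x), 0)

# marker for a measure that cannot be computed on this input; carries the
# reason so reports can log it, but is NA to every numeric consumer
not_computable <- function(reason) {
  structure(NA_real_, reason = reason, class = c("not_computable", "numeric"))
}

#' Test for a not-computable marker
#'
#' Measures that are undefined on an input (e.g. Coupon when an alternative
#' is never used) return an `NA` carrying the reason; they are never silently
#' reported as zero.
#'
#' @param x A measure value.
#' @return `TRUE` if `x` is a not-computable marker or `NA`.
#' @export
is_not_computable <- function(x) {
  inherits(x, "not_computable") || (is.atomic(x) && length(x) == 1L && is.na(x))
}

#' @export
print.not_computable <- function(x, ...) {
  cat("NA (not computable:", attr(x, "reason"), ")\n")
  invisible(x)
}

as_seq <- function(seq) {
  if (!inherits(seq, "symbol_sequence"))
    stop("expected a `symbol_sequence`; build one with make_sequence()")
  seq
}

check_mode <- function(mode) match.arg(mode, c("default", "classical"))
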