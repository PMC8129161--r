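#' RQA parameter set
#'
#' Parameters of the categorical auto-recurrence analysis. The defaults are
#' the recommended settings for nominal sequences: no embedding (`m = 1`,
#' `tau = 1`), minimal line length 2 for both orientations, and a radius
#' below 1 so that only exact symbol matches count as recurrent.
#'
#' @param m Embedding dimension (>= 1). Values above 1 delay-embed the
#'   ordinal codes; recurrence then requires all `m` coordinates to match.
#' @param tau Embedding delay (>= 1); only used when `m > 1`.
#' @param lmin Minimal diagonal line length (>= 2 recommended).
#' @param vmin Minimal vertical line length (>= 2 recommended).
#' @param radius Match radius; any value < 1 means exact categorical match.
#'   Values >= 1 are rejected: this engine is exact-match only.
#' @return Object of class `rqa_params`.
#' @export
rqa_params <- function(m = 1L, tau = 1L, lmin = 2L, vmin = 2L, radius = 0.1) {
  m <- canonical_int(m, "m"); tau <- canonical_int(tau, "tau")
  lmin <- canonical_int(lmin, "lmin"); vmin <- canonical_int(vmin, "vmin")
  if (m < 1L || tau < 1L) stop("`m` and `tau` must be >= 1")
  if (lmin < 1L || vmin < 1L) stop("`lmin` and `vmin` must be >= 1")
  if (!is.numeric(radius) || radius >= 1)
    stop("`radius` must be < 1: only exact categorical matches are supported")
  structure(list(m = m, tau = tau, lmin = lmin, vmin = vmin, radius = radius),
            class = "rqa_params")
}

#' Build a categorical auto-recurrence plot
#'
#' The N x N binary matrix marking every cell (i, j) where the response at
#' position j equals the response at position i (exact match on the ordinal
#' codes; with embedding `m > 1` all embedded coordinates must match). The
#' main diagonal — the trivial line of self-identity — is excluded.
#'
#' @param seq A `symbol_sequence`.
#' @param params An [rqa_params()].
#' @return Object of class `recurrence_plot`: `size` (N after embedding),
#'   logical `matrix` (diagonal all `FALSE`), `diagonal_excluded = TRUE`,
#'   and the `params` used.
#' @export
recurrence_matrix <- function(seq, params = rqa_params()) {
  seq <- as_seq(seq)
  stopifnot(inherits(params, "rqa_params"))
  o <- seq$ordinals
  if (params$m > 1L) {
    span <- (params$m - 1L) * params$tau
    if (seq$n <= span) stop("sequence too short for this embedding")
    nn <- seq$n - span
    emb <- vapply(seq_len(params$m),
                  function(k) o[seq_len(nn) + (k - 1L) * params$tau],
                  integer(nn))
    emb <- matrix(emb, nrow = nn)
    key <- apply(emb, 1L, paste, collapse = "\r")
    m <- outer(key, key, "==")
  } else {
    if (seq$n < 2L) stop("a recurrence plot needs N >= 2")
    m <- outer(o, o, "==")
  }
  diag(m) <- FALSE
  structure(list(size = nrow(m), matrix = m, diagonal_excluded = TRUE,
                 params = params),
            class = "recurrence_plot")
}

#' @export
print.recurrence_plot <- function(x, ...) {
  cat(sprintf("<recurrence plot: %d x %d, %d recurrent cells, diagonal excluded>\n",
              x$size, x$size, sum(x$matrix)))
  invisible(x)
}

#' Recurrence rate
#'
#' Proportion of recurrent cells in the plot: the count of off-diagonal
#' recurrent cells divided by N^2 (the main diagonal is excluded from the
#' count but N^2 remains the normalizer).
#'
#' @param rp A [recurrence_matrix()] result.
#' @return Numeric in `[0, (N^2 - N) / N^2]`.
#' @export
rr <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  sum(rp$matrix) / rp$size^2
}

#' Diagonal line-length histogram
#'
#' Counts of maximal runs of recurrent cells along directions parallel to
#' the main diagonal, over both triangles of the plot. The excluded main
#' diagonal never contributes. Every recurrent cell belongs to exactly one
#' maximal diagonal run, so `sum(length * count)` equals the number of
#' recurrent cells.
#'
#' @param rp A [recurrence_matrix()] result.
#' @return A [freq_table()] keyed by run length (class also
#'   `line_histogram`, attribute `orientation = "diagonal"`).
#' @export
diagonal_line_hist <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  n <- rp$size
  acc <- integer(n)
  for (k in seq_len(n - 1L)) {       # upper triangle offsets; mirror below
    v <- rp$matrix[cbind(seq_len(n - k), k + seq_len(n - k))]
    r <- rle(v)
    lens <- r$lengths[r$values]
    for (l in lens) acc[l] <- acc[l] + 1L
  }
  acc <- acc * 2L                    # lower triangle is the exact mirror
  line_hist_from_tabulation(acc, "diagonal")
}

#' Vertical line-length histogram
#'
#' Counts of maximal runs of consecutive recurrent rows within each column.
#' The excluded diagonal cell of a column splits runs that would otherwise
#' cross it.
#'
#' @param rp A [recurrence_matrix()] result.
#' @return A [freq_table()] keyed by run length (class also
#'   `line_histogram`, attribute `orientation = "vertical"`).
#' @export
vertical_line_hist <- function(rp) {
  stopifnot(inherits(rp, "recurrence_plot"))
  n <- rp$size
  acc <- integer(n)
  for (j in seq_len(n)) {
    r <- rle(rp$matrix[, j])
    lens <- r$lengths[r$values]
    for (l in lens) acc[l] <- acc[l] + 1L
  }
  line_hist_from_tabulation(acc, "vertical")
}

line_hist_from_tabulation <- function(acc, orientation) {
  lens <- which(acc > 0L)
  ft <- structure(stats::setNames(acc[lens], as.character(lens)),
                  total = sum(acc), orientation = orientation,
                  class = c("line_histogram", "freq_table"))
  ft
}

#' Categorical auto-RQA measures
#'
#' The nine recurrence-quantification measures for a nominal sequence:
#'
#' * `RR` — recurrence rate (off-diagonal recurrent cells / N^2);
#' * `DET`, `Lmax`, `Lmean`, `Lentr` — share of recurrent points on diagonal
#'   lines of length >= `lmin`, and the maximum, mean and Shannon entropy
#'   (natural log) of the diagonal line-length distribution restricted to
#'   lengths >= `lmin`;
#' * `LAM`, `Vmax`, `TT`, `Ventr` — the vertical-line analogues with
#'   threshold `vmin`; `TT` (trapping time) is the mean vertical line length.
#'
#' When no line reaches the threshold, `DET`/`LAM` are 0 and the
#' max/mean/entropy statistics are not-computable markers.
#'
#' @param seq A `symbol_sequence`.
#' @param params An [rqa_params()].
#' @return Object of class `rqa_result`: named list with the nine measures,
#'   the two histograms, `N`, and `params`.
#' @export
rqa_measures <- function(seq, params = rqa_params()) {
  rp <- recurrence_matrix(seq, params)
  dh <- diagonal_line_hist(rp)
  vh <- vertical_line_hist(rp)
  d <- line_stats(dh, params$lmin)
  v <- line_stats(vh, params$vmin)
  structure(
    list(RR = rr(rp),
         DET = d$prop, Lmax = d$max, Lmean = d$mean, Lentr = d$entr,
         LAM = v$prop, Vmax = v$max, TT = v$mean, Ventr = v$entr,
         diagonal_hist = dh, vertical_hist = vh,
         N = rp$size, params = params),
    class = "rqa_result"
  )
}

# proportion on lines >= min_len, plus max/mean/entropy of the >= min_len
# line-length distribution (natural log; point mass -> entropy 0)
line_stats <- function(hist, min_len) {
  lens <- as.integer(names(hist))
  cnts <- as.integer(hist)
  tot_points <- sum(lens * cnts)
  keep <- lens >= min_len
  la <- lens[keep]; ca <- cnts[keep]
  if (length(la) == 0L || tot_points == 0L) {
    return(list(prop = 0,
                max = not_computable("no line reaches the minimal length"),
                mean = not_computable("no line reaches the minimal length"),
                entr = not_computable("no line reaches the minimal length")))
  }
  p <- ca / sum(ca)
  list(prop = sum(la * ca) / tot_points,
       max = max(la),
       mean = sum(la * ca) / sum(ca),
       entr = -sum(p * log(p)) + 0)  # + 0 normalizes IEEE -0
}

#' @export
print.rqa_result <- function(x, digits = 3, ...) {
  cat(sprintf("<RQA measures: N = %d, lmin = %d, vmin = %d>\n",
              x$N, x$params$lmin, x$params$vmin))
  vals <- unlist(lapply(
    x[c("RR", "DET", "Lmax", "Lmean", "Lentr", "LAM", "Vmax", "TT", "Ventr")],
    function(v) if (is_not_computable(v)) NA_real_ else as.numeric(v)))
  print(round(vals, digits))
  invisible(x)
}
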