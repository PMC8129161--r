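#' Brute-force RQA reference implementation
#'
#' Recomputes all nine RQA measures by materializing the full N x N boolean
#' matrix token-by-token and scanning every diagonal and every column
#' cell-by-cell with explicit loops. It shares no code with
#' [rqa_measures()] and exists purely as an independent verification path;
#' intended for test-scale inputs (N <= 500).
#'
#' @param seq A `symbol_sequence`.
#' @param params An [rqa_params()] (only `m = 1`, `tau = 1` supported here).
#' @return A list with the nine measure values, named as in
#'   [rqa_measures()] (`NA` where not computable).
#' @export
rqa_oracle <- function(seq, params = rqa_params()) {
  seq <- as_seq(seq)
  stopifnot(inherits(params, "rqa_params"))
  if (params$m != 1L || params$tau != 1L)
    stop("the oracle supports the unembedded case only")
  toks <- seq$tokens
  n <- length(toks)
  if (n > 500L) stop("oracle is limited to N <= 500")

  # build the matrix one cell at a time
  mat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && identical(toks[i], toks[j])) mat[i, j] <- TRUE
    }
  }

  total <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (mat[i, j]) total <- total + 1L
  rr_val <- total / (n * n)

  # diagonal runs: walk every diagonal (offset != 0) cell by cell
  diag_lens <- integer(0)
  for (off in c(-(n - 1L):-1L, 1L:(n - 1L))) {
    if (off == 0L) next
    run <- 0L
    i_start <- max(1L, 1L - off)
    i_end <- min(n, n - off)
    for (i in i_start:i_end) {
      j <- i + off
      if (mat[i, j]) {
        run <- run + 1L
      } else if (run > 0L) {
        diag_lens <- c(diag_lens, run); run <- 0L
      }
    }
    if (run > 0L) diag_lens <- c(diag_lens, run)
  }

  # vertical runs: walk every column top to bottom
  vert_lens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      if (mat[i, j]) {
        run <- run + 1L
      } else if (run > 0L) {
        vert_lens <- c(vert_lens, run); run <- 0L
      }
    }
    if (run > 0L) vert_lens <- c(vert_lens, run)
  }

  summarize <- function(lens, thr, total_points) {
    keep <- lens[lens >= thr]
    if (length(keep) == 0L || total_points == 0L) {
      return(list(prop = 0, mx = NA_real_, mn = NA_real_, en = NA_real_))
    }
    tab <- table(keep)
    p <- as.numeric(tab) / sum(tab)
    list(prop = sum(keep) / total_points,
         mx = max(keep),
         mn = sum(keep) / length(keep),
         en = -sum(p * log(p)) + 0)
  }
  ds <- summarize(diag_lens, params$lmin, total)
  vs <- summarize(vert_lens, params$vmin, total)

  list(RR = rr_val,
       DET = ds$prop, Lmax = ds$mx, Lmean = ds$mn, Lentr = ds$en,
       LAM = vs$prop, Vmax = vs$mx, TT = vs$mn, Ventr = vs$en)
}
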