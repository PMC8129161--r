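# shared fixtures and small independent oracles for the test suite

digits9 <- alphabet(min_scale = 1, max_scale = 9)

# independent turning-point scan: collapse ties, count sign changes;
# written against the raw definition, not via the package internals
scan_turning_points <- function(x) {
  y <- x[c(TRUE, diff(x) != 0)]
  if (length(y) < 3L) return(0L)
  tp <- 0L
  for (i in 2:(length(y) - 1L)) {
    if ((y[i] - y[i - 1L]) * (y[i + 1L] - y[i]) < 0) tp <- tp + 1L
  }
  tp
}

# independent vertical-run scan over the exact-match matrix of a token vector
scan_vertical_runs <- function(tokens) {
  n <- length(tokens)
  lens <- integer(0)
  for (j in seq_len(n)) {
    run <- 0L
    for (i in seq_len(n)) {
      rec <- i != j && tokens[i] == tokens[j]
      if (rec) run <- run + 1L
      else if (run > 0L) { lens <- c(lens, run); run <- 0L }
    }
    if (run > 0L) lens <- c(lens, run)
  }
  lens
}

# independent redundancy: direct Shannon-entropy summation
shannon_redundancy <- function(counts, a) {
  n <- sum(counts)
  h <- 0
  for (ci in counts) if (ci > 0) h <- h + ci * log2(ci)
  1 - (log2(n) - h / n) / log2(a)
}

# distinct ordered adjacent pairs, by direct enumeration
count_distinct_digrams <- function(tokens) {
  n <- length(tokens)
  length(unique(paste(tokens[-n], tokens[-1L], sep = "|")))
}

rand_tokens <- function(n, a, seed) {
  set.seed(seed)
  sample.int(a, n, replace = TRUE)
}
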