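#' Null distribution of repeat counts at fixed distances
#'
#' Monte-Carlo reference for the phi indices: over `reps` seeded IID uniform
#' sequences of the same length and alphabet, the mean and standard
#' deviation of the number of repeats at exactly each distance in `lags`
#' (distances taken from the repetition-distance table). Computing the null
#' once and passing it to [phi_indices()] amortizes the simulation across
#' many sequences of the same shape.
#'
#' @param alph An [alphabet()].
#' @param n Sequence length.
#' @param lags Integer distances of interest (default 2..7).
#' @param reps Number of simulated sequences.
#' @param seed Integer seed for the simulation stream.
#' @return Object of class `phi_null`: list with `lags`, `mean`, `sd`, `n`,
#'   `alphabet_size`, `reps`.
#' @export
phi_null <- function(alph, n, lags = 2:7, reps = 1000L, seed = 1L) {
  stopifnot(inherits(alph, "rng_alphabet"))
  n <- canonical_int(n, "n")
  lags <- canonical_int(lags, "lags")
  reps <- canonical_int(reps, "reps")
  if (reps < 2L) stop("`reps` must be >= 2")
  sims <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      o <- sample.int(alph$size, n, replace = TRUE)
      repeat_counts(o, lags)
    }, numeric(length(lags)))
  })
  sims <- matrix(sims, nrow = length(lags))
  structure(
    list(lags = lags,
         mean = rowMeans(sims),
         sd = apply(sims, 1L, stats::sd),
         n = n, alphabet_size = alph$size, reps = reps),
    class = "phi_null"
  )
}

# number of repeats at exactly each distance in `lags` (distance to the most
# recent prior occurrence of the same symbol)
repeat_counts <- function(ordinals, lags) {
  idx <- split(seq_along(ordinals), ordinals)
  gaps <- unlist(lapply(idx, function(i) if (length(i) > 1L) diff(i)),
                 use.names = FALSE)
  if (is.null(gaps)) gaps <- integer(0)
  vapply(lags, function(g) sum(gaps == g), numeric(1))
}

#' Phi indices
#'
#' Standardized repeat-rate indices: for each distance `g`, the observed
#' number of repeats at exactly distance `g` is contrasted with its
#' expectation under IID uniform responding over the same alphabet and
#' length, as a z-score `(observed - E) / SD`. The index has mean 0 over
#' random sequences and is unbounded in both directions. The expectation and
#' scale are estimated by seeded Monte-Carlo simulation (see [phi_null()]);
#' identical in both output modes.
#'
#' @inheritParams redundancy
#' @param lags Integer distances (default 2..7).
#' @param reps Monte-Carlo replicates used when `null` is not supplied.
#' @param seed Seed for the Monte-Carlo stream.
#' @param null Optional precomputed [phi_null()] for this sequence shape.
#' @return Named numeric vector, one value per lag (`NA` marker for lags
#'   that are not computable, e.g. lag >= n or a degenerate null).
#' @export
phi_indices <- function(seq, lags = 2:7, reps = 1000L, seed = 1L,
                        mode = c("default", "classical"), null = NULL) {
  seq <- as_seq(seq); match.arg(mode)
  lags <- canonical_int(lags, "lags")
  if (any(lags < 1L)) stop("`lags` must be positive")
  if (is.null(null)) {
    null <- phi_null(seq$alphabet, seq$n, lags = lags, reps = reps, seed = seed)
  } else {
    stopifnot(inherits(null, "phi_null"))
    if (null$n != seq$n || null$alphabet_size != seq$alphabet$size)
      stop("`null` was computed for a different sequence shape")
    if (!all(lags %in% null$lags))
      stop("`null` does not cover all requested lags")
  }
  obs <- repeat_counts(seq$ordinals, lags)
  out <- stats::setNames(rep(NA_real_, length(lags)), paste0("phi", lags))
  for (k in seq_along(lags)) {
    if (lags[k] >= seq$n) next                      # no repeat can be that far
    j <- match(lags[k], null$lags)
    if (is.na(null$sd[j]) || null$sd[j] == 0) next  # degenerate null
    out[k] <- (obs[k] - null$mean[j]) / null$sd[j]
  }
  out
}
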