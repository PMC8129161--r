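#' Names of the randomization measure groups
#'
#' The measure-flag vocabulary accepted by [all_rng()] and the batch
#' interface.
#'
#' @return Character vector of measure names.
#' @export
rng_measure_names <- function() {
  c("Redundancy", "RNG", "RNG2", "NSQ", "RF", "Coupon", "FOD", "Adjacency",
    "TPI", "PhL", "Runs", "repDistance", "repGap", "PhiIndex")
}

#' Compute all randomization measures
#'
#' One call computing every enabled randomization measure for a sequence,
#' in either output convention. A measure that cannot be computed on this
#' input is reported as a not-computable marker (printed `NA`) and never
#' aborts the remaining measures; a disabled measure is absent from the
#' result.
#'
#' @inheritParams redundancy
#' @param enabled Character vector of measure names to compute (see
#'   [rng_measure_names()]); `"all"` enables everything.
#' @param phi_lags,phi_reps,phi_seed Parameters forwarded to [phi_indices()].
#' @param phi_null Optional precomputed [phi_null()] matching this
#'   sequence's shape.
#' @return Object of class `rng_result`: a named list of measure values
#'   (scalars, named vectors, or [freq_table()]s) plus attributes `mode` and
#'   `tp_observed`.
#' @export
all_rng <- function(seq, mode = c("default", "classical"), enabled = "all",
                    phi_lags = 2:7, phi_reps = 1000L, phi_seed = 1L,
                    phi_null = NULL) {
  seq <- as_seq(seq); mode <- match.arg(mode)
  valid <- rng_measure_names()
  if (identical(enabled, "all")) enabled <- valid
  bad <- setdiff(enabled, valid)
  if (length(bad))
    stop("unknown measure name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(valid, collapse = ", "))
  if (length(enabled) == 0L) stop("no measures enabled")

  grab <- function(f) {
    tryCatch(f(), error = function(e) not_computable(conditionMessage(e)))
  }
  out <- list()
  tp_obs <- NA_integer_
  for (m in enabled) {
    out[[m]] <- switch(m,
      Redundancy = grab(function() redundancy(seq, mode)),
      RNG = grab(function() rng_index(seq, mode)),
      RNG2 = grab(function() rng2_index(seq, mode)),
      NSQ = grab(function() nsq(seq, mode)),
      RF = grab(function() response_frequencies(seq)),
      Coupon = grab(function() coupon(seq, mode)),
      FOD = grab(function() fod_table(seq)),
      Adjacency = grab(function() adjacency(seq, mode)),
      TPI = grab(function() {
        tp_obs <<- turning_points(seq)
        tpi(seq, mode)
      }),
      PhL = grab(function() phase_lengths(seq)),
      Runs = grab(function() runs(seq, mode)),
      repDistance = grab(function() repetition_distances(seq)),
      repGap = grab(function() repetition_gap(seq, mode)),
      PhiIndex = grab(function() phi_indices(seq, lags = phi_lags,
                                             reps = phi_reps, seed = phi_seed,
                                             mode = mode, null = phi_null))
    )
  }
  structure(out, mode = mode, tp_observed = tp_obs, n = seq$n,
            class = "rng_result")
}

#' @export
print.rng_result <- function(x, digits = 3, ...) {
  cat(sprintf("<randomization measures: %s mode, n = %d>\n",
              attr(x, "mode"), attr(x, "n")))
  fmt <- function(v) {
    if (is_not_computable(v)) return("NA")
    paste(format(round(as.numeric(v), digits), nsmall = digits,
                 trim = TRUE), collapse = " ")
  }
  for (m in names(x)) {
    v <- x[[m]]
    if (inherits(v, "freq_table")) {
      cat(sprintf("  %-12s %s\n", m,
                  if (length(v) == 0L) "(empty)"
                  else paste(sprintf("%s:%d", names(v), as.integer(v)),
                             collapse = " ")))
    } else if (is.list(v)) {  # phase lengths
      asc <- v$ascending; desc <- v$descending
      cat(sprintf("  %-12s asc{%s} desc{%s}\n", m,
                  paste(sprintf("%s:%d", names(asc), as.integer(asc)),
                        collapse = " "),
                  paste(sprintf("%s:%d", names(desc), as.integer(desc)),
                        collapse = " ")))
    } else if (length(v) > 1L) {
      cat(sprintf("  %-12s %s\n", m,
                  paste(sprintf("%s=%s", names(v),
                                format(round(v, digits), nsmall = digits,
                                       trim = TRUE)),
                        collapse = " ")))
    } else {
      cat(sprintf("  %-12s %s\n", m, fmt(v)))
    }
  }
  invisible(x)
}
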