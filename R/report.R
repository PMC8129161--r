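#' Build a batch run configuration
#'
#' Validated configuration for [run_batch()]: where to read sequences, how
#' to interpret them, which measures to compute, and how to write results.
#' Exactly one alphabet specification must be given: a numeric
#' `min_scale`/`max_scale` pair, an explicit `alternatives` vector, or a
#' named `preset` (currently `"letters"`).
#'
#' @param input Path to the input file (one sequence per line).
#' @param min_scale,max_scale Numeric scale bounds.
#' @param alternatives Ordered vector of response alternatives.
#' @param preset Named preset alphabet (`"letters"`).
#' @param mode Output convention: `"default"` (modern proportions) or
#'   `"classical"` (legacy percentages with wrapped RNG digrams).
#' @param measures Character vector of randomization measure names (see
#'   [rng_measure_names()]), `"all"`, or `character(0)` to disable
#'   randomization output entirely (requires `rqa = TRUE`).
#' @param rqa Also compute the nine RQA measures?
#' @param rqa_params An [rqa_params()].
#' @param delimiter Token delimiter (`"auto"`, `"comma"`, `"whitespace"`).
#' @param format Output file format: `"csv"` or `"json"`.
#' @param out Output path, or `NULL` to only return results.
#' @param plot_dir Directory for per-sequence recurrence-plot images, or
#'   `NULL`.
#' @param seed Seed for the phi-index resampling stream.
#' @param phi_reps Monte-Carlo replicates for the phi indices.
#' @param verbose Emit progress messages?
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, min_scale = NULL, max_scale = NULL,
                       alternatives = NULL, preset = NULL,
                       mode = c("default", "classical"),
                       measures = "all", rqa = FALSE,
                       rqa_params = rngtask::rqa_params(),
                       delimiter = c("auto", "comma", "whitespace"),
                       format = c("csv", "json"), out = NULL,
                       plot_dir = NULL, seed = 1L, phi_reps = 1000L,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  delimiter <- match.arg(delimiter)
  format <- match.arg(format)
  specs <- c(!is.null(min_scale) || !is.null(max_scale),
             !is.null(alternatives), !is.null(preset))
  if (sum(specs) != 1L)
    stop("exactly one alphabet spec is required: min/max scale, ",
         "alternatives, or preset")
  alph <- if (!is.null(preset)) alphabet_preset(preset)
          else alphabet(alternatives = alternatives,
                        min_scale = min_scale, max_scale = max_scale)
  if (identical(measures, "all")) measures <- rng_measure_names()
  bad <- setdiff(measures, rng_measure_names())
  if (length(bad)) stop("unknown measure name(s): ", paste(bad, collapse = ", "))
  if (length(measures) == 0L && !rqa)
    stop("nothing to compute: no measures enabled and RQA disabled")
  stopifnot(inherits(rqa_params, "rqa_params"))
  structure(
    list(input = input, alphabet = alph, mode = mode, measures = measures,
         rqa = rqa, rqa_params = rqa_params, delimiter = delimiter,
         format = format, out = out, plot_dir = plot_dir,
         seed = canonical_int(seed, "seed"),
         phi_reps = canonical_int(phi_reps, "phi_reps"), verbose = verbose),
    class = "run_config"
  )
}

#' Run the full measurement suite over a file of sequences
#'
#' Reads every sequence in the input file, computes the enabled
#' randomization measures (long table: one row per sequence, measure and
#' component, mirroring the classic measure-by-sequence layout) and
#' optionally the nine RQA measures (wide table: one row per sequence), and
#' writes CSV or JSON output. A malformed line or a not-computable measure
#' is recorded and never aborts the remaining sequences. Tabular CSV values
#' are rendered to 3 decimals (round half to even); JSON keeps full
#' precision. Re-running an identical configuration is byte-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `randomization` and `rqa` data frames,
#'   `errors` (per-line failure messages), `log` (run description lines),
#'   and `files` (paths written).
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  raw <- read_sequences(config$input, delimiter = config$delimiter)
  log <- c(sprintf("input: %s (%d sequences)", config$input, length(raw)),
           sprintf("alphabet: %d alternatives", config$alphabet$size),
           sprintf("mode: %s; seed: %d", config$mode, config$seed),
           sprintf("measures: %s", paste(config$measures, collapse = ",")),
           sprintf("rqa: %s", config$rqa))
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("%s", paste(log, collapse = "\n"))

  # phi nulls are a function of (n, a) only; share them across same-length
  # sequences so a batch does not redo the resampling per line
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(n) {
    key <- as.character(n)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- phi_null(config$alphabet, n, lags = 2:7,
                                    reps = config$phi_reps, seed = config$seed)
    null_cache[[key]]
  }

  rng_rows <- list(); rqa_rows <- list(); errors <- character(0)
  for (k in seq_along(raw)) {
    id <- sprintf("seq%d", k)
    res <- tryCatch({
      s <- make_sequence(raw[[k]], alphabet = config$alphabet)
      out <- list()
      if (length(config$measures)) {
        need_phi <- "PhiIndex" %in% config$measures
        out$rng <- all_rng(s, mode = config$mode, enabled = config$measures,
                           phi_reps = config$phi_reps, phi_seed = config$seed,
                           phi_null = if (need_phi) get_null(s$n))
      }
      if (config$rqa) out$rqa <- rqa_measures(s, config$rqa_params)
      if (!is.null(config$plot_dir)) {
        dir.create(config$plot_dir, showWarnings = FALSE, recursive = TRUE)
        render_plot(recurrence_matrix(s, config$rqa_params),
                    file = file.path(config$plot_dir, paste0(id, ".png")))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("%s: %s", id, conditionMessage(res))
      errors <- c(errors, msg)
      log <- c(log, paste("error:", msg))
      say("skipping %s", msg)
      next
    }
    if (!is.null(res$rng)) rng_rows[[id]] <- rng_result_rows(id, res$rng)
    if (!is.null(res$rqa)) rqa_rows[[id]] <- rqa_result_row(id, res$rqa)
  }

  rng_df <- if (length(rng_rows)) do.call(rbind, rng_rows) else NULL
  rqa_df <- if (length(rqa_rows)) do.call(rbind, rqa_rows) else NULL
  if (!is.null(rng_df)) rownames(rng_df) <- NULL
  if (!is.null(rqa_df)) rownames(rqa_df) <- NULL

  files <- write_outputs(config, rng_df, rqa_df, log)
  invisible(list(randomization = rng_df, rqa = rqa_df, errors = errors,
                 log = log, files = files))
}

# flatten an rng_result into rows: sequence, measure, component, value
rng_result_rows <- function(id, res) {
  rows <- list()
  add <- function(measure, component, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sequence = id, measure = measure, component = component,
      value = if (is_not_computable(value)) NA_real_ else as.numeric(value),
      stringsAsFactors = FALSE)
  }
  for (m in names(res)) {
    v <- res[[m]]
    if (inherits(v, "freq_table")) {
      if (length(v) == 0L) add(m, "(empty)", NA_real_)
      else for (k in seq_along(v)) add(m, names(v)[k], as.integer(v)[k])
    } else if (is.list(v)) {  # phase lengths
      for (side in c("ascending", "descending")) {
        ft <- v[[side]]
        if (length(ft) == 0L) add(m, paste0(side, ":(empty)"), NA_real_)
        else for (k in seq_along(ft))
          add(m, paste0(side, ":", names(ft)[k]), as.integer(ft)[k])
      }
    } else if (length(v) > 1L) {
      for (k in seq_along(v)) add(m, names(v)[k], v[k])
    } else {
      add(m, "", v)
    }
  }
  do.call(rbind, rows)
}

rqa_result_row <- function(id, res) {
  vals <- lapply(
    res[c("RR", "DET", "Lmax", "Lmean", "Lentr", "LAM", "Vmax", "TT", "Ventr")],
    function(v) if (is_not_computable(v)) NA_real_ else as.numeric(v))
  data.frame(sequence = id,
             RR = vals$RR, DET = vals$DET, Lmax = vals$Lmax, L = vals$Lmean,
             Lentr = vals$Lentr, LAM = vals$LAM, Vmax = vals$Vmax,
             TT = vals$TT, Ventr = vals$Ventr, stringsAsFactors = FALSE)
}

write_outputs <- function(config, rng_df, rqa_df, log) {
  if (is.null(config$out)) return(character(0))
  files <- character(0)
  if (config$format == "json") {
    payload <- list(
      config = list(mode = config$mode, seed = config$seed,
                    measures = config$measures, rqa = config$rqa),
      log = log,
      randomization = rng_df,
      rqa = rqa_df
    )
    jsonlite::write_json(payload, config$out, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
    files <- config$out
  } else {
    render3 <- function(df) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) {
        vapply(x, function(v) {
          if (is.na(v)) return(NA_character_)
          if (v == round(v)) format(v, trim = TRUE, scientific = FALSE)
          else format(round(v, 3), nsmall = 3, trim = TRUE, scientific = FALSE)
        }, character(1))
      })
      df
    }
    targets <- c(rng = NA_character_, rqa = NA_character_)
    both <- !is.null(rng_df) && !is.null(rqa_df)
    stem_for <- function(tag) {
      if (!both) return(config$out)
      sub("(\\.[A-Za-z0-9]+)?$", paste0("_", tag, "\\1"), config$out)
    }
    if (!is.null(rng_df)) {
      targets["rng"] <- stem_for("rng")
      utils::write.csv(render3(rng_df), targets["rng"], row.names = FALSE,
                       quote = TRUE, na = "NA")
    }
    if (!is.null(rqa_df)) {
      targets["rqa"] <- stem_for("rqa")
      utils::write.csv(render3(rqa_df), targets["rqa"], row.names = FALSE,
                       quote = TRUE, na = "NA")
    }
    files <- targets[!is.na(targets)]
  }
  files
}

#' Compute a single measure from raw tokens
#'
#' Convenience wrapper matching the per-measure helpers of the batch
#' interface: builds the sequence and computes exactly one named measure
#' with the same semantics as [all_rng()] restricted to it. RQA measure
#' names (`"rqa"`) run the nine-measure RQA set.
#'
#' @param name Measure name (case-insensitive; one of
#'   [rng_measure_names()] or `"rqa"`).
#' @param tokens Token vector (or a `symbol_sequence`).
#' @inheritParams make_sequence
#' @inheritParams redundancy
#' @param ... Extra arguments forwarded to the measure (e.g. `lags`,
#'   `reps`, `seed` for the phi indices; `params` for RQA).
#' @return The measure value.
#' @export
single_measure <- function(name, tokens, min_scale = NULL, max_scale = NULL,
                           alternatives = NULL, mode = c("default", "classical"),
                           ...) {
  mode <- match.arg(mode)
  s <- if (inherits(tokens, "symbol_sequence")) tokens
       else make_sequence(tokens, min_scale = min_scale,
                          max_scale = max_scale, alternatives = alternatives)
  key <- tolower(name)
  valid <- c(tolower(rng_measure_names()), "rqa")
  if (!key %in% valid)
    stop("unknown measure '", name, "'; valid names: ",
         paste(c(rng_measure_names(), "rqa"), collapse = ", "))
  switch(key,
    redundancy = redundancy(s, mode),
    rng = rng_index(s, mode),
    rng2 = rng2_index(s, mode),
    nsq = nsq(s, mode),
    rf = response_frequencies(s),
    coupon = coupon(s, mode),
    fod = fod_table(s),
    adjacency = adjacency(s, mode),
    tpi = tpi(s, mode),
    phl = phase_lengths(s),
    runs = runs(s, mode),
    repdistance = repetition_distances(s),
    repgap = repetition_gap(s, mode),
    phiindex = phi_indices(s, mode = mode, ...),
    rqa = rqa_measures(s, ...)
  )
}
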