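#' Render a recurrence plot
#'
#' Draws or prints the square recurrence structure, position 1..N on both
#' axes, symmetric about the main diagonal. `format = "text"` produces an
#' ASCII grid (`#` marks a recurrent cell, `.` a non-recurrent one), one row
#' per sequence position from position N (top) down to 1; graphical formats
#' are chosen from the file extension (`.png` or `.pdf`).
#'
#' @param rp A [recurrence_matrix()] result.
#' @param file Output path, or `NULL` to return/print without writing. A
#'   `.png`/`.pdf` extension selects a graphical device; anything else (or
#'   `NULL` with `format = "text"`) writes the text grid.
#' @param format `"text"` or `"image"`; default inferred from `file`.
#' @return Invisibly, the character vector of grid rows (text) or the file
#'   path (image).
#' @export
render_plot <- function(rp, file = NULL, format = NULL) {
  stopifnot(inherits(rp, "recurrence_plot"))
  if (is.null(format)) {
    format <- if (!is.null(file) && grepl("\\.(png|pdf)$", file, ignore.case = TRUE))
      "image" else "text"
  }
  format <- match.arg(format, c("text", "image"))
  if (format == "text") {
    n <- rp$size
    rows <- vapply(rev(seq_len(n)), function(i) {
      paste(ifelse(rp$matrix[i, ], "#", "."), collapse = "")
    }, character(1))
    if (!is.null(file)) {
      ok <- tryCatch({ writeLines(rows, file); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) stop("cannot write plot to ", file)
    }
    return(invisible(rows))
  }
  if (is.null(file)) stop("image rendering needs a `file` path")
  opener <- if (grepl("\\.pdf$", file, ignore.case = TRUE)) {
    function(f) grDevices::pdf(f, width = 6, height = 6)
  } else {
    function(f) grDevices::png(f, width = 600, height = 600)
  }
  ok <- tryCatch({ opener(file); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot open graphics device for ", file)
  on.exit(grDevices::dev.off())
  plot.recurrence_plot(rp)
  invisible(file)
}

#' Plot method for recurrence plots
#'
#' @param x A `recurrence_plot`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.recurrence_plot <- function(x, ...) {
  n <- x$size
  idx <- which(x$matrix, arr.ind = TRUE)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0.5, n + 0.5),
                 xlab = "position", ylab = "position", asp = 1, ...)
  if (nrow(idx)) graphics::points(idx[, 2L], idx[, 1L], pch = 15,
                                  cex = max(0.2, 30 / n))
  invisible(x)
}
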