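#' Build a polyline trace
#'
#' A trace is the hand-trace surrogate: an ordered polyline in pixel
#' coordinates starting at the soma edge and following one neurite outward.
#' Traces are plain tibbles so that several neurons can be stacked in one
#' table and round-tripped through CSV.
#'
#' @param x,y Numeric vectors of vertex coordinates in pixels (0-based,
#'   pixel-center convention).
#' @param neuron_id Identifier for the traced cell.
#' @param localization_class One of `"direct"`, `"acd"`, `"multi"` — the
#'   per-neuron AIS localization annotation noted at tracing time.
#' @return A tibble with columns `neuron_id`, `vertex_index`, `x_px`, `y_px`,
#'   `localization_class`.
#' @export
#' @examples
#' polyline_trace(c(0, 5, 10), c(2, 2, 4), "cell1", "direct")
polyline_trace <- function(x, y, neuron_id, localization_class = "direct") {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  tr <- tibble(
    neuron_id = as.character(neuron_id),
    vertex_index = seq_along(x),
    x_px = as.numeric(x),
    y_px = as.numeric(y),
    localization_class = match.arg(localization_class, LOCALIZATION_CLASSES)
  )
  validate_trace(tr)
  tr
}

#' Validate a single-neuron trace
#'
#' Checks the polyline invariants: at least two vertices, consecutive
#' vertices distinct, positive total length.
#'
#' @param trace A trace tibble for one neuron (see [polyline_trace()]).
#' @return The trace, invisibly, if valid; otherwise an error.
#' @export
validate_trace <- function(trace) {
  need <- c("x_px", "y_px")
  if (!all(need %in% names(trace))) {
    abort("A trace needs `x_px` and `y_px` columns.")
  }
  if ("neuron_id" %in% names(trace) && length(unique(trace$neuron_id)) > 1) {
    abort("`trace` must describe a single neuron; got multiple `neuron_id`s.")
  }
  if (nrow(trace) < 2) {
    abort("A trace needs at least 2 vertices.")
  }
  if ("vertex_index" %in% names(trace)) {
    trace <- trace[order(trace$vertex_index), ]
  }
  dx <- diff(trace$x_px)
  dy <- diff(trace$y_px)
  dup <- which(dx == 0 & dy == 0)
  if (length(dup) > 0) {
    abort(paste0(
      "Degenerate trace: consecutive identical vertices at position(s) ",
      paste(dup, collapse = ", "), "."
    ))
  }
  invisible(trace)
}

#' Arc length of a trace
#'
#' @param trace A single-neuron trace tibble.
#' @param pixel_size Pixel size in micrometres per pixel; if omitted the
#'   length is returned in pixels.
#' @return Total polyline length.
#' @export
trace_arc_length <- function(trace, pixel_size = 1) {
  trace <- validate_trace(trace)
  sum(sqrt(diff(trace$x_px)^2 + diff(trace$y_px)^2)) * pixel_size
}

#' Read and write trace tables
#'
#' CSV schema: `neuron_id`, `vertex_index`, `x_px`, `y_px`,
#' `localization_class`, one row per vertex. Multiple neurons may share one
#' file.
#'
#' @param path File path.
#' @return `read_traces_csv()` returns the traces tibble.
#' @export
read_traces_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_traces_csv
#' @param traces Traces tibble.
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(traces, path, progress = FALSE)
  invisible(path)
}
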