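#' Per-cell fluorescence trace container
#'
#' Couples a table of cell metadata with a matrix of fluorescence intensities
#' (one row per cell, one column per frame) on a shared, strictly increasing
#' time axis in seconds from the cavitation event. Both the synthetic
#' generator and the image-stack extractor produce this container, so either
#' source can feed the kinetics module.
#'
#' @param cells Tibble of per-cell metadata; must contain `cell_id`.
#' @param time_s Numeric vector of frame times, s; strictly increasing.
#' @param intensities Numeric matrix, `nrow(cells)` x `length(time_s)`, AU.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(cells, time_s, intensities) {
  cells <- tibble::as_tibble(cells)
  if (!"cell_id" %in% names(cells)) stop("`cells` must contain a `cell_id` column", call. = FALSE)
  intensities <- as.matrix(intensities)
  if (length(time_s) >= 2 && any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  if (nrow(intensities) != nrow(cells)) {
    stop("`intensities` must have one row per cell", call. = FALSE)
  }
  if (ncol(intensities) != length(time_s)) {
    stop("`intensities` must have one column per frame time", call. = FALSE)
  }
  structure(list(cells = cells, time_s = as.numeric(time_s), intensities = intensities),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d cells x %d frames (t = %.3g .. %.3g s)\n",
              nrow(x$cells), length(x$time_s),
              if (length(x$time_s)) min(x$time_s) else NA,
              if (length(x$time_s)) max(x$time_s) else NA))
  invisible(x)
}

#' Number of cells in a trace set
#' @param traces A [trace_set()].
#' @return Integer count.
#' @export
n_cells <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  nrow(traces$cells)
}

#' Write / read per-cell traces as wide CSV
#'
#' The wide schema is shared between the synthetic generator and the image
#' extractor: metadata columns (`cell_id`, `x_um`, `y_um`, `gamma`, and any
#' ground-truth columns) followed by one column per frame named `t_<seconds>`.
#'
#' @param traces A [trace_set()].
#' @param path Output CSV path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [trace_set()].
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  wide <- data.table::as.data.table(traces$cells)
  mat <- data.table::as.data.table(traces$intensities)
  data.table::setnames(mat, sprintf("t_%g", traces$time_s))
  data.table::fwrite(cbind(wide, mat), path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  dt <- data.table::fread(path)
  is_frame <- grepl("^t_", names(dt))
  if (!any(is_frame)) stop("no frame columns (t_<seconds>) found in ", path, call. = FALSE)
  time_s <- as.numeric(sub("^t_", "", names(dt)[is_frame]))
  trace_set(cells = tibble::as_tibble(dt[, !is_frame, with = FALSE]),
            time_s = time_s,
            intensities = as.matrix(dt[, is_frame, with = FALSE]))
}

#' Subset a trace set by row index
#' @param traces A [trace_set()].
#' @param idx Integer or logical row index into the cells.
#' @return A [trace_set()] with the selected cells.
#' @export
subset_traces <- function(traces, idx) {
  stopifnot(inherits(traces, "trace_set"))
  trace_set(traces$cells[idx, , drop = FALSE], traces$time_s,
            traces$intensities[idx, , drop = FALSE])
}
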