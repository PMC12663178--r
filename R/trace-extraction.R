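#' Register a stack to its final frame
#'
#' Translation-only registration removing passive sample drift: each frame is
#' shifted by the integer offset that maximizes its cross-correlation with the
#' final frame (computed via FFT), with the search capped at `max_shift`
#' pixels in each direction. Vacated pixels are zero-filled. Frames with no
#' signal (zero variance) are left unshifted with a warning, and a warning is
#' issued when the unconstrained correlation peak falls outside the cap.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param max_shift Maximum allowed shift, px.
#' @return The registered [image_stack()]; the applied shifts (rows `dy`,
#'   `dx` per frame) are attached as attribute `"shifts"`.
#' @export
register_stack <- function(stack, max_shift = 10L) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$frames)[3]
  if (nf < 2) stop("registration needs at least 2 frames", call. = FALSE)
  ref <- stack$frames[, , nf]
  fref <- stats::fft(ref)
  shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  out <- stack$frames
  for (i in seq_len(nf - 1L)) {
    fr <- stack$frames[, , i]
    if (stats::sd(fr) == 0) {
      warning(sprintf("frame %d has no signal; registered with zero shift", i))
      next
    }
    cc <- Re(stats::fft(fref * Conj(stats::fft(fr)), inverse = TRUE))
    s <- best_shift(cc, max_shift)
    if (s$capped) {
      warning(sprintf("frame %d: correlation peak beyond max_shift = %d px; shift capped", i, max_shift))
    }
    shifts[i, ] <- c(s$dy, s$dx)
    out[, , i] <- translate_zero(fr, s$dy, s$dx)
  }
  res <- stack
  res$frames <- out
  attr(res, "shifts") <- shifts
  res
}

# pick the in-window argmax of a circular cross-correlation surface;
# window is the set of shifts with |dy|,|dx| <= max_shift
best_shift <- function(cc, max_shift) {
  ny <- nrow(cc); nx <- ncol(cc)
  wrap <- function(idx, n) ifelse(idx > n / 2, idx - n, idx)
  peak <- arrayInd(which.max(cc), dim(cc))
  g_dy <- wrap(peak[1] - 1L, ny); g_dx <- wrap(peak[2] - 1L, nx)
  dy_all <- wrap(seq_len(ny) - 1L, ny)
  dx_all <- wrap(seq_len(nx) - 1L, nx)
  ok_r <- abs(dy_all) <= max_shift
  ok_c <- abs(dx_all) <= max_shift
  sub <- cc[ok_r, ok_c, drop = FALSE]
  p <- arrayInd(which.max(sub), dim(sub))
  list(dy = dy_all[ok_r][p[1]], dx = dx_all[ok_c][p[2]],
       capped = abs(g_dy) > max_shift || abs(g_dx) > max_shift)
}

# integer translation with zero fill: result[y, x] = m[y - dy, x - dx]
translate_zero <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Subtract the first frame as background
#'
#' The initial frame (acquired just after the mirror flips back, before
#' appreciable dye uptake) estimates the static background; it is subtracted
#' from every frame and negative differences are clamped to zero. The first
#' frame itself becomes identically zero.
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @return The background-subtracted [image_stack()].
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (dim(stack$frames)[3] < 2) stop("background subtraction needs at least 2 frames", call. = FALSE)
  bg <- stack$frames[, , 1]
  out <- stack
  for (i in seq_len(dim(stack$frames)[3])) {
    out$frames[, , i] <- pmax(stack$frames[, , i] - bg, 0)
  }
  out
}

#' Mask autofluorescent beads
#'
#' The magnetic beads used to nucleate the bubble autofluoresce in the PI
#' detection band and must be excluded from ROI measurements. Connected
#' components of pixels above `intensity_min` whose area exceeds `area_min`
#' are masked; both conditions must hold (bright-but-small and
#' large-but-dim objects are kept). Apply to a raw (pre-subtraction) frame,
#' since bead autofluorescence is static and vanishes after background
#' subtraction.
#'
#' @param frame 2D intensity matrix, AU.
#' @param area_min Minimum component area, um^2 (exclusive).
#' @param intensity_min Minimum intensity, AU (exclusive).
#' @param pixel_size um/px.
#' @return A `bead_mask`: list with `mask` (logical matrix) and `components`
#'   (tibble `label`, `area_um2`, `peak_AU`, `x_um`, `y_um` of the excluded
#'   components).
#' @export
mask_beads <- function(frame, area_min = 5, intensity_min = 15000,
                       pixel_size = 223.5 / 1024) {
  check_positive(area_min, "area_min")
  check_positive(intensity_min, "intensity_min")
  check_positive(pixel_size, "pixel_size")
  bin <- frame > intensity_min
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(frame), ncol(frame))
  mask <- matrix(FALSE, nrow(frame), ncol(frame))
  comps <- list()
  if (max(lab) > 0) {
    areas_px <- tabulate(lab[lab > 0L])
    for (l in which(areas_px * pixel_size^2 > area_min)) {
      pix <- lab == l
      mask[pix] <- TRUE
      idx <- which(pix, arr.ind = TRUE)
      comps[[length(comps) + 1L]] <- tibble::tibble(
        label = l,
        area_um2 = areas_px[l] * pixel_size^2,
        peak_AU = max(frame[pix]),
        x_um = (mean(idx[, 2]) - 0.5) * pixel_size,
        y_um = (mean(idx[, 1]) - 0.5) * pixel_size
      )
    }
  }
  components <- if (length(comps)) do.call(rbind, comps) else {
    tibble::tibble(label = integer(), area_um2 = numeric(), peak_AU = numeric(),
                   x_um = numeric(), y_um = numeric())
  }
  structure(list(mask = mask, components = components), class = "bead_mask")
}

#' Extract per-cell fluorescence traces from a registered stack
#'
#' For every label in the cell mask, measures the ROI intensity in each frame
#' (mean over ROI pixels by default, matching the AU scale of typical ROI
#' measurements; `"sum"` gives integrated intensity) after removing pixels
#' covered by the bead mask. Cells whose ROI lies entirely inside the bead
#' mask are dropped with a message. Cell positions are ROI centroids at pixel
#' centers, converted to um.
#'
#' @param stack A registered, background-subtracted [image_stack()].
#' @param cell_mask Integer label matrix (0 = background); defaults to
#'   `stack$cell_labels`.
#' @param bead_mask Optional [mask_beads()] result.
#' @param statistic `"mean"` or `"sum"` over ROI pixels.
#' @return A [trace_set()] with cells ordered by label.
#' @export
extract_cell_traces <- function(stack, cell_mask = stack$cell_labels,
                                bead_mask = NULL,
                                statistic = c("mean", "sum")) {
  stopifnot(inherits(stack, "image_stack"))
  statistic <- match.arg(statistic)
  if (is.null(cell_mask)) stop("a labeled `cell_mask` is required", call. = FALSE)
  d <- dim(stack$frames)
  if (!all(dim(cell_mask) == d[1:2])) stop("`cell_mask` size must match frames", call. = FALSE)
  drop_pix <- if (!is.null(bead_mask)) {
    stopifnot(inherits(bead_mask, "bead_mask"))
    as.vector(bead_mask$mask)
  } else rep(FALSE, d[1] * d[2])
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  labels <- sort(unique(as.vector(cell_mask[cell_mask > 0L])))
  rows <- list()
  traces <- list()
  for (l in labels) {
    pix <- which(as.vector(cell_mask == l) & !drop_pix)
    if (!length(pix)) {
      message(sprintf("cell %d fully inside bead mask; dropped", l))
      next
    }
    v <- flat[pix, , drop = FALSE]
    traces[[length(traces) + 1L]] <- if (statistic == "mean") colMeans(v) else colSums(v)
    rr <- ((pix - 1L) %% d[1]) + 1L
    cc <- ((pix - 1L) %/% d[1]) + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      cell_id = l,
      x_um = (mean(cc) - 0.5) * stack$pixel_size,
      y_um = (mean(rr) - 0.5) * stack$pixel_size
    )
  }
  if (!length(rows)) {
    return(trace_set(tibble::tibble(cell_id = integer(), x_um = numeric(), y_um = numeric()),
                     stack$time_s,
                     matrix(numeric(), 0, d[3])))
  }
  trace_set(do.call(rbind, rows), stack$time_s, do.call(rbind, traces))
}

#' Compute radial distance and gamma for cell records
#'
#' Adds `l_cell` (Euclidean distance from the cavitation center, um) and
#' `gamma = l_cell / R_max` to the cell table of a trace set (or to any data
#' frame with `x_um`, `y_um` columns). The cavitation center defaults to the
#' midpoint of the field of view.
#'
#' @param records A [trace_set()] or data frame with `x_um`, `y_um`.
#' @param center Numeric length-2, cavitation center (x, y) in um.
#' @param R_max Maximum bubble radius, um.
#' @return Same type as `records`, with `l_cell` and `gamma` columns added.
#' @export
compute_gamma <- function(records, center, R_max = 29.7) {
  check_positive(R_max, "R_max")
  if (length(center) != 2L || !is.numeric(center)) {
    stop("`center` must be numeric length 2 (x, y) in um", call. = FALSE)
  }
  add <- function(df) {
    df$l_cell <- sqrt((df$x_um - center[1])^2 + (df$y_um - center[2])^2)
    df$gamma <- df$l_cell / R_max
    df
  }
  if (inherits(records, "trace_set")) {
    records$cells <- add(records$cells)
    records
  } else {
    add(records)
  }
}

#' Keep cells within a gamma radius of the cavitation center
#'
#' The analysis region is the disc gamma <= `gamma_max` (inclusive) around
#' the cavitation center; outside it uptake is indistinguishable from
#' background.
#'
#' @param records A [trace_set()] or data frame with a `gamma` column.
#' @param gamma_max Inclusive upper bound on gamma.
#' @return Filtered object of the same type.
#' @export
filter_region <- function(records, gamma_max = 3) {
  check_nonneg(gamma_max, "gamma_max")
  if (inherits(records, "trace_set")) {
    if (!"gamma" %in% names(records$cells)) stop("run compute_gamma() first", call. = FALSE)
    subset_traces(records, records$cells$gamma <= gamma_max)
  } else {
    if (!"gamma" %in% names(records)) stop("`records` must have a `gamma` column", call. = FALSE)
    records[records$gamma <= gamma_max, , drop = FALSE]
  }
}
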