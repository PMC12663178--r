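#' Fluorescence image-stack container
#'
#' Frames are stored as a 3D array `[row, col, frame]` of non-negative
#' intensities in AU, with pixel size in um/px and the frame time axis in
#' seconds. An optional brightfield companion frame and a labeled cell mask
#' (integer labels, 0 = background) support downstream ROI extraction.
#'
#' @param frames 3D numeric array, `[row, col, frame]`, AU.
#' @param pixel_size um per pixel.
#' @param time_s Frame times, s (length = number of frames).
#' @param brightfield Optional matrix, same spatial size.
#' @param cell_labels Optional integer label matrix, same spatial size.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, time_s, brightfield = NULL,
                        cell_labels = NULL) {
  check_positive(pixel_size, "pixel_size")
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L) stop("`frames` must be a 3D array", call. = FALSE)
  if (dim(frames)[3] != length(time_s)) {
    stop("frame count must equal length of `time_s`", call. = FALSE)
  }
  if (any(frames < 0)) stop("frame intensities must be non-negative", call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 time_s = as.numeric(time_s), brightfield = brightfield,
                 cell_labels = cell_labels),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d x %d px, %d frames, %.4g um/px\n", d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

# linear pixel indices (into an ny x nx matrix) of a capsule-shaped cell
# footprint: segment of half-length hl with cap radius r, centered at
# (x0, y0) um at angle theta. Pixel centers at ((col-0.5), (row-0.5)) * ps.
capsule_pixels <- function(x0, y0, theta, length_um, width_um, ps, ny, nx) {
  r <- width_um / 2
  hl <- max(length_um / 2 - r, 0)
  ux <- cos(theta); uy <- sin(theta)
  reach <- hl + r
  cmin <- max(1L, floor((x0 - reach) / ps)); cmax <- min(nx, ceiling((x0 + reach) / ps) + 1L)
  rmin <- max(1L, floor((y0 - reach) / ps)); rmax <- min(ny, ceiling((y0 + reach) / ps) + 1L)
  if (cmin > cmax || rmin > rmax) return(integer())
  cols <- cmin:cmax; rows <- rmin:rmax
  px <- (rep(cols, each = length(rows)) - 0.5) * ps
  py <- (rep(rows, times = length(cols)) - 0.5) * ps
  # distance from pixel center to the capsule spine segment
  t <- pmin(pmax((px - x0) * ux + (py - y0) * uy, -hl), hl)
  d2 <- (px - (x0 + t * ux))^2 + (py - (y0 + t * uy))^2
  inside <- d2 <= r^2
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * ny + rr
}

disc_pixels <- function(x0, y0, radius_um, ps, ny, nx) {
  capsule_pixels(x0, y0, 0, 2 * radius_um, 2 * radius_um, ps, ny, nx)
}

#' Render a synthetic fluorescence stack from a cell field and traces
#'
#' Paints every cell as a rod-shaped (capsule) footprint of the given length
#' and width at a random orientation, distributing each frame's trace value
#' uniformly over the footprint so the summed ROI intensity per frame equals
#' the trace value up to rasterization. Beads are painted as bright discs in
#' every frame (they autofluoresce above the bead-masking threshold). The
#' brightfield companion marks cell footprints dark on a bright background,
#' and the ground-truth labeled cell mask is returned alongside (automated
#' segmentation is out of scope; the reference analysis drew ROIs manually).
#' Overlapping footprints have their fluorescence summed; the label mask keeps
#' the lowest cell id on contested pixels.
#'
#' @param field A [generate_cell_field()] result.
#' @param traces A [trace_set()] whose cells match `field$positions` row
#'   order (e.g. built via [assign_ground_truth()] + [simulate_traces()]).
#' @param pixel_size um/px (default: 223.5 um over 1024 px).
#' @param bead_intensity Bead fluorescence, AU (constant across frames).
#' @param cell_length_um,cell_width_um Rod footprint dimensions, um.
#' @param seed Optional seed for the random orientations.
#' @return An [image_stack()] with `brightfield` and `cell_labels` filled in.
#' @export
render_stack <- function(field, traces, pixel_size = 223.5 / 1024,
                         bead_intensity = 20000,
                         cell_length_um = 2, cell_width_um = 1, seed = NULL) {
  stopifnot(inherits(field, "cell_field"), inherits(traces, "trace_set"))
  check_positive(pixel_size, "pixel_size")
  with_seed(seed, {
    npx <- max(1L, as.integer(round(field$fov_size / pixel_size)))
    ny <- npx; nx <- npx
    nf <- length(traces$time_s)
    n <- nrow(field$positions)
    if (n != n_cells(traces)) stop("field and traces disagree on cell count", call. = FALSE)
    flat <- matrix(0, ny * nx, nf)
    labels <- integer(ny * nx)
    theta <- stats::runif(n, 0, pi)
    for (i in seq_len(n)) {
      pix <- capsule_pixels(field$positions$x_um[i], field$positions$y_um[i],
                            theta[i], cell_length_um, cell_width_um,
                            pixel_size, ny, nx)
      if (!length(pix)) next
      flat[pix, ] <- flat[pix, ] + matrix(traces$intensities[i, ] / length(pix),
                                          length(pix), nf, byrow = TRUE)
      unset <- labels[pix] == 0L
      labels[pix[unset]] <- traces$cells$cell_id[i]
    }
    bright <- matrix(1000, ny, nx)
    bright[labels > 0L] <- 500
    for (j in seq_len(nrow(field$beads))) {
      pix <- disc_pixels(field$beads$x_um[j], field$beads$y_um[j],
                         field$beads$radius_um[j], pixel_size, ny, nx)
      if (!length(pix)) next
      flat[pix, ] <- flat[pix, ] + bead_intensity
      bright[pix] <- 3000
    }
    image_stack(frames = array(flat, c(ny, nx, nf)), pixel_size = pixel_size,
                time_s = traces$time_s, brightfield = bright,
                cell_labels = matrix(labels, ny, nx))
  })
}

#' Write / read an image stack as 16-bit multi-page TIFF with a JSON sidecar
#'
#' Intensities are linearly mapped to the 16-bit range; the scale factor,
#' pixel size and time axis are recorded in `<path>.json` so the round trip
#' recovers AU values. The brightfield frame and label mask, when present, go
#' to `<path>_brightfield.tif` and `<path>_labels.tif`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_image_stack()` returns `path` invisibly; `read_image_stack()`
#'   returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  top <- max(stack$frames, 1)
  pages <- lapply(seq_along(stack$time_s), function(i) stack$frames[, , i] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  sidecar <- list(pixel_size_um = stack$pixel_size, time_s = stack$time_s,
                  intensity_scale_AU = top)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(stack$brightfield)) {
    tiff::writeTIFF(stack$brightfield / max(stack$brightfield, 1),
                    sub("\\.tiff?$", "_brightfield.tif", path), bits.per.sample = 16)
  }
  if (!is.null(stack$cell_labels)) {
    tiff::writeTIFF(stack$cell_labels / 65535,
                    sub("\\.tiff?$", "_labels.tif", path), bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]] * sidecar$intensity_scale_AU
  lab_path <- sub("\\.tiff?$", "_labels.tif", path)
  labels <- if (file.exists(lab_path)) {
    matrix(as.integer(round(tiff::readTIFF(lab_path) * 65535)),
           dim(pages[[1]])[1], dim(pages[[1]])[2])
  }
  image_stack(frames = frames, pixel_size = sidecar$pixel_size_um,
              time_s = sidecar$time_s, cell_labels = labels)
}

#' Read a labeled cell mask from TIFF
#'
#' 16-bit label images as written by [write_image_stack()]; label 0 is
#' background.
#' @param path TIFF path.
#' @return Integer matrix of labels.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
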