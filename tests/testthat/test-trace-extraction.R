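base_frame <- function(seed = 1, n = 48) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[15:20, 22:28] <- 500
  m[30:34, 10:13] <- 900
  m
}

test_that("registration recovers known integer shifts", {
  ref <- base_frame()
  offsets <- rbind(c(2, -3), c(-4, 1), c(0, 5))
  frames <- array(0, c(48, 48, 4))
  for (i in 1:3) {
    frames[, , i] <- piuptake:::translate_zero(ref, offsets[i, 1], offsets[i, 2])
  }
  frames[, , 4] <- ref
  st <- image_stack(frames, pixel_size = 0.25, time_s = 1:4)
  reg <- register_stack(st)
  shifts <- attr(reg, "shifts")
  # recovered shifts are the negatives of the applied offsets
  expect_equal(unname(shifts[1:3, ]), unname(-offsets))
  for (i in 1:3) expect_equal(reg$frames[, , i], ref)
})

test_that("registration is idempotent and handles degenerate frames", {
  ref <- base_frame()
  frames <- array(rep(ref, 3), c(48, 48, 3))
  st <- image_stack(frames, pixel_size = 0.25, time_s = 1:3)
  reg <- register_stack(st)
  expect_equal(unname(attr(reg, "shifts")), matrix(0L, 3, 2))
  expect_equal(reg$frames, st$frames)
  # an empty frame registers with zero shift and a warning
  frames[, , 1] <- 0
  st2 <- image_stack(frames, pixel_size = 0.25, time_s = 1:3)
  expect_warning(reg2 <- register_stack(st2), "no signal")
  expect_equal(unname(attr(reg2, "shifts")[1, ]), c(0L, 0L))
  # a frame shifted beyond the cap is capped, with a warning
  frames[, , 1] <- piuptake:::translate_zero(ref, 14, 0)
  st3 <- image_stack(frames, pixel_size = 0.25, time_s = 1:3)
  expect_warning(reg3 <- register_stack(st3, max_shift = 10), "capped")
  expect_true(all(abs(attr(reg3, "shifts")) <= 10))
  expect_error(register_stack(image_stack(array(0, c(4, 4, 1)),
                                          0.25, 1)), "2 frames")
})

test_that("background subtraction removes the first frame and clamps at zero", {
  n <- 8
  f0 <- matrix(runif(n^2, 0, 100), n, n)
  frames <- array(0, c(n, n, 4))
  for (i in 1:4) frames[, , i] <- f0 + (i - 1) * 5
  st <- subtract_background(image_stack(frames, 0.25, 1:4))
  for (i in 1:4) expect_equal(st$frames[, , i], matrix(5 * (i - 1), n, n))
  # constant stack maps to all zeros; negative differences clamp to 0
  const <- subtract_background(image_stack(array(7, c(4, 4, 3)), 0.25, 1:3))
  expect_true(all(const$frames == 0))
  dec <- array(0, c(4, 4, 2)); dec[, , 1] <- 10; dec[, , 2] <- 3
  expect_true(all(subtract_background(image_stack(dec, 0.25, 1:2))$frames == 0))
})

test_that("bead masking requires both area and intensity thresholds", {
  ps <- 0.25
  paint_disc <- function(frame, x, y, r, value) {
    pix <- piuptake:::disc_pixels(x, y, r, ps, nrow(frame), ncol(frame))
    frame[pix] <- value
    frame
  }
  frame <- matrix(0, 120, 120)
  frame <- paint_disc(frame, 6, 6, 1.5, 20000)    # bead: big and bright
  frame <- paint_disc(frame, 15, 15, 0.7, 20000)  # small and bright
  frame <- paint_disc(frame, 24, 24, 1.8, 1000)   # big and dim
  bm <- mask_beads(frame, area_min = 5, intensity_min = 15000, pixel_size = ps)
  expect_s3_class(bm, "bead_mask")
  expect_identical(nrow(bm$components), 1L)
  expect_gt(bm$components$area_um2, 5)
  expect_gt(bm$components$peak_AU, 15000)
  expect_true(bm$mask[round(6 / ps), round(6 / ps)])
  expect_false(bm$mask[round(15 / ps), round(15 / ps)])
  expect_false(bm$mask[round(24 / ps), round(24 / ps)])
})

test_that("bead masking is conjunctive over random component geometries", {
  ps <- 0.5
  set.seed(42)
  for (rep in 1:5) {
    frame <- matrix(0, 160, 160)
    centers <- expand.grid(x = c(12, 32, 52, 72), y = c(12, 32, 52, 72))
    radius <- runif(16, 0.4, 2.4)           # area 0.5 .. 18 um^2
    value <- sample(c(1000, 20000), 16, replace = TRUE)
    for (i in 1:16) {
      pix <- piuptake:::disc_pixels(centers$x[i], centers$y[i], radius[i],
                                    ps, 160, 160)
      frame[pix] <- value[i]
    }
    bm <- mask_beads(frame, pixel_size = ps)
    for (i in 1:16) {
      pix <- piuptake:::disc_pixels(centers$x[i], centers$y[i], radius[i],
                                    ps, 160, 160)
      should <- value[i] > 15000 && length(pix) * ps^2 > 5
      expect_identical(unname(all(bm$mask[pix])), should)
    }
  }
})

test_that("extraction yields one ordered trace per labeled ROI", {
  fx <- make_rendered_fixture(seed = 31, n_frames = 6)
  st <- fx$stack
  ex <- extract_cell_traces(st, st$cell_labels, statistic = "sum")
  expect_identical(ex$cells$cell_id, sort(unique(as.vector(
    st$cell_labels[st$cell_labels > 0]))))
  # centroids land within a pixel of the generating positions
  idx <- match(ex$cells$cell_id, fx$truth$cell_id)
  expect_lt(max(abs(ex$cells$x_um - fx$truth$x_um[idx])), 0.5)
  expect_lt(max(abs(ex$cells$y_um - fx$truth$y_um[idx])), 0.5)
  # empty mask gives an empty record list
  ex0 <- extract_cell_traces(st, matrix(0L, dim(st$frames)[1], dim(st$frames)[2]))
  expect_identical(n_cells(ex0), 0L)
  # an ROI fully inside the bead mask is dropped
  full_mask <- structure(list(
    mask = matrix(TRUE, dim(st$frames)[1], dim(st$frames)[2]),
    components = data.frame()), class = "bead_mask")
  expect_message(exd <- extract_cell_traces(st, st$cell_labels, full_mask),
                 "dropped")
  expect_identical(n_cells(exd), 0L)
})

test_that("gamma computation and the region filter follow the definitions", {
  df <- data.frame(cell_id = 1:3,
                   x_um = c(50, 53, 50 + 29.7),
                   y_um = c(50, 54, 50))
  out <- compute_gamma(df, center = c(50, 50), R_max = 29.7)
  expect_equal(out$l_cell, c(0, 5, 29.7))     # 3-4-5 triangle for cell 2
  expect_equal(out$gamma, c(0, 5 / 29.7, 1))  # cell at R_max has gamma = 1
  recs <- data.frame(gamma = c(0.5, 3.0, 3.1))
  expect_equal(filter_region(recs, 3)$gamma, c(0.5, 3.0))  # inclusive bound
  expect_identical(nrow(filter_region(recs[0, , drop = FALSE], 3)), 0L)
  expect_equal(nrow(filter_region(data.frame(gamma = c(0, 1)), 0)), 1L)
  # gamma is invariant to pixel size given consistent um coordinates
  out2 <- compute_gamma(df, center = c(50, 50), R_max = 29.7)
  expect_identical(out$gamma, out2$gamma)
})

test_that("rendered stack round trip recovers generated traces", {
  fx <- make_rendered_fixture(seed = 41, n_frames = 10)
  st <- fx$stack
  bm <- mask_beads(st$frames[, , 1], pixel_size = st$pixel_size)
  ex <- extract_cell_traces(st, st$cell_labels, bm, statistic = "sum")
  idx <- match(ex$cells$cell_id, fx$traces$cells$cell_id)
  gen <- fx$traces$intensities[idx, , drop = FALSE]
  rel <- abs(ex$intensities - gen) / pmax(gen, 1)
  expect_lt(max(rel), 0.02)
})

test_that("trace CSV round trip preserves the trace set", {
  fx <- make_small_cohort(seed = 9, density = 0.005, fov = 60, n_frames = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(fx$traces, path)
  back <- read_trace_csv(path)
  expect_equal(back$time_s, fx$traces$time_s)
  expect_equal(back$intensities, fx$traces$intensities, ignore_attr = TRUE)
  expect_equal(as.data.frame(back$cells), as.data.frame(fx$traces$cells),
               ignore_attr = TRUE)
})
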