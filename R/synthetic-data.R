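#' Generate a synthetic field of surface-attached cells
#'
#' Places cells in a square field of view by a spatial Poisson process: the
#' cell count is Poisson with mean `density * fov_size^2` and positions are
#' uniform. One autofluorescent bead (the nucleation bead) is always placed at
#' the field center, where the cavitation bubble collapses; additional beads
#' are scattered uniformly. Defaults reproduce the imaged preparation:
#' 0.28 cells/um^2 on a 223.5 um field of view.
#'
#' @param density Planar cell density, cells/um^2.
#' @param fov_size Side of the square field of view, um.
#' @param n_beads Number of beads (>= 1; the first is the nucleation bead at
#'   the center).
#' @param bead_radius Bead radius, um (3 um diameter beads by default).
#' @param seed Optional integer seed; identical seeds give identical fields.
#' @return A `cell_field`: list with `positions` (tibble `x_um`, `y_um`),
#'   `fov_size`, `density`, `beads` (tibble `x_um`, `y_um`, `radius_um`) and
#'   `seed`.
#' @export
#' @examples
#' field <- generate_cell_field(density = 0.05, fov_size = 50, seed = 1)
#' nrow(field$positions)
generate_cell_field <- function(density = 0.28, fov_size = 223.5, n_beads = 1,
                                bead_radius = 1.5, seed = NULL) {
  check_nonneg(density, "density")
  check_positive(fov_size, "fov_size")
  check_positive(bead_radius, "bead_radius")
  if (n_beads < 0) stop("`n_beads` must be >= 0", call. = FALSE)
  with_seed(seed, {
    n <- stats::rpois(1L, density * fov_size^2)
    positions <- tibble::tibble(
      x_um = stats::runif(n, 0, fov_size),
      y_um = stats::runif(n, 0, fov_size)
    )
    beads <- if (n_beads >= 1L) {
      tibble::tibble(
        x_um = c(fov_size / 2, stats::runif(n_beads - 1L, 0, fov_size)),
        y_um = c(fov_size / 2, stats::runif(n_beads - 1L, 0, fov_size)),
        radius_um = rep(bead_radius, n_beads)
      )
    } else {
      tibble::tibble(x_um = numeric(), y_um = numeric(), radius_um = numeric())
    }
    structure(
      list(positions = positions, fov_size = fov_size, density = density,
           beads = beads, seed = seed),
      class = "cell_field"
    )
  })
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("Synthetic cell field: %d cells on %.1f x %.1f um (%.3g cells/um^2), %d bead(s)\n",
              nrow(x$positions), x$fov_size, x$fov_size, x$density, nrow(x$beads)))
  invisible(x)
}

#' Assign ground-truth uptake parameters to a cell field
#'
#' Computes each cell's normalized distance gamma from the cavitation center
#' (the field midpoint), evaluates the generating radial law there, adds
#' optional per-cell Gaussian scatter to the plateau intensity, and draws a
#' per-cell first-order rate constant k from a truncated normal distribution.
#' Draws below `k_floor` are redrawn so every k is physically positive.
#'
#' Cells numerically at the center are clamped to `gamma_min` (closest
#' analyzable cells in the reference experiment sit near gamma = 0.14, so the
#' clamp only guards the degenerate gamma = 0 case). An optional detachment
#' annulus removes cells with gamma < `detach_gamma`, emulating the zone of
#' cells stripped off by the collapse jet.
#'
#' @param field A [generate_cell_field()] result.
#' @param law Generating [radial_law()].
#' @param k_mean,k_sd Mean and sd of the rate-constant distribution, 1/s.
#' @param R_max Maximum bubble radius, um, used to normalize distances.
#' @param i_final_sd Per-cell Gaussian sd of the plateau intensity, AU.
#' @param gamma_min Lower clamp on gamma.
#' @param k_floor Redraw threshold for k, 1/s.
#' @param detach_gamma If non-`NULL`, drop cells with gamma < this value.
#' @param seed Optional integer seed.
#' @return Tibble with `cell_id`, `x_um`, `y_um`, `gamma`, `I_final_law`
#'   (the noiseless law value), `I_final_true` (with per-cell scatter,
#'   floored at 0) and `k_true`.
#' @export
assign_ground_truth <- function(field, law = radial_law(),
                                k_mean = 0.0046, k_sd = 0.0018,
                                R_max = 29.7, i_final_sd = 50,
                                gamma_min = 0.05, k_floor = 1e-5,
                                detach_gamma = NULL, seed = NULL) {
  stopifnot(inherits(field, "cell_field"), inherits(law, "radial_law"))
  check_positive(k_mean, "k_mean")
  check_nonneg(k_sd, "k_sd")
  check_positive(R_max, "R_max")
  check_nonneg(i_final_sd, "i_final_sd")
  check_positive(gamma_min, "gamma_min")
  with_seed(seed, {
    cx <- field$fov_size / 2
    cy <- field$fov_size / 2
    x <- field$positions$x_um
    y <- field$positions$y_um
    l_cell <- sqrt((x - cx)^2 + (y - cy)^2)
    gamma <- pmax(l_cell / R_max, gamma_min)
    n <- length(gamma)
    k_true <- stats::rnorm(n, k_mean, k_sd)
    # redraw non-physical rates (truncated normal by rejection)
    while (any(bad <- k_true < k_floor)) {
      k_true[bad] <- stats::rnorm(sum(bad), k_mean, k_sd)
    }
    i_law <- if (n > 0) predict(law, gamma) else numeric()
    i_true <- pmax(i_law + stats::rnorm(n, 0, i_final_sd), 0)
    truth <- tibble::tibble(
      cell_id = seq_len(n), x_um = x, y_um = y, gamma = gamma,
      I_final_law = i_law, I_final_true = i_true, k_true = k_true
    )
    if (!is.null(detach_gamma)) truth <- truth[truth$gamma >= detach_gamma, , drop = FALSE]
    attr(truth, "law") <- law
    attr(truth, "R_max") <- R_max
    truth
  })
}

#' Simulate per-cell fluorescence traces
#'
#' Evaluates the first-order saturation curve
#' I(t) = I_final_true (1 - exp(-k_true t)) on a uniform frame grid and adds
#' additive Gaussian measurement noise, floored at zero. Time is measured from
#' the cavitation event; the first fluorescence frame is acquired after
#' `delay` seconds (mirror rotation back to the fluorescence camera).
#'
#' @param truth Ground-truth tibble from [assign_ground_truth()] (needs
#'   columns `cell_id`, `I_final_true`, `k_true`; positional/gamma columns are
#'   carried through when present).
#' @param dt Frame interval, s.
#' @param n_frames Number of frames (>= 2).
#' @param delay Acquisition delay after cavitation, s.
#' @param noise_sd Additive Gaussian noise sd, AU.
#' @param seed Optional integer seed.
#' @return A [trace_set()].
#' @export
simulate_traces <- function(truth, dt = 0.5, n_frames = 1300, delay = 3,
                            noise_sd = 20, seed = NULL) {
  check_positive(dt, "dt")
  check_nonneg(delay, "delay")
  check_nonneg(noise_sd, "noise_sd")
  if (n_frames < 2) stop("`n_frames` must be >= 2", call. = FALSE)
  stopifnot(all(c("cell_id", "I_final_true", "k_true") %in% names(truth)))
  with_seed(seed, {
    time_s <- delay + (seq_len(n_frames) - 1) * dt
    n <- nrow(truth)
    clean <- truth$I_final_true * (1 - exp(-outer(truth$k_true, time_s)))
    noisy <- clean + matrix(stats::rnorm(n * n_frames, 0, noise_sd), n, n_frames)
    noisy <- pmax(noisy, 0)
    keep <- intersect(c("cell_id", "x_um", "y_um", "gamma", "I_final_true", "k_true"),
                      names(truth))
    trace_set(cells = tibble::as_tibble(truth[, keep, drop = FALSE]),
              time_s = time_s, intensities = noisy)
  })
}
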