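#' Default pipeline configuration
#'
#' All tunable parameters of the staged analysis with their reference-
#' experiment defaults, as a nested list: `mode` (one of `"synthetic"`,
#' `"stack"`, `"traces"`), `seed`, `synthetic` (generator settings),
#' `extraction` (registration/masking/ROI settings), `kinetics` and `model`.
#' Configurations loaded from YAML are validated against this template:
#' unknown keys are rejected.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "synthetic",
    seed = 1L,
    input = list(traces_csv = NULL, stack_tif = NULL, mask_tif = NULL),
    synthetic = list(
      density = 0.28, fov_size = 223.5, n_beads = 1, bead_radius = 1.5,
      a_AU = 321, b_AU = 228, k_mean = 0.0046, k_sd = 0.0018,
      R_max = 29.7, i_final_sd = 50, gamma_min = 0.05, k_floor = 1e-5,
      detach_gamma = NULL,
      dt = 0.5, n_frames = 1300, delay = 3, noise_sd = 20,
      n_cells = NULL  # optional subsample size after the gamma filter
    ),
    extraction = list(
      pixel_size = 223.5 / 1024, max_shift = 10, statistic = "mean",
      bead_area_min = 5, bead_intensity_min = 15000
    ),
    kinetics = list(start_k = 0.01, gamma_max = 3, n_sigma = 3),
    model = list(
      I_100 = 2500, n_gamma = 60, n_t = 121,
      c0 = 6e-5, dPhi_m = 0.125, z = 2, T = 300, D = 1e-12, L = 50e-9,
      h0 = 2e-6, a_cell = 2e-6, r_e = 0.5e-6, rho = 0.275e12, beta = 0.41,
      R_max = 29.7e-6, T_obs = 600, k1 = 0.011
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(defaults)) stop("unknown config key: ", full, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], full)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) file and layers it over [default_config()];
#' unknown keys raise an error so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML/JSON file, or `NULL` for pure defaults.
#' @param overrides Optional named list layered on top (e.g. from CLI flags).
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  if (!cfg$mode %in% c("synthetic", "stack", "traces")) {
    stop("`mode` must be one of synthetic/stack/traces", call. = FALSE)
  }
  cfg
}

goldman_params_from_config <- function(m) {
  goldman_params(c0 = m$c0, dPhi_m = m$dPhi_m, z = m$z, T = m$T, D = m$D,
                 L = m$L, h0 = m$h0, a_cell = m$a_cell, r_e = m$r_e,
                 rho = m$rho, beta = m$beta, R_max = m$R_max,
                 T_obs = m$T_obs, k1 = m$k1)
}

#' Generate the synthetic reference cohort
#'
#' Convenience wrapper running the full generator chain under one seed:
#' cell field, ground truth, gamma filter, optional subsampling to a fixed
#' cohort size, and trace simulation.
#'
#' @param cfg A configuration list (see [default_config()]); only the
#'   `synthetic` and `kinetics$gamma_max` entries are used.
#' @param seed Integer seed for the whole chain.
#' @return List with `field`, `truth` (filtered), and `traces`.
#' @export
synthesize_cohort <- function(cfg = default_config(), seed = cfg$seed) {
  s <- cfg$synthetic
  law <- radial_law(s$a_AU, s$b_AU)
  field <- generate_cell_field(s$density, s$fov_size, s$n_beads, s$bead_radius,
                               seed = seed)
  truth <- assign_ground_truth(field, law, s$k_mean, s$k_sd, s$R_max,
                               s$i_final_sd, s$gamma_min, s$k_floor,
                               s$detach_gamma, seed = seed + 1L)
  truth <- filter_region(truth, cfg$kinetics$gamma_max)
  if (!is.null(s$n_cells) && nrow(truth) > s$n_cells) {
    with_seed(seed + 2L, {
      truth <- truth[sort(sample.int(nrow(truth), s$n_cells)), , drop = FALSE]
    })
  }
  traces <- simulate_traces(truth, s$dt, s$n_frames, s$delay, s$noise_sd,
                            seed = seed + 3L)
  list(field = field, truth = truth, traces = traces)
}

#' Run the staged analysis pipeline
#'
#' Executes the pipeline for the configured mode — `synthetic` (generate a
#' cohort), `traces` (read a wide trace CSV) or `stack` (read a TIFF stack +
#' labeled mask, register, subtract background, mask beads, extract) — then
#' fits per-cell saturation kinetics, summarizes the rate-constant
#' population, fits the radial law, and evaluates the Goldman field map.
#' Writes into `out_dir`: `resolved_config.yaml`, `traces.csv`, `fits.csv`,
#' `summary.json`, `fields.csv`, and figures (`fig_radial.pdf`,
#' `fig_k_hist.pdf`, `fig_single_cell.pdf`, `fig_fields.pdf`), plus a
#' `run.log` recording seeds and versions.
#'
#' @param config Configuration list from [load_config()].
#' @param out_dir Output directory (created if missing).
#' @param figures Write figures (default `TRUE`).
#' @return Invisibly, a list with the main results and output paths.
#' @export
run_pipeline <- function(config = load_config(), out_dir, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logf, append = TRUE)
    message(msg)
  }
  cat("", file = logf)
  log_line("piuptake %s | mode=%s seed=%s | R %s",
           as.character(utils::packageVersion("piuptake")),
           config$mode, config$seed, getRversion())

  traces <- switch(
    config$mode,
    synthetic = {
      coh <- synthesize_cohort(config, config$seed)
      log_line("synthetic cohort: %d cells (gamma <= %g)",
               n_cells(coh$traces), config$kinetics$gamma_max)
      coh$traces
    },
    traces = {
      p <- config$input$traces_csv
      if (is.null(p) || !file.exists(p)) stop("traces mode requires input$traces_csv", call. = FALSE)
      read_trace_csv(p)
    },
    stack = {
      p <- config$input$stack_tif
      if (is.null(p) || !file.exists(p)) stop("stack mode requires input$stack_tif", call. = FALSE)
      stack <- read_image_stack(p)
      mask <- if (!is.null(config$input$mask_tif)) read_label_mask(config$input$mask_tif) else stack$cell_labels
      if (is.null(mask)) stop("stack mode requires a labeled cell mask", call. = FALSE)
      beads <- mask_beads(stack$frames[, , 1],
                          config$extraction$bead_area_min,
                          config$extraction$bead_intensity_min,
                          stack$pixel_size)
      log_line("masked %d bead component(s)", nrow(beads$components))
      reg <- register_stack(stack, config$extraction$max_shift)
      sub <- subtract_background(reg)
      ts <- extract_cell_traces(sub, mask, beads, config$extraction$statistic)
      fov <- dim(stack$frames)[1] * stack$pixel_size
      ts <- compute_gamma(ts, center = c(fov / 2, fov / 2),
                          R_max = config$synthetic$R_max)
      filter_region(ts, config$kinetics$gamma_max)
    }
  )

  if (!"gamma" %in% names(traces$cells)) {
    stop("traces lack a `gamma` column; positions or gamma are required", call. = FALSE)
  }

  fits <- fit_uptake(traces, config$kinetics$start_k)
  pop <- population_k_stats(fits, config$kinetics$n_sigma)
  law <- fit_radial_law(fits$gamma[fits$converged], fits$I_final[fits$converged])
  rate <- initial_rate_vs_final(fits)
  log_line("fits: %d/%d converged; mean k = %.4g 1/s (sd %.4g), tau = %.4g s",
           sum(fits$converged), nrow(fits), pop$mean_k, pop$sd_k, pop$tau_char)
  log_line("radial law: a = %.4g AU, b = %.4g AU (R^2 = %.3f)",
           law$a_AU, law$b_AU, law$r_squared)

  params <- goldman_params_from_config(config$model)
  fields <- compute_field_map(
    params, k = pop$mean_k, law = law,
    gamma = seq(max(config$synthetic$gamma_min, 0.14), config$kinetics$gamma_max,
                length.out = config$model$n_gamma),
    t_s = seq(0, params$T_obs, length.out = config$model$n_t),
    I_100 = config$model$I_100)

  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  write_trace_csv(traces, file.path(out_dir, "traces.csv"))
  data.table::fwrite(fits, file.path(out_dir, "fits.csv"))
  summary <- list(
    n_cells = nrow(fits), n_converged = sum(fits$converged),
    mean_k = pop$mean_k, sd_k = pop$sd_k, tau_char = pop$tau_char,
    n_used = pop$n_used, n_excluded = pop$n_excluded,
    radial_a_AU = law$a_AU, radial_b_AU = law$b_AU,
    radial_r_squared = law$r_squared,
    rate_slope = rate$slope,
    k2 = calibrate_k2(params, derive_constants(params, pop$mean_k)),
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  export_field_maps(fields, file.path(out_dir, "fields.csv"))
  if (figures) {
    save_fig(plot_radial_law(fits, law), file.path(out_dir, "fig_radial.pdf"))
    save_fig(plot_k_histogram(fits, pop), file.path(out_dir, "fig_k_hist.pdf"))
    save_fig(plot_single_cell(traces, fits), file.path(out_dir, "fig_single_cell.pdf"))
    save_fig(plot_field_map(fields), file.path(out_dir, "fig_fields.pdf"), width = 9)
  }
  log_line("outputs written to %s", normalizePath(out_dir))
  invisible(list(traces = traces, fits = fits, population = pop, law = law,
                 rate = rate, fields = fields, summary = summary,
                 out_dir = out_dir))
}

#' Export a field map as long-format CSV
#'
#' @param fields A `field_map` tibble from [compute_field_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_field_maps <- function(fields, path) {
  if (!nrow(fields)) stop("empty field map", call. = FALSE)
  data.table::fwrite(fields, path)
  invisible(path)
}
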