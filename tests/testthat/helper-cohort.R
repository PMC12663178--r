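# Fixture builders shared across test files. Everything is generated in code
# under fixed seeds; no stored data.

# a small field + ground truth + traces, sized for unit tests
make_small_cohort <- function(seed = 11, density = 0.02, fov = 120,
                              n_frames = 1300, noise_sd = 20,
                              i_final_sd = 0, k_sd = 0.0018) {
  field <- generate_cell_field(density, fov, seed = seed)
  truth <- assign_ground_truth(field, k_sd = k_sd, i_final_sd = i_final_sd,
                               seed = seed + 1)
  truth <- filter_region(truth, 3)
  traces <- simulate_traces(truth, n_frames = n_frames, noise_sd = noise_sd,
                            seed = seed + 2)
  list(field = field, truth = truth, traces = traces)
}

# noiseless traces with known parameters on an explicit gamma set
make_noiseless_traces <- function(gamma, k, law = radial_law(),
                                  dt = 0.5, n_frames = 400, delay = 3) {
  truth <- tibble::tibble(
    cell_id = seq_along(gamma), gamma = gamma,
    I_final_true = predict(law, gamma),
    k_true = rep_len(k, length(gamma))
  )
  simulate_traces(truth, dt = dt, n_frames = n_frames, delay = delay,
                  noise_sd = 0)
}

# tiny disjoint two-cell stack rendered from noiseless traces
make_rendered_fixture <- function(seed = 21, n_frames = 8, fov = 30,
                                  density = 0.004, noise_sd = 0) {
  field <- generate_cell_field(density, fov, n_beads = 1, seed = seed)
  truth <- assign_ground_truth(field, i_final_sd = 0, seed = seed + 1)
  traces <- simulate_traces(truth, dt = 0.5, n_frames = n_frames,
                            noise_sd = noise_sd, seed = seed + 2)
  stack <- render_stack(field, traces, pixel_size = 0.25, seed = seed + 3)
  list(field = field, truth = truth, traces = traces, stack = stack)
}
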