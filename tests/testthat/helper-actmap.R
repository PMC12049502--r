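# Shared fixtures: small synthetic participants built in code.

# Simulate the 6 task-1 runs of one participant for a given region model.
make_task1_runs <- function(seed, model, n_runs = 6L, iti = 2) {
  design <- generate_task1_session(seed = seed, iti = iti)
  assignment <- sample_assignment(seed)
  mean_dist <- mean(design$trials$length)
  runs <- lapply(seq_len(n_runs), function(r) {
    ev <- events_for_run(design, r, assignment)
    simulate_run(ev, model, design$n_scans, design$tr,
                 seed = seed * 101L + r, mean_distance = mean_dist)
  })
  list(design = design, assignment = assignment, runs = runs)
}

# Zero-noise model helper
quiet_model <- function(preset, n_voxels = 4L, seed = 1L, ...) {
  region_model(preset, n_voxels = n_voxels, sigma_p = 0, sigma_b = 0,
               drift = 0, seed = seed, ...)
}
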