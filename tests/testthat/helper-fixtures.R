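# Small configurations used across tests: short trials and a small field
# keep unit tests fast; science-level checks use the package defaults.
tiny_cfg <- function(seed = 1L, genotype = "WT", odorants = "L", ...) {
  args <- list(seed = seed, genotype = genotype, odorants = odorants,
               fov_px = 32L, um_per_px = 25, n_trials = 2L,
               trial_length_s = 8, stim_onset_s = 3, stim_duration_s = 2,
               noise_sd = 0.01)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# trial set built directly from a list of T x H x W arrays
manual_trialset <- function(trials, frame_rate = 25, stim_onset_s = 3,
                            stim_duration_s = 2, um_per_px = 25) {
  structure(list(odorant = "X", genotype = "WT", trials = trials,
                 frame_rate = frame_rate, um_per_px = um_per_px,
                 stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s,
                 trial_length_s = dim(trials[[1]])[1] / frame_rate),
            class = "trial_set")
}

# straight-line sagittal contour along y (dorsal at top), for geometry tests
line_contour <- function(n = 101, x = 5, y_max = 100) {
  glomerular_contour(cbind(x, seq(0, y_max, length.out = n)),
                     plane = "sagittal")
}
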