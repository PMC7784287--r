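#' Odorant panel and dorsoventral odor groups
#'
#' Seven odorants are used throughout: lyral (L), acetophenone (A),
#' eugenol (E), geraniol (G), allyl phenylacetate (AP), heptanoic acid (HA)
#' and heptanal (H).  Group A (L, A, E) evokes dorsally focused glomerular
#' activity; group B (G, AP, HA, H) evokes ventrally focused activity and is
#' the group suppressed in the 5xFAD genotype.
#'
#' @format `odorant_panel()` returns a character vector of the seven labels;
#'   `odorant_group(odorant)` returns `"A"` or `"B"` per label.
#' @export
odorant_panel <- function() c("L", "A", "E", "G", "AP", "HA", "H")

#' @rdname odorant_panel
#' @param odorant character vector of odorant labels.
#' @export
odorant_group <- function(odorant) {
  groups <- c(L = "A", A = "A", E = "A", G = "B", AP = "B", HA = "B", H = "B")
  unknown <- setdiff(odorant, names(groups))
  if (length(unknown)) {
    stop("unknown odorant label(s): ", paste(unknown, collapse = ", "),
         " (expected one of ", paste(names(groups), collapse = ", "), ")")
  }
  unname(groups[odorant])
}

#' Simulation configuration for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator.  Defaults encode the
#' study conditions: 10 repeats of 20-s trials with a 2-s stimulus, a
#' dorsal odor-group focus near 40 deg and a ventral one near 150 deg,
#' 70% ventral calcium suppression and a 2-fold ventral amyloid-oligomer
#' (A11) enrichment in the 5xFAD genotype.
#'
#' @param seed integer seed; a fixed seed yields byte-identical datasets.
#' @param genotype `"WT"` or `"5xFAD"`.
#' @param odorants subset of [odorant_panel()].
#' @param group_a_center_deg,group_b_center_deg focus-angle centers (deg on
#'   the sagittal 0-180 dorsoventral scale) for odor groups A and B.
#' @param ventral_suppression fraction in \[0,1\]; group-B response
#'   amplitudes in 5xFAD are scaled by `1 - ventral_suppression`.
#' @param ab_ventral_gain multiplicative A11 enrichment of ventral angular
#'   bins (180 +/- 80 deg) in 5xFAD histology.
#' @param noise_sd imaging noise SD as a fraction of baseline fluorescence.
#' @param frame_rate acquisition rate in Hz, within \[25, 125\].
#' @param fov_px square field of view in pixels.
#' @param um_per_px pixel pitch in micrometres.
#' @param n_trials repeats per odorant (10).
#' @param trial_length_s,stim_onset_s,stim_duration_s trial timing in s.
#' @param focus_sigma_um isotropic Gaussian focus width (sigma, um).
#' @param angle_jitter_deg SD of the normal jitter of focus angles about the
#'   group center (positional variability between animals).
#' @param peak_dff planted relative fluorescence dips (primary, secondary
#'   focus); fura-2 at 380 nm excitation darkens on activation, so these are
#'   fractional decreases.
#' @param baseline mean baseline fluorescence (a.u.).
#' @param tau_decay_s single-exponential decay constant after stimulus offset.
#' @param hist_noise_sd per-bin noise SD of the synthetic A11 angular profile
#'   (relative units; baseline intensity is 1).
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genotype = c("WT", "5xFAD"),
                       odorants = odorant_panel(),
                       group_a_center_deg = 40,
                       group_b_center_deg = 150,
                       ventral_suppression = 0.7,
                       ab_ventral_gain = 2,
                       noise_sd = 0.02,
                       frame_rate = 25,
                       fov_px = 48L,
                       um_per_px = 25,
                       n_trials = 10L,
                       trial_length_s = 20,
                       stim_onset_s = 5,
                       stim_duration_s = 2,
                       focus_sigma_um = 100,
                       angle_jitter_deg = 10,
                       peak_dff = c(0.20, 0.12),
                       baseline = 1000,
                       tau_decay_s = 1,
                       hist_noise_sd = 0.08) {
  genotype <- match.arg(genotype)
  odorant_group(odorants)  # validates labels
  cfg <- list(
    seed = as.integer(seed), genotype = genotype, odorants = odorants,
    group_a_center_deg = group_a_center_deg,
    group_b_center_deg = group_b_center_deg,
    ventral_suppression = ventral_suppression,
    ab_ventral_gain = ab_ventral_gain,
    noise_sd = noise_sd, frame_rate = frame_rate,
    fov_px = as.integer(fov_px), um_per_px = um_per_px,
    n_trials = as.integer(n_trials),
    trial_length_s = trial_length_s, stim_onset_s = stim_onset_s,
    stim_duration_s = stim_duration_s,
    focus_sigma_um = focus_sigma_um, angle_jitter_deg = angle_jitter_deg,
    peak_dff = peak_dff, baseline = baseline, tau_decay_s = tau_decay_s,
    hist_noise_sd = hist_noise_sd
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (cfg$ventral_suppression < 0 || cfg$ventral_suppression > 1) {
    stop("ventral_suppression must lie in [0, 1]")
  }
  if (cfg$frame_rate < 25 || cfg$frame_rate > 125) {
    stop("frame_rate must lie in [25, 125] Hz")
  }
  if (cfg$stim_onset_s < 3) {
    stop("stim_onset_s must allow a 3-s pre-stimulus baseline window")
  }
  if (cfg$stim_onset_s + cfg$stim_duration_s > cfg$trial_length_s) {
    stop("stimulus window must fit inside the trial")
  }
  if (cfg$noise_sd < 0 || cfg$baseline <= 0) {
    stop("noise_sd must be >= 0 and baseline > 0")
  }
  invisible(cfg)
}
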