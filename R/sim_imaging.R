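#' Generate a synthetic widefield calcium-imaging dataset
#'
#' Emulates single-wavelength fura-2 (380 nm excitation) movies of the
#' lateral olfactory bulb: for each odorant, `n_trials` trials of
#' `trial_length_s` seconds at `frame_rate` Hz with a `stim_duration_s`
#' stimulus.  Odor-evoked foci are isotropic Gaussian blobs placed on the
#' glomerular-layer contour at angles drawn near the odorant group's center
#' (group A dorsal, group B ventral).  Activation darkens the fluorescence
#' (380-nm fura-2 convention): the planted focus amplitude is a fractional
#' dip of the baseline.  For the 5xFAD genotype, group-B amplitudes are
#' scaled by `1 - ventral_suppression`.
#'
#' @param cfg a [sim_config()].
#' @return list with elements
#'   * `trialsets`: named list (one per odorant) of class `"trial_set"`,
#'     each holding `trials` (list of T x H x W arrays) plus acquisition
#'     metadata;
#'   * `ground_truth`: data frame of planted focus angles and peak dips;
#'   * `geometry`: the bulb [ellipse_contour()] (with mask attribute);
#'   * `cfg`: the configuration used.
#' @export
generate_imaging_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  geom <- ellipse_contour(cfg$fov_px, plane = "sagittal")
  parts <- lapply(cfg$odorants,
                  function(od) generate_odorant_trialset(cfg, od, geom))
  trialsets <- lapply(parts, `[[`, "trialset")
  names(trialsets) <- cfg$odorants
  list(trialsets = trialsets,
       ground_truth = do.call(rbind, lapply(parts, `[[`, "ground_truth")),
       geometry = geom, cfg = cfg)
}

#' @rdname generate_imaging_dataset
#' @param odorant one odorant label from `cfg$odorants`.
#' @param geom optional precomputed [ellipse_contour()] for `cfg$fov_px`.
#' @details `generate_odorant_trialset()` generates a single odorant's
#'   trials (identical to the corresponding entry of the full dataset),
#'   which lets callers stream odorants without holding all movies in
#'   memory.
#' @export
generate_odorant_trialset <- function(cfg, odorant, geom = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  oi <- match(odorant, cfg$odorants)
  if (is.na(oi)) stop("odorant '", odorant, "' is not in cfg$odorants")
  if (is.null(geom)) geom <- ellipse_contour(cfg$fov_px, plane = "sagittal")
  n_frames <- round(cfg$trial_length_s * cfg$frame_rate)
  t_s <- (seq_len(n_frames) - 1) / cfg$frame_rate
  kern <- temporal_kernel(t_s, cfg$stim_onset_s, cfg$stim_duration_s,
                          cfg$tau_decay_s)
  sigma_px <- cfg$focus_sigma_um / cfg$um_per_px
  xs <- matrix(seq_len(cfg$fov_px), cfg$fov_px, cfg$fov_px, byrow = TRUE)
  ys <- matrix(seq_len(cfg$fov_px), cfg$fov_px, cfg$fov_px)

  od <- cfg$odorants[oi]
  grp <- odorant_group(od)
  center <- if (grp == "A") cfg$group_a_center_deg else cfg$group_b_center_deg
  amps <- cfg$peak_dff
  if (cfg$genotype == "5xFAD" && grp == "B") {
    amps <- amps * (1 - cfg$ventral_suppression)
  }
  res <- with_seed(derive_seed(cfg$seed, 101 + oi), {
    ang <- rnorm(length(amps), mean = center, sd = cfg$angle_jitter_deg)
    ang <- pmin(pmax(ang, 5), 175)
    # snap each focus to the nearest pixel center so the planted peak dip
    # is realized exactly at one pixel
    cent <- round(t(vapply(ang, function(a) contour_point_at(geom, a),
                           numeric(2))))
    # planted dip field: max over foci so the deepest dip equals max(amps)
    field <- matrix(0, cfg$fov_px, cfg$fov_px)
    for (j in seq_along(amps)) {
      g <- exp(-((xs - cent[j, 1])^2 + (ys - cent[j, 2])^2) /
                 (2 * sigma_px^2))
      field <- pmax(field, amps[j] * g)
    }
    signal <- cfg$baseline * (1 - outer(kern, field))  # T x H x W
    trials <- vector("list", cfg$n_trials)
    for (k in seq_len(cfg$n_trials)) {
      fr <- signal
      if (cfg$noise_sd > 0) {
        fr <- fr + array(rnorm(length(signal), 0,
                               cfg$noise_sd * cfg$baseline),
                         dim = dim(signal))
      }
      trials[[k]] <- pmax(fr, 1)  # fluorescence stays positive
    }
    list(trials = trials, angles = ang, centers = cent, amps = amps)
  })
  trialset <- structure(
    list(odorant = od, genotype = cfg$genotype, trials = res$trials,
         frame_rate = cfg$frame_rate, um_per_px = cfg$um_per_px,
         stim_onset_s = cfg$stim_onset_s,
         stim_duration_s = cfg$stim_duration_s,
         trial_length_s = cfg$trial_length_s),
    class = "trial_set")
  gt <- data.frame(
    odorant = od, group = grp, focus = seq_along(res$amps),
    focus_angle_deg = res$angles,
    focus_x = res$centers[, 1], focus_y = res$centers[, 2],
    peak_dff = res$amps)
  list(trialset = trialset, ground_truth = gt)
}

# boxcar stimulus with single-exponential offset decay
temporal_kernel <- function(t_s, onset, duration, tau) {
  k <- numeric(length(t_s))
  during <- t_s >= onset & t_s < onset + duration
  after <- t_s >= onset + duration
  k[during] <- 1
  k[after] <- exp(-(t_s[after] - (onset + duration)) / tau)
  k
}

#' Write an imaging dataset to disk as multi-page TIFFs plus a manifest
#'
#' One 32-bit float multi-page TIFF per trial (intensities divided by
#' `scale` to fit \[0,1\]), a `trials.csv` manifest, and
#' `ground_truth.json`.  Byte-identical output for identical configs.
#'
#' @param ds result of [generate_imaging_dataset()].
#' @param dir output directory (created if needed).
#' @param scale intensity divisor used for TIFF storage.
#' @return `dir`, invisibly.
#' @export
write_imaging_dataset <- function(ds, dir, scale = 65536) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (od in names(ds$trialsets)) {
    ts <- ds$trialsets[[od]]
    for (k in seq_along(ts$trials)) {
      fn <- sprintf("%s_trial%02d.tif", gsub("[^A-Za-z0-9]", "", od), k)
      arr <- ts$trials[[k]]
      pages <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ] / scale)
      tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = 32)
      manifest[[length(manifest) + 1L]] <- data.frame(
        odorant = od, trial = k, file = fn,
        frame_rate = ts$frame_rate, um_per_px = ts$um_per_px,
        stim_onset_s = ts$stim_onset_s,
        stim_duration_s = ts$stim_duration_s,
        trial_length_s = ts$trial_length_s, genotype = ts$genotype,
        scale = scale)
    }
  }
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  jsonlite::write_json(ds$ground_truth, file.path(dir, "ground_truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_imaging_dataset()]
#' @param dir dataset directory.
#' @return named list of `"trial_set"` objects.
#' @export
read_imaging_dataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "trials.csv"),
                         colClasses = c(odorant = "character"))
  out <- list()
  for (od in unique(man$odorant)) {
    rows <- man[man$odorant == od, ]
    rows <- rows[order(rows$trial), ]
    trials <- lapply(seq_len(nrow(rows)), function(i) {
      pages <- tiff::readTIFF(file.path(dir, rows$file[i]), all = TRUE)
      arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
      for (p in seq_along(pages)) arr[p, , ] <- pages[[p]] * rows$scale[i]
      arr
    })
    r <- rows[1, ]
    out[[od]] <- structure(
      list(odorant = od, genotype = r$genotype, trials = trials,
           frame_rate = r$frame_rate, um_per_px = r$um_per_px,
           stim_onset_s = r$stim_onset_s, stim_duration_s = r$stim_duration_s,
           trial_length_s = r$trial_length_s),
      class = "trial_set")
  }
  out
}
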