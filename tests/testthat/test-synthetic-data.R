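test_that("identical configs give identical datasets, including TIFF bytes", {
  cfg <- tiny_cfg(seed = 42, odorants = c("L", "H"))
  ds1 <- generate_imaging_dataset(cfg)
  ds2 <- generate_imaging_dataset(cfg)
  expect_identical(ds1$trialsets$L$trials, ds2$trialsets$L$trials)
  expect_identical(ds1$ground_truth, ds2$ground_truth)

  d1 <- file.path(tempdir(), "ds_a"); d2 <- file.path(tempdir(), "ds_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_imaging_dataset(ds1, d1)
  write_imaging_dataset(ds2, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in grep("[.]tif$", f1, value = TRUE)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and the TIFF round trip restores the arrays to storage precision
  back <- read_imaging_dataset(d1)
  expect_equal(back$L$trials[[1]], ds1$trialsets$L$trials[[1]],
               tolerance = 1e-6)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("streamed single-odorant generation matches the full dataset", {
  cfg <- tiny_cfg(seed = 5, odorants = c("L", "G", "H"))
  ds <- generate_imaging_dataset(cfg)
  part <- generate_odorant_trialset(cfg, "G")
  expect_identical(part$trialset$trials, ds$trialsets$G$trials)
  expect_error(generate_odorant_trialset(cfg, "XX"), "not in cfg")
})

test_that("a noise-free planted dip appears verbatim in dF/F0", {
  cfg <- tiny_cfg(seed = 7, noise_sd = 0, peak_dff = 0.2)
  ds <- generate_imaging_dataset(cfg)
  ts <- ds$trialsets$L
  F0 <- compute_baseline(ts)
  dff <- compute_dff(ts$trials[[1]], F0)
  expect_equal(min(dff), -0.20, tolerance = 1e-9)
  expect_identical(attr(dff, "sign_flag"), "raw")
})

test_that("focus angles land near the odorant group's center", {
  cfg <- sim_config(seed = 11, genotype = "WT", odorants = c("L", "H"))
  ds <- generate_imaging_dataset(cfg)
  gt <- ds$ground_truth
  expect_true(all(abs(gt$focus_angle_deg[gt$odorant == "H"] -
                        cfg$group_b_center_deg) <= 4 * cfg$angle_jitter_deg))
  expect_true(all(abs(gt$focus_angle_deg[gt$odorant == "L"] -
                        cfg$group_a_center_deg) <= 4 * cfg$angle_jitter_deg))
})

test_that("5xFAD scales group-B amplitudes by 1 - ventral_suppression", {
  wt <- generate_imaging_dataset(tiny_cfg(seed = 3, odorants = c("L", "H")))
  tg <- generate_imaging_dataset(tiny_cfg(seed = 3, genotype = "5xFAD",
                                          odorants = c("L", "H")))
  gw <- wt$ground_truth; gt <- tg$ground_truth
  expect_equal(gt$peak_dff[gt$odorant == "H"],
               gw$peak_dff[gw$odorant == "H"] * (1 - 0.7))
  expect_equal(gt$peak_dff[gt$odorant == "L"],
               gw$peak_dff[gw$odorant == "L"])
})

test_that("generated movies never contain non-positive fluorescence", {
  cfg <- tiny_cfg(seed = 13, noise_sd = 0.5)  # absurd noise still clips safe
  ds <- generate_imaging_dataset(cfg)
  expect_true(all(vapply(ds$trialsets$L$trials,
                         function(a) min(a) > 0, logical(1))))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(tiny_cfg(odorants = "Q"), "unknown odorant")
  expect_error(sim_config(ventral_suppression = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(frame_rate = 10), "\\[25, 125\\]")
  expect_error(sim_config(stim_onset_s = 2), "3-s pre-stimulus")
})

test_that("histology generator plants a flat WT and gained 5xFAD profile", {
  wt <- generate_histology_profile(tiny_cfg(seed = 2), plane = "sagittal")
  rs_wt <- profile_region_summary(wt$profile)
  expect_lt(abs(rs_wt["dorsal"] - rs_wt["ventral"]), 0.1)

  tg <- generate_histology_profile(tiny_cfg(seed = 2, genotype = "5xFAD"),
                                   plane = "sagittal")
  rs_tg <- profile_region_summary(tg$profile)
  expect_equal(unname(rs_tg["ventral"] / rs_tg["dorsal"]), 2,
               tolerance = 0.1)
  # ground truth is exact by construction
  gt <- tg$ground_truth
  mids <- seq(0.5, 179.5)
  expect_true(all(gt[mids >= 100] == 2) && all(gt[mids <= 80] == 1))
})

test_that("rendered section round-trips through color deconvolution", {
  tg <- generate_histology_profile(tiny_cfg(seed = 9, genotype = "5xFAD"),
                                   plane = "coronal", render_image = TRUE)
  ch <- color_deconvolve(tg$image)
  prof <- angular_immunoreactivity(ch$dab, tg$contour, max_dist_px = 3)
  ok <- !is.na(prof$values)
  expect_gt(sum(ok), 300)
  # the renderer paints the (noisy) planted per-bin intensities; the
  # deconvolved per-bin OD must track them
  expect_gt(cor(prof$values[ok], tg$profile$values[ok],
                method = "spearman"), 0.95)
})

test_that("trajectory sessions have the stated frame count and determinism", {
  s1 <- generate_trajectory(TRUE, duration_s = 60, seed = 21)
  expect_identical(nrow(s1$frames), 60L * 30L)
  s2 <- generate_trajectory(TRUE, duration_s = 60, seed = 21)
  expect_identical(s1$frames, s2$frames)
  expect_true(all(s1$frames$nose_x >= 0 & s1$frames$nose_x <= s1$cage[1]))
  expect_true(all(s1$frames$nose_y >= 0 & s1$frames$nose_y <= s1$cage[2]))
})

test_that("non-detecting sessions occupy the odor third at chance", {
  s <- generate_trajectory(FALSE, duration_s = 1200, seed = 8)
  occ <- zone_occupancy(s)
  expect_equal(occ$odor_fraction, 1 / 3, tolerance = 0.12)
  expect_equal(s$ground_truth$p_odor, 1 / 3)
})

test_that("count tables have animals x regions x markers rows and planted effects", {
  ct <- generate_count_tables(n_per_group = 6, seed = 1)
  expect_identical(nrow(ct), 2L * 6L * 8L)  # genotypes x animals x (marker, region)
  expect_setequal(unique(ct$marker), c("OMP", "TH", "Ki67", "TUNEL"))
  omp <- ct[ct$marker == "OMP" & ct$region == "ecto", ]
  expect_lt(mean(omp$value[omp$genotype == "5xFAD"]),
            mean(omp$value[omp$genotype == "WT"]))
  # null mode removes every genotype effect
  null_ct <- generate_count_tables(n_per_group = 500, seed = 3,
                                   effect_scale = 0)
  ne <- null_ct[null_ct$marker == "OMP" & null_ct$region == "ecto", ]
  expect_equal(mean(ne$value[ne$genotype == "5xFAD"]),
               mean(ne$value[ne$genotype == "WT"]), tolerance = 0.02)
})
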