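test_that("baseline is the pooled 3-s pre-stimulus mean", {
  # constant frames: F0 equals the constant
  const <- array(100, dim = c(100, 4, 4))
  ts <- manual_trialset(list(const, const), frame_rate = 25)
  F0 <- compute_baseline(ts)
  expect_true(all(unclass(F0) == 100))
  # 25 Hz, 3-s window: 75 frames per trial pooled across trials
  expect_identical(attr(F0, "n_frames_pooled"), 150L)
  ts10 <- manual_trialset(rep(list(const), 10), frame_rate = 25)
  expect_identical(attr(compute_baseline(ts10), "n_frames_pooled"), 750L)

  # two-valued checkerboard alternating per frame: per-pixel mean of both
  a <- array(0, dim = c(100, 4, 4))
  for (t in 1:100) a[t, , ] <- if (t %% 2) 80 else 120
  tsc <- manual_trialset(list(a), frame_rate = 25)
  # direct oracle: mean over the window frames, per pixel
  idx <- which((0:99) / 25 >= 0 & (0:99) / 25 < 3)
  oracle <- apply(a[idx, , ], c(2, 3), mean)
  expect_equal(unclass(compute_baseline(tsc)), oracle, ignore_attr = TRUE)

  # too-early onset errors, naming the trial set
  ts_bad <- manual_trialset(list(const), stim_onset_s = 2)
  expect_error(compute_baseline(ts_bad), "pre-stimulus")
})

test_that("dF/F0 follows its definition and masks bad baselines", {
  F0 <- matrix(100, 2, 2)
  fr <- array(100, dim = c(3, 2, 2))
  fr[2, 1, 1] <- 90
  dff <- compute_dff(fr, F0)
  expect_equal(dff[2, 1, 1], -0.10)
  expect_true(all(dff[1, , ] == 0))

  F0b <- F0; F0b[2, 2] <- 0
  dffb <- compute_dff(fr, F0b)
  expect_identical(attr(dffb, "n_masked"), 1L)
  expect_true(all(is.na(dffb[, 2, 2])))

  # joint scaling of F and F0 leaves dF/F0 unchanged
  expect_equal(unclass(compute_dff(fr * 3, F0 * 3)), unclass(dff),
               ignore_attr = TRUE)

  # sign flip recorded
  dfff <- compute_dff(fr, F0, sign_flip = TRUE)
  expect_equal(dfff[2, 1, 1], 0.10)
  expect_identical(attr(dfff, "sign_flag"), "activation-positive")
})

test_that("trial averaging and 1-s binning behave as stated", {
  base <- array(rep(seq(0, 1, length.out = 50), 4), dim = c(50, 2, 2))
  # 10 identical trials equal any single trial binned
  avg10 <- average_trials(rep(list(base), 10), frame_rate = 25)
  avg1 <- average_trials(list(base), frame_rate = 25)
  expect_equal(avg10$dff, avg1$dff)
  expect_identical(avg10$n_trials_used, 10L)

  # one trial excluded: mean over the rest
  other <- base + 1
  avg_ex <- average_trials(list(base, other, base), frame_rate = 25,
                           exclude = 2L)
  expect_equal(avg_ex$dff, avg1$dff)
  expect_identical(avg_ex$n_trials_used, 2L)

  # linear ramp: each 1-s bin holds the mid-bin mean (direct oracle)
  ramp <- array(seq_len(50), dim = c(50, 1, 1))
  avg_r <- average_trials(list(ramp), frame_rate = 25)
  oracle <- c(mean(1:25), mean(26:50))
  expect_equal(as.numeric(avg_r$dff), oracle)

  expect_error(average_trials(list(base), 25, exclude = 1L), "all trials")
})

test_that("trial averaging commutes with dF/F0 for identical trials", {
  cfg <- tiny_cfg(seed = 4, noise_sd = 0)
  ts <- generate_imaging_dataset(cfg)$trialsets$L
  F0 <- compute_baseline(ts)
  dffs <- lapply(ts$trials, compute_dff, F0 = F0)
  a <- average_trials(dffs, ts$frame_rate)
  mean_frames <- Reduce(`+`, ts$trials) / length(ts$trials)
  b <- average_trials(list(compute_dff(mean_frames, F0)), ts$frame_rate)
  expect_equal(a$dff, b$dff, tolerance = 1e-12)
})

test_that("response image reduces the stimulus-window bins", {
  dff <- array(0, dim = c(8, 2, 2))
  dff[4, , ] <- -0.3   # bin covering [3, 4) s
  dff[5, , ] <- -0.1   # bin covering [4, 5) s
  dm <- structure(list(dff = dff, bin_s = 1, sign_flag = "raw",
                       n_trials_used = 1L), class = "dff_map")
  r_mean <- response_image(dm, stim_onset_s = 3, stim_duration_s = 2)
  expect_equal(unclass(r_mean), matrix(-0.2, 2, 2), ignore_attr = TRUE)
  r_sum <- response_image(dm, 3, 2, statistic = "sum")
  expect_equal(unclass(r_sum), matrix(-0.4, 2, 2), ignore_attr = TRUE)
  r_abs <- response_image(dm, 3, 2, abs = TRUE)
  expect_equal(unclass(r_abs), matrix(0.2, 2, 2), ignore_attr = TRUE)
  expect_identical(attr(r_abs, "sign_flag"), "magnitude")
})

test_that("ROI detection finds planted foci and respects the 200-um outline", {
  expect_identical(nrow(detect_activity_rois(matrix(0, 32, 32), 25)), 0L)

  # two foci 600 um apart (24 px at 25 um/px) on a quiet background
  xs <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  ys <- matrix(seq_len(64), 64, 64)
  resp <- -0.3 * exp(-((xs - 20)^2 + (ys - 32)^2) / (2 * 4^2)) -
    0.25 * exp(-((xs - 44)^2 + (ys - 32)^2) / (2 * 4^2))
  set.seed(1)
  resp <- resp + rnorm(length(resp), 0, 0.002)
  rois <- detect_activity_rois(resp, um_per_px = 25)
  expect_identical(nrow(rois), 2L)
  ord <- order(rois$x)
  expect_true(all(abs(rois$x[ord] - c(20, 44)) <= 1))
  expect_true(all(abs(rois$y - 32) <= 1))
  expect_equal(attr(rois, "radius_px"), 8)  # round(200 / 25)
  expect_equal(attr(detect_activity_rois(resp, um_per_px = 30),
                    "radius_px"), 7)  # round(200 / 30)
})

test_that("the analysis grid is 10 x 180 with per-cell means", {
  mask <- matrix(TRUE, 40, 40)
  resp <- matrix(1, 40, 40)
  g <- build_grid(resp, mask)
  expect_identical(dim(g), c(10L, 180L))
  expect_true(all(g[!is.na(g)] == 1))  # uniform response, uniform cells

  # random response vs direct per-cell mean oracle
  set.seed(2)
  resp2 <- matrix(rnorm(1600), 40, 40)
  mask2 <- matrix(runif(1600) > 0.3, 40, 40)
  g2 <- build_grid(resp2, mask2, n_ap = 4L, n_dv = 5L)
  px <- which(mask2, arr.ind = TRUE)
  bb_x <- range(px[, 2]); bb_y <- range(px[, 1])
  for (i in 1:4) for (j in 1:5) {
    # oracle: proportional position of each pixel within the bounding box
    ap <- pmin(floor((px[, 2] - bb_x[1]) / (diff(bb_x) + 1e-9) * 4) + 1, 4)
    dv <- pmin(floor((px[, 1] - bb_y[1]) / (diff(bb_y) + 1e-9) * 5) + 1, 5)
    sel <- ap == i & dv == j
    expected <- if (any(sel)) mean(resp2[px[sel, , drop = FALSE]]) else NA_real_
    expect_equal(g2[i, j], expected)
  }
  expect_error(build_grid(resp, matrix(FALSE, 40, 40)), "empty")
})

test_that("end-to-end peak recovery on default synthetic data", {
  cfg_wt <- sim_config(seed = 6, genotype = "WT", odorants = c("L", "H"))
  geom <- ellipse_contour(cfg_wt$fov_px)
  for (od in c("L", "H")) {
    part <- generate_odorant_trialset(cfg_wt, od, geom)
    am <- compute_activity_map(part$trialset, geom)
    planted <- max(part$ground_truth$peak_dff)
    expect_equal(am$peak_dff, planted, tolerance = 0.1)
  }
  # 5xFAD group-B peak reduced by ventral_suppression
  cfg_tg <- sim_config(seed = 6, genotype = "5xFAD", odorants = c("L", "H"))
  part <- generate_odorant_trialset(cfg_tg, "H", geom)
  am <- compute_activity_map(part$trialset, geom)
  expect_equal(am$peak_dff, 0.20 * (1 - cfg_tg$ventral_suppression),
               tolerance = 0.1 * 0.20)
})
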