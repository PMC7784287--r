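#' Pooled pre-stimulus baseline image (F0)
#'
#' Per-pixel mean fluorescence over the 3-s window before stimulus onset,
#' pooled across all (non-excluded) trials of a trial set.
#'
#' @param trialset a `"trial_set"` (see [generate_imaging_dataset()]), or a
#'   list with `trials`, `frame_rate`, `stim_onset_s`.
#' @param window_s length of the pre-stimulus window (default 3 s).
#' @param exclude integer indices of artifact trials to drop.
#' @return H x W matrix of class `"baseline_image"` with attribute
#'   `"n_frames_pooled"`.
#' @export
compute_baseline <- function(trialset, window_s = 3, exclude = integer(0)) {
  if (trialset$stim_onset_s < window_s) {
    stop("stim_onset_s = ", trialset$stim_onset_s,
         " s leaves no ", window_s, "-s pre-stimulus window (trial set '",
         trialset$odorant %||% "?", "')")
  }
  keep <- setdiff(seq_along(trialset$trials), exclude)
  if (!length(keep)) stop("all trials excluded")
  t0 <- trialset$stim_onset_s - window_s
  acc <- NULL
  n_pooled <- 0L
  for (k in keep) {
    arr <- trialset$trials[[k]]
    d <- dim(arr)
    t_s <- (seq_len(d[1]) - 1) / trialset$frame_rate
    idx <- which(t_s >= t0 & t_s < trialset$stim_onset_s)
    m <- arr
    dim(m) <- c(d[1], d[2] * d[3])
    s <- matrix(colSums(m[idx, , drop = FALSE]), d[2], d[3])
    acc <- if (is.null(acc)) s else acc + s
    n_pooled <- n_pooled + length(idx)
  }
  F0 <- acc / n_pooled
  structure(F0, class = c("baseline_image", class(F0)),
            n_frames_pooled = n_pooled)
}

#' Per-frame relative fluorescence change (dF/F0)
#'
#' `dff[t, x, y] = (F[t, x, y] - F0[x, y]) / F0[x, y]`.  Pixels with
#' non-positive baseline are masked to `NA`; their count is reported in the
#' `"n_masked"` attribute.  No sign flip is applied here: at 380-nm fura-2
#' excitation, activation appears as a negative dF/F0.
#'
#' @param frames T x H x W array of one trial.
#' @param F0 baseline image ([compute_baseline()]).
#' @param sign_flip if `TRUE`, return activation-positive values
#'   (`-dff`); recorded in the `"sign_flag"` attribute.
#' @return T x H x W array with attributes `sign_flag` and `n_masked`.
#' @export
compute_dff <- function(frames, F0, sign_flip = FALSE) {
  F0 <- unclass(F0)
  bad <- F0 <= 0
  F0m <- F0
  F0m[bad] <- NA_real_
  d <- dim(frames)
  dff <- frames
  dim(dff) <- c(d[1], d[2] * d[3])
  denom <- rep(as.vector(F0m), each = d[1])
  dff <- (dff - denom) / denom
  dim(dff) <- d
  if (sign_flip) dff <- -dff
  structure(dff,
            sign_flag = if (sign_flip) "activation-positive" else "raw",
            n_masked = sum(bad))
}

#' Trial-average and 1-s binning of per-trial dF/F0 movies
#'
#' Means across the retained trials, then means within each 1-s bin,
#' yielding S x H x W with S = trial length in seconds (20 bins for the
#' standard protocol).  Artifact trials are excluded by explicit index (no
#' automatic detection; inspection lists are an input).
#'
#' @param dff_list list of T x H x W per-trial dF/F0 arrays
#'   ([compute_dff()]).
#' @param frame_rate acquisition rate (Hz).
#' @param trial_length_s trial duration (s); must equal `T / frame_rate`.
#' @param exclude integer indices of trials to drop.
#' @return object of class `"dff_map"`: list with `dff` (S x H x W),
#'   `bin_s = 1`, `sign_flag`, `n_trials_used`.
#' @export
average_trials <- function(dff_list, frame_rate, trial_length_s = NULL,
                           exclude = integer(0)) {
  keep <- setdiff(seq_along(dff_list), exclude)
  if (!length(keep)) stop("all trials excluded")
  d <- dim(dff_list[[keep[1]]])
  n_frames <- d[1]
  trial_length_s <- trial_length_s %||% (n_frames / frame_rate)
  S <- round(trial_length_s)
  acc <- array(0, dim = d)
  for (k in keep) acc <- acc + dff_list[[k]]
  avg <- acc / length(keep)
  dim(avg) <- c(n_frames, d[2] * d[3])
  t_s <- (seq_len(n_frames) - 1) / frame_rate
  bin <- pmin(floor(t_s) + 1L, S)
  counts <- tabulate(bin, nbins = S)
  binned <- rowsum(avg, group = bin) / counts
  dim(binned) <- c(S, d[2], d[3])
  structure(list(dff = binned, bin_s = 1,
                 sign_flag = attr(dff_list[[keep[1]]], "sign_flag") %||% "raw",
                 n_trials_used = length(keep)),
            class = "dff_map")
}

#' Stimulus-window response image
#'
#' Reduces a binned dF/F0 map to one H x W summary over the bins covering
#' the stimulus window \[onset, onset + duration).  The reduction is the
#' mean by default ("cumulated signal" is available as `statistic =
#' "sum"`); `abs = TRUE` summarizes magnitudes instead of signed values.
#'
#' @param dff_map an [average_trials()] result.
#' @param stim_onset_s,stim_duration_s stimulus timing (s).
#' @param statistic `"mean"` or `"sum"` over the stimulus-window bins.
#' @param abs summarize `|dF/F0|` rather than signed dF/F0.
#' @return H x W matrix with attributes `statistic`, `sign_flag`.
#' @export
response_image <- function(dff_map, stim_onset_s, stim_duration_s = 2,
                           statistic = c("mean", "sum"), abs = FALSE) {
  statistic <- match.arg(statistic)
  S <- dim(dff_map$dff)[1]
  starts <- seq_len(S) - 1
  sel <- which(starts < stim_onset_s + stim_duration_s &
                 (starts + dff_map$bin_s) > stim_onset_s)
  x <- dff_map$dff[sel, , , drop = FALSE]
  if (abs) x <- base::abs(x)
  d <- dim(x)
  dim(x) <- c(d[1], d[2] * d[3])
  out <- matrix(colSums(x), d[2], d[3])
  if (statistic == "mean") out <- out / d[1]
  structure(out, statistic = statistic,
            sign_flag = if (abs) "magnitude" else dff_map$sign_flag)
}

#' Detect activity ROIs as thresholded local maxima
#'
#' Stand-in for the LC Pro target-point selection: local maxima of the
#' response magnitude exceeding median + k * MAD, kept in decreasing order
#' of magnitude with a minimum mutual separation, each outlined by a disk
#' of radius 200 um clipped to the image.
#'
#' @param resp H x W response image (signed or magnitude).
#' @param um_per_px pixel pitch (um).
#' @param k MAD multiplier of the detection threshold (default 3).
#' @param min_sep_um minimum center separation (default 200 um).
#' @param radius_um ROI outline radius (default 200 um).
#' @return data frame (possibly 0-row) with columns `x`, `y`, `value`
#'   and attributes `radius_px`, `threshold`.
#' @export
detect_activity_rois <- function(resp, um_per_px, k = 3,
                                 min_sep_um = 200, radius_um = 200) {
  a <- abs(unclass(resp))
  thr <- stats::median(a, na.rm = TRUE) + k * stats::mad(a, na.rm = TRUE)
  H <- nrow(a); W <- ncol(a)
  radius_px <- round(radius_um / um_per_px)
  empty <- data.frame(x = numeric(0), y = numeric(0), value = numeric(0))
  # 3x3-neighborhood local maxima above threshold
  cand <- which(a > thr, arr.ind = TRUE)
  if (nrow(cand)) {
    is_max <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      nb <- a[max(1, r - 1):min(H, r + 1), max(1, c - 1):min(W, c + 1)]
      a[r, c] >= max(nb, na.rm = TRUE)
    }, logical(1))
    cand <- cand[is_max, , drop = FALSE]
  }
  if (!nrow(cand)) {
    return(structure(empty, radius_px = radius_px, threshold = thr))
  }
  vals <- a[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]
  min_sep_px <- min_sep_um / um_per_px
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(keep)) { keep <- i; next }
    dd <- sqrt((cand[keep, 2] - cand[i, 2])^2 +
                 (cand[keep, 1] - cand[i, 1])^2)
    if (all(dd >= min_sep_px)) keep <- c(keep, i)
  }
  out <- data.frame(x = cand[keep, 2], y = cand[keep, 1],
                    value = resp[cand[keep, , drop = FALSE]])
  structure(out, radius_px = radius_px, threshold = thr)
}

#' Build the 10 x 180 anterior-posterior x dorsoventral analysis grid
#'
#' The bounding box of the bulb mask is split into 10 equal
#' anterior-posterior columns and 180 equal dorsoventral rows; each cell
#' holds the mean of the response values of its mask pixels (`NA` where a
#' cell holds no mask pixel).
#'
#' @param resp H x W response image (typically the stimulus-window
#'   `|dF/F0|` from [response_image()] with `abs = TRUE`).
#' @param mask logical H x W bulb mask.
#' @param n_ap,n_dv grid dimensions (default 10 x 180).
#' @return `n_ap` x `n_dv` matrix (rows anterior->posterior, columns
#'   dorsal->ventral).
#' @export
build_grid <- function(resp, mask, n_ap = 10L, n_dv = 180L) {
  stopifnot(all(dim(resp) == dim(mask)))
  px <- which(mask, arr.ind = TRUE)
  if (!nrow(px)) stop("empty bulb mask")
  ys <- px[, 1]; xs <- px[, 2]
  bb_x <- range(xs); bb_y <- range(ys)
  # pixel centers binned over the bounding box; epsilon keeps the max inside
  ap <- pmin(floor((xs - bb_x[1]) / (diff(bb_x) + 1e-9) * n_ap) + 1L, n_ap)
  dv <- pmin(floor((ys - bb_y[1]) / (diff(bb_y) + 1e-9) * n_dv) + 1L, n_dv)
  vals <- resp[px]
  grid <- matrix(NA_real_, n_ap, n_dv)
  sums <- rowsum(vals, group = (ap - 1L) * n_dv + dv)
  cnts <- rowsum(rep(1, length(vals)), group = (ap - 1L) * n_dv + dv)
  cell <- as.integer(rownames(sums))
  grid[cbind((cell - 1L) %/% n_dv + 1L, (cell - 1L) %% n_dv + 1L)] <-
    sums[, 1] / cnts[, 1]
  grid
}

#' Angle-resolved calcium profile along the glomerular-layer contour
#'
#' Samples the response image at the contour vertices (nearest pixel) and
#' bins the samples by angular position, yielding the dorsoventral calcium
#' profile that is correlated against histology.  By default the signed
#' response is used (raw 380-nm convention: activation negative).
#'
#' @param resp H x W response image.
#' @param contour a [glomerular_contour()] in the same pixel frame.
#' @param bin_deg bin width (default 1 deg).
#' @return class `"angular_profile"` (see [build_profile()]).
#' @export
calcium_angular_profile <- function(resp, contour, bin_deg = 1) {
  pts <- contour$points
  H <- nrow(resp); W <- ncol(resp)
  cx <- pmin(pmax(round(pts[, 1]), 1L), W)
  cy <- pmin(pmax(round(pts[, 2]), 1L), H)
  vals <- resp[cbind(cy, cx)]
  ang <- assign_angle(pts, contour)
  build_profile(ang, vals, plane = contour$plane, bin_deg = bin_deg)
}

#' End-to-end activity map for one odorant trial set
#'
#' Convenience wrapper: baseline, per-trial dF/F0, trial averaging and
#' binning, stimulus-window summaries, ROI detection, 10 x 180 grid and the
#' angular calcium profile.
#'
#' @param trialset a `"trial_set"`.
#' @param geometry bulb [ellipse_contour()] (mask + contour).
#' @param exclude artifact-trial indices.
#' @param statistic stimulus-window reduction (`"mean"` or `"sum"`).
#' @return list of class `"activity_map"`: `odorant`, `grid` (10 x 180
#'   magnitudes), `rois`, `response` (signed), `response_abs`, `profile`
#'   (signed angular profile), `profile_abs`, `peak_dff` (max magnitude),
#'   `sign_flag`, `n_trials_used`.
#' @export
compute_activity_map <- function(trialset, geometry, exclude = integer(0),
                                 statistic = "mean") {
  F0 <- compute_baseline(trialset, exclude = exclude)
  keep <- setdiff(seq_along(trialset$trials), exclude)
  # dF/F0 is linear in F for a shared F0, so averaging the raw frames
  # before one dF/F0 pass equals the mean of the per-trial dF/F0 movies
  acc <- trialset$trials[[keep[1]]]
  for (k in keep[-1]) acc <- acc + trialset$trials[[k]]
  avg_dff <- compute_dff(acc / length(keep), F0)
  avg <- average_trials(list(avg_dff), trialset$frame_rate,
                        trial_length_s = trialset$trial_length_s)
  avg$n_trials_used <- length(keep)
  resp <- response_image(avg, trialset$stim_onset_s,
                         trialset$stim_duration_s, statistic = statistic)
  resp_abs <- abs(resp)
  mask <- attr(geometry, "mask")
  structure(list(
    odorant = trialset$odorant,
    genotype = trialset$genotype,
    grid = build_grid(resp_abs, mask),
    rois = detect_activity_rois(resp, trialset$um_per_px),
    response = resp,
    response_abs = resp_abs,
    profile = calcium_angular_profile(resp, geometry),
    profile_abs = calcium_angular_profile(resp_abs, geometry),
    peak_dff = max(resp_abs, na.rm = TRUE),
    sign_flag = avg$sign_flag,
    n_trials_used = avg$n_trials_used), class = "activity_map")
}
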