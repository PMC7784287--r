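#' Generate a synthetic nose-poke trajectory session
#'
#' Emulates DeepLabCut-style tracking of four points of interest (nose,
#' two ears, tail) at 30 frames/s in a rectangular test cage divided into
#' three equal compartments along its long axis.  The nose visits the cage
#' in bouts; each bout targets the odorant compartment with probability
#' `p_odor` (default 0.6 when the animal detects the odorant, 1/3 -- chance
#' -- when it does not), so long-session occupancy of the odorant third
#' converges to `p_odor`.
#'
#' @param detects logical; does the animal detect the odorant?
#' @param duration_s session length in seconds (the test presents the
#'   odorant for 2 min).
#' @param seed integer seed.
#' @param fps frame rate (30).
#' @param cage `c(width, height)` in cm; compartments split the width.
#' @param odor_zone which third (1..3) holds the scented cotton tip.
#' @param p_odor per-bout probability of targeting the odorant third;
#'   defaults to 0.6 if `detects` else 1/3.
#' @param mean_bout_s mean exponential bout duration (s).
#' @param condition free-text condition label (odorant or `"MO"` control).
#' @return object of class `"trajectory_session"`: list with `frames`
#'   (data frame: frame, t_s, nose/earL/earR/tail x-y columns), `fps`,
#'   `cage`, `odor_zone`, `condition`, `duration_s` and `ground_truth`
#'   (the occupancy parameter and the realized fraction).
#' @export
generate_trajectory <- function(detects, duration_s = 120, seed = 1L,
                                fps = 30, cage = c(45, 25), odor_zone = 3L,
                                p_odor = NULL, mean_bout_s = 2,
                                condition = if (detects) "odorant" else "MO") {
  p <- p_odor %||% (if (detects) 0.6 else 1 / 3)
  stopifnot(p >= 0, p <= 1, duration_s > 0, fps > 0)
  n_frames <- round(duration_s * fps)
  zone_w <- cage[1] / 3
  others <- setdiff(1:3, odor_zone)
  frames <- with_seed(seed, {
    zone <- integer(n_frames)
    i <- 1L
    while (i <= n_frames) {
      len <- max(1L, round(rexp(1, rate = 1 / mean_bout_s) * fps))
      z <- if (runif(1) < p) odor_zone else sample(others, 1L)
      j <- min(n_frames, i + len - 1L)
      zone[i:j] <- z
      i <- j + 1L
    }
    # within-bout nose position: zone-center target plus a small jitter walk
    margin <- 1
    tx <- (zone - 0.5) * zone_w
    nose_x <- tx + cumsum(rnorm(n_frames, 0, 0.35))
    nose_y <- pmin(pmax(cage[2] / 2 + cumsum(rnorm(n_frames, 0, 0.35)),
                        margin), cage[2] - margin)
    # keep the nose strictly inside its bout's compartment
    nose_x <- pmin(pmax(nose_x, (zone - 1) * zone_w + margin),
                   zone * zone_w - margin)
    clip_x <- function(v) pmin(pmax(v, 0), cage[1])
    clip_y <- function(v) pmin(pmax(v, 0), cage[2])
    data.frame(
      frame = seq_len(n_frames),
      t_s = (seq_len(n_frames) - 1) / fps,
      nose_x = nose_x, nose_y = nose_y,
      earL_x = clip_x(nose_x - 1.5 + rnorm(n_frames, 0, 0.1)),
      earL_y = clip_y(nose_y - 1.0 + rnorm(n_frames, 0, 0.1)),
      earR_x = clip_x(nose_x - 1.5 + rnorm(n_frames, 0, 0.1)),
      earR_y = clip_y(nose_y + 1.0 + rnorm(n_frames, 0, 0.1)),
      tail_x = clip_x(nose_x - 7 + rnorm(n_frames, 0, 0.3)),
      tail_y = clip_y(nose_y + rnorm(n_frames, 0, 0.3)),
      zone = zone)
  })
  realized <- mean(frames$zone == odor_zone)
  frames$zone <- NULL
  structure(list(frames = frames, fps = fps, cage = cage,
                 odor_zone = as.integer(odor_zone), condition = condition,
                 duration_s = duration_s,
                 ground_truth = list(p_odor = p,
                                     realized_odor_fraction = realized)),
            class = "trajectory_session")
}

#' Write / read a trajectory session as CSV
#' @param session a `"trajectory_session"`.
#' @param path CSV path.
#' @return `path` invisibly; `read_trajectory()` returns the session.
#' @export
write_trajectory <- function(session, path) {
  utils::write.csv(session$frames, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param fps,cage,odor_zone,condition session metadata (not stored in the
#'   CSV itself).
#' @export
read_trajectory <- function(path, fps = 30, cage = c(45, 25),
                            odor_zone = 3L, condition = "odorant") {
  frames <- utils::read.csv(path)
  structure(list(frames = frames, fps = fps, cage = cage,
                 odor_zone = as.integer(odor_zone), condition = condition,
                 duration_s = nrow(frames) / fps, ground_truth = NULL),
            class = "trajectory_session")
}
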