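#' Zone occupancy of a tracked session
#'
#' Fraction of valid frames whose tracked point lies in each of the three
#' equal compartments along the cage's long axis.  Frames with missing
#' coordinates are dropped and counted, never interpolated.
#'
#' @param session a `"trajectory_session"` (see [generate_trajectory()]).
#' @param poi `"nose"` (default; the odorant question concerns sniffing
#'   position) or `"centroid"` (mean of the four tracked points).
#' @return list: `fractions` (length 3, sums to 1 over valid frames),
#'   `odor_fraction`, `odor_zone`, `n_valid`, `n_missing`.
#' @export
zone_occupancy <- function(session, poi = c("nose", "centroid")) {
  poi <- match.arg(poi)
  fr <- session$frames
  if (poi == "nose") {
    x <- fr$nose_x
  } else {
    x <- rowMeans(cbind(fr$nose_x, fr$earL_x, fr$earR_x, fr$tail_x))
  }
  valid <- !is.na(x)
  zone_w <- session$cage[1] / 3
  z <- pmin(pmax(floor(x[valid] / zone_w) + 1L, 1L), 3L)
  fractions <- tabulate(z, nbins = 3L) / length(z)
  list(fractions = fractions,
       odor_fraction = fractions[session$odor_zone],
       odor_zone = session$odor_zone,
       n_valid = sum(valid), n_missing = sum(!valid))
}

#' Odor-detection performance index
#'
#' `PI = pct_exp - pct_ctrl`, the percentage of session time spent in the
#' odorant compartment under the experimental odorant minus the same
#' percentage under the control condition (mineral oil).  100 means
#' unambiguous detection; near 0 means the odorant was not distinguished
#' from control.
#'
#' @param pct_exp,pct_ctrl occupancy percentages (0-100).
#' @return PI in percentage points, in \[-100, 100\].
#' @export
performance_index <- function(pct_exp, pct_ctrl) {
  stopifnot(pct_exp >= 0, pct_exp <= 100, pct_ctrl >= 0, pct_ctrl <= 100)
  pct_exp - pct_ctrl
}

#' Dwell-time occupancy heat map
#'
#' Bins the tracked point into an `nx` x `ny` grid over the cage; each cell
#' holds dwell time in seconds.  Cell times sum to the valid-frame
#' duration.
#'
#' @param session a `"trajectory_session"`.
#' @param nx,ny grid size (default 12 x 8).
#' @param poi tracked point as in [zone_occupancy()].
#' @return ny x nx matrix of seconds (rows = y from cage front to back).
#' @export
occupancy_heatmap <- function(session, nx = 12L, ny = 8L,
                              poi = c("nose", "centroid")) {
  poi <- match.arg(poi)
  fr <- session$frames
  if (poi == "nose") {
    x <- fr$nose_x; y <- fr$nose_y
  } else {
    x <- rowMeans(cbind(fr$nose_x, fr$earL_x, fr$earR_x, fr$tail_x))
    y <- rowMeans(cbind(fr$nose_y, fr$earL_y, fr$earR_y, fr$tail_y))
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  ix <- pmin(pmax(floor(x / session$cage[1] * nx) + 1L, 1L), nx)
  iy <- pmin(pmax(floor(y / session$cage[2] * ny) + 1L, 1L), ny)
  m <- matrix(0, ny, nx)
  tab <- table(factor(iy, levels = seq_len(ny)),
               factor(ix, levels = seq_len(nx)))
  m[] <- as.numeric(tab)
  m / session$fps
}

#' Wild-type-normalized food-seeking latency
#'
#' Divides each latency by the mean wild-type latency; observations at the
#' recording cutoff (10 min) are flagged as censored.
#'
#' @param latencies_s numeric latencies (s).
#' @param wt_latencies_s wild-type latencies used for the normalizer.
#' @param cutoff_s maximum recording time (default 600 s).
#' @return data frame: `latency_s`, `normalized`, `censored`.
#' @export
normalize_latency <- function(latencies_s, wt_latencies_s, cutoff_s = 600) {
  wt_mean <- mean(wt_latencies_s, na.rm = TRUE)
  if (!is.finite(wt_mean) || wt_mean <= 0) stop("invalid WT mean latency")
  data.frame(latency_s = latencies_s,
             normalized = latencies_s / wt_mean,
             censored = latencies_s >= cutoff_s)
}

#' Y-maze spontaneous alternation percentage
#'
#' `100 * actual alternations / (N - 2)`, where an actual alternation is a
#' window of three consecutive arm entries visiting all three arms, and
#' N is the total number of entries.
#'
#' @param entries character vector of arm labels (subset of A, B, C).
#' @return percentage, or `NA` when fewer than 3 entries are recorded.
#' @export
ymaze_alternation <- function(entries) {
  bad <- setdiff(unique(entries), c("A", "B", "C"))
  if (length(bad)) stop("unknown arm label(s): ", paste(bad, collapse = ", "))
  n <- length(entries)
  if (n < 3L) return(NA_real_)
  wins <- vapply(seq_len(n - 2L), function(i) {
    length(unique(entries[i:(i + 2L)])) == 3L
  }, logical(1))
  100 * sum(wins) / (n - 2L)
}
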