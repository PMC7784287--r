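#' Generate a synthetic A11 (amyloid-beta-oligomer) angular profile
#'
#' Emulates the angle-resolved DAB immunoreactivity of the glomerular layer.
#' Baseline intensity is flat at 1 (relative units) with per-bin Gaussian
#' noise; in the 5xFAD genotype the ventral bins (180 +/- 80 deg, circular)
#' are multiplied by `cfg$ab_ventral_gain`.  Optionally renders an RGB
#' hematoxylin + DAB section through the forward stain-mixing model so that
#' color deconvolution recovers the planted profile.
#'
#' @param cfg a [sim_config()].
#' @param plane `"sagittal"` (180 one-degree bins) or `"coronal"` (360).
#' @param render_image if `TRUE`, also return a synthetic RGB section.
#' @param image_px side of the rendered image (pixels).
#' @param band_px half-thickness of the rendered glomerular-layer band.
#' @param od_scale DAB optical density corresponding to profile value 1.
#' @return list with `profile` (class `"angular_profile"`, noisy),
#'   `ground_truth` (noise-free per-bin values), and when rendered:
#'   `image` (H x W x 3 array, 0-255), `contour`, `od_scale`.
#' @export
generate_histology_profile <- function(cfg, plane = c("coronal", "sagittal"),
                                       render_image = FALSE,
                                       image_px = 96L, band_px = 3,
                                       od_scale = 0.4) {
  stopifnot(inherits(cfg, "sim_config"))
  plane <- match.arg(plane)
  dom <- angular_domain(plane)
  edges <- seq(0, dom, by = 1)
  mids <- edges[-1] - 0.5
  base <- rep(1, length(mids))
  if (cfg$genotype == "5xFAD") {
    ventral <- circ_dist(mids, 180, 360) <= 80
    base[ventral] <- base[ventral] * cfg$ab_ventral_gain
  }
  noisy <- with_seed(derive_seed(cfg$seed, 301 + (plane == "coronal")), {
    pmax(base + rnorm(length(base), 0, cfg$hist_noise_sd), 0)
  })
  profile <- structure(list(plane = plane, bin_edges = edges, values = noisy,
                            n_contributing = rep(1L, length(mids))),
                       class = "angular_profile")
  out <- list(profile = profile, ground_truth = base, plane = plane)
  if (render_image) {
    ct <- ellipse_contour(image_px, plane = plane)
    img <- render_hdab_section(noisy, ct, image_px, band_px, od_scale)
    out$image <- img
    out$contour <- ct
    out$od_scale <- od_scale
  }
  out
}

# Paint the glomerular-layer band with DAB OD proportional to the profile
# value at each pixel's angle, hematoxylin counterstain over the tissue
# mask, and synthesize continuous RGB through the H-DAB forward model.
render_hdab_section <- function(values, contour, image_px, band_px,
                                od_scale, hema_od = 0.3) {
  mask <- attr(contour, "mask")
  xs <- matrix(seq_len(image_px), image_px, image_px, byrow = TRUE)
  ys <- matrix(seq_len(image_px), image_px, image_px)
  centers <- cbind(as.vector(xs), as.vector(ys))
  # distance of each pixel to the contour polyline (vertex distance)
  pts <- contour$points
  d2 <- outer(rowSums(centers^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(centers)), rowSums(pts^2)) -
    2 * centers %*% t(pts)
  nearest <- max.col(-d2, ties.method = "first")
  mind <- sqrt(pmax(d2[cbind(seq_len(nrow(centers)), nearest)], 0))
  in_band <- mind <= band_px
  ang <- assign_angle(centers[in_band, , drop = FALSE], contour)
  dom <- angular_domain(contour$plane)
  idx <- pmin(pmax(ceiling(ang), 1L), dom)
  od_dab <- numeric(nrow(centers))
  od_dab[in_band] <- od_scale * values[idx]
  od_dab <- matrix(od_dab, image_px, image_px)
  od_h <- matrix(0, image_px, image_px)
  od_h[mask] <- hema_od
  synth_hdab_image(od_h, od_dab)
}
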