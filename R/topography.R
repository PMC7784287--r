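#' Glomerular-layer contour
#'
#' An ordered trace of the glomerular layer in image pixel coordinates
#' (origin top-left, y increasing downward, so dorsal means smaller y).
#' The zero landmark is the point treated as 0 deg: the top of the
#' glomerular layer (for coronal sections, the point on the upper rostral
#' migratory stream track).  For coronal sections a center point is needed
#' to measure polar angles; it defaults to the contour centroid.
#'
#' @param points n x 2 numeric matrix (columns x, y) of ordered contour
#'   coordinates, n >= 3.
#' @param plane `"sagittal"` (angles 0-180 by normalized arc length) or
#'   `"coronal"` (angles 0-360 by polar angle about `center`).
#' @param zero_landmark index of the contour point mapped to 0 deg.
#' @param center length-2 point for coronal polar angles (default centroid).
#' @return an object of class `"glom_contour"`.
#' @export
glomerular_contour <- function(points, plane = c("sagittal", "coronal"),
                               zero_landmark = 1L, center = NULL) {
  plane <- match.arg(plane)
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L) {
    stop("contour needs an n x 2 matrix with n >= 3")
  }
  if (zero_landmark < 1L || zero_landmark > nrow(points)) {
    stop("zero_landmark must index a contour point")
  }
  if (is.null(center)) center <- colMeans(points)
  structure(list(points = points, plane = plane,
                 zero_landmark = as.integer(zero_landmark),
                 center = as.numeric(center),
                 arc = arc_length(points)),
            class = "glom_contour")
}

#' Angular domain of a section plane
#' @param plane `"sagittal"` or `"coronal"`.
#' @return 180 or 360 (degrees).
#' @export
angular_domain <- function(plane) {
  switch(plane, sagittal = 180, coronal = 360,
         stop("plane must be 'sagittal' or 'coronal'"))
}

#' Map ROI centers to degree positions on the glomerular layer
#'
#' Sagittal sections: each point is projected to its nearest contour vertex
#' and receives `180 * arc / total_arc`, where `arc` is the arc length from
#' the zero landmark, so the dorsal extreme maps to 0 deg and the ventral
#' extreme to 180 deg.  Coronal sections: the polar angle about the contour
#' center, measured from the ray through the zero landmark and increasing in
#' the direction the contour is ordered, in \[0, 360).
#'
#' @param centers n x 2 matrix (or length-2 vector) of ROI centers, pixel
#'   coordinates.
#' @param contour a [glomerular_contour()].
#' @param max_dist ROIs farther than this from the contour (same units as
#'   the coordinates) are excluded and returned as `NA` (default `Inf`).
#' @return numeric vector of degrees, `NA` for excluded ROIs, with attribute
#'   `"n_excluded"`.
#' @export
assign_angle <- function(centers, contour, max_dist = Inf) {
  stopifnot(inherits(contour, "glom_contour"))
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  centers <- as.matrix(centers)
  pts <- contour$points
  # nearest contour vertex and its distance, per center
  d2 <- outer(rowSums(centers^2), rep(1, nrow(pts))) +
    outer(rep(1, nrow(centers)), rowSums(pts^2)) -
    2 * centers %*% t(pts)
  nearest <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(centers)), nearest)], 0))

  if (contour$plane == "sagittal") {
    arc0 <- contour$arc[contour$zero_landmark]
    total <- max(abs(contour$arc - arc0))
    ang <- 180 * abs(contour$arc[nearest] - arc0) / total
  } else {
    ref <- contour$points[contour$zero_landmark, ] - contour$center
    ref_ang <- atan2(ref[2], ref[1])
    # orientation: direction of increasing contour order at the landmark
    nxt <- if (contour$zero_landmark < nrow(pts)) contour$zero_landmark + 1L else 1L
    v <- contour$points[nxt, ] - contour$center
    step <- (atan2(v[2], v[1]) - ref_ang) %% (2 * pi)
    orient <- if (step <= pi) 1 else -1
    rel <- centers - matrix(contour$center, nrow(centers), 2, byrow = TRUE)
    ang <- (orient * (atan2(rel[, 2], rel[, 1]) - ref_ang)) %% (2 * pi)
    ang <- ang * 180 / pi
  }
  excl <- dist > max_dist
  ang[excl] <- NA_real_
  structure(ang, n_excluded = sum(excl))
}

#' Bin values by angular position into an angular profile
#'
#' @param angles_deg angles of the contributing observations (degrees).
#' @param values one value per angle.
#' @param plane `"sagittal"` or `"coronal"`.
#' @param bin_deg bin width in degrees (default 1, giving the 180
#'   dorsoventral sections of a sagittal profile).
#' @return an object of class `"angular_profile"`: list with `plane`,
#'   `bin_edges`, `values` (per-bin mean, `NA` where empty) and
#'   `n_contributing`.
#' @export
build_profile <- function(angles_deg, values, plane = "sagittal", bin_deg = 1) {
  dom <- angular_domain(plane)
  keep <- !is.na(angles_deg) & !is.na(values)
  angles_deg <- angles_deg[keep]
  values <- values[keep]
  edges <- seq(0, dom, by = bin_deg)
  nb <- length(edges) - 1L
  # right-open bins; the closing angle of the domain joins the last bin
  idx <- pmin(findInterval(angles_deg, edges, rightmost.closed = TRUE), nb)
  ok <- idx >= 1L & angles_deg >= 0 & angles_deg <= dom
  sums <- tabulate_sum(idx[ok], values[ok], nb)
  n <- tabulate(idx[ok], nbins = nb)
  vals <- ifelse(n > 0, sums / n, NA_real_)
  structure(list(plane = plane, bin_edges = edges, values = vals,
                 n_contributing = n),
            class = "angular_profile")
}

tabulate_sum <- function(idx, values, nbins) {
  out <- numeric(nbins)
  if (length(idx)) {
    agg <- rowsum(values, group = idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  out
}

#' @export
as.data.frame.angular_profile <- function(x, ...) {
  data.frame(bin_start_deg = x$bin_edges[-length(x$bin_edges)],
             bin_end_deg = x$bin_edges[-1],
             value = x$values, n = x$n_contributing)
}

#' Classify an angle as dorsal, ventral, or unassigned
#'
#' Dorsal means within 80 deg (circular distance) of 0 deg; ventral within
#' 80 deg of 180 deg; anything else is unassigned.
#'
#' @param angle_deg numeric angles in degrees.
#' @param plane `"sagittal"` or `"coronal"` (sets the circular period).
#' @param halfwidth_deg region half-width (default 80).
#' @return character vector in `{"dorsal", "ventral", "unassigned"}`.
#' @export
region_classify <- function(angle_deg, plane = "sagittal", halfwidth_deg = 80) {
  period <- if (plane == "coronal") 360 else 360  # sagittal 0..180 embeds in the circle
  out <- rep("unassigned", length(angle_deg))
  out[circ_dist(angle_deg, 0, period) <= halfwidth_deg] <- "dorsal"
  out[circ_dist(angle_deg, 180, period) <= halfwidth_deg] <- "ventral"
  out[is.na(angle_deg)] <- NA_character_
  out
}

#' Dorsal and ventral means of an angular profile
#'
#' Missing-aware means over the bins whose centers classify as dorsal
#' (0 +/- 80 deg) or ventral (180 +/- 80 deg).
#'
#' @param profile an [build_profile()] result.
#' @return named numeric `c(dorsal =, ventral =)`.
#' @export
profile_region_summary <- function(profile) {
  stopifnot(inherits(profile, "angular_profile"))
  mids <- (profile$bin_edges[-1] + profile$bin_edges[-length(profile$bin_edges)]) / 2
  cls <- region_classify(mids, profile$plane)
  c(dorsal = mean(profile$values[cls == "dorsal"], na.rm = TRUE),
    ventral = mean(profile$values[cls == "ventral"], na.rm = TRUE))
}

#' Elliptical-arc contour used by the synthetic bulb geometry
#'
#' For the sagittal (lateral) view the glomerular layer is traced as the
#' posterior half-ellipse from the dorsal pole (top of the image) to the
#' ventral pole; for the coronal view the full ellipse, starting at the
#' dorsal pole.
#'
#' @param fov_px image side in pixels.
#' @param plane section plane.
#' @param n_points number of polyline vertices.
#' @return a [glomerular_contour()] plus attribute `"mask"` (logical
#'   fov x fov bulb mask) and `"semiaxes"`.
#' @export
ellipse_contour <- function(fov_px, plane = "sagittal", n_points = 721L) {
  cx <- (fov_px + 1) / 2
  cy <- (fov_px + 1) / 2
  rx <- 0.42 * fov_px
  ry <- 0.44 * fov_px
  if (plane == "sagittal") {
    th <- seq(pi / 2, -pi / 2, length.out = n_points)
  } else {
    th <- seq(pi / 2, pi / 2 - 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  }
  pts <- cbind(x = cx + rx * cos(th), y = cy - ry * sin(th))
  xs <- matrix(seq_len(fov_px), fov_px, fov_px, byrow = TRUE)
  ys <- matrix(seq_len(fov_px), fov_px, fov_px)
  mask <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  ct <- glomerular_contour(pts, plane = plane, zero_landmark = 1L,
                           center = c(cx, cy))
  attr(ct, "mask") <- mask
  attr(ct, "semiaxes") <- c(rx = rx, ry = ry)
  ct
}

#' Point on a sagittal contour at a given angular position
#' @param contour a sagittal [glomerular_contour()].
#' @param angle_deg degrees in \[0, 180\].
#' @return length-2 numeric (x, y).
#' @keywords internal
contour_point_at <- function(contour, angle_deg) {
  arc0 <- contour$arc[contour$zero_landmark]
  total <- max(abs(contour$arc - arc0))
  target <- arc0 + (angle_deg / 180) * total
  i <- which.min(abs(contour$arc - target))
  contour$points[i, ]
}
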