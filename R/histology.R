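#' Standard H-DAB stain vectors
#'
#' Unit optical-density vectors for hematoxylin and DAB (the widely used
#' published set), with the residual channel as their normalized cross
#' product.  Rows are stains, columns RGB.
#'
#' @return 3 x 3 matrix with rownames `hematoxylin`, `dab`, `residual`.
#' @export
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(m) <- c("R", "G", "B")
  m
}

#' Color deconvolution of an RGB brightfield image
#'
#' Converts intensities to optical densities, `OD = -log10(I / 255)`
#' (intensities floored at `eps` so blank pixels stay finite), and unmixes
#' them with the inverse stain matrix.  Negative stain densities are
#' clipped to zero.
#'
#' @param img H x W x 3 numeric array, intensities in \[0, 255\].
#' @param vectors 3 x 3 stain matrix (rows = unit stain OD vectors),
#'   default [hdab_stain_vectors()].
#' @param eps intensity floor preventing infinite OD (default 1e-3).
#' @return object of class `"stain_channels"`: named list of H x W OD
#'   matrices (one per stain row).
#' @export
color_deconvolve <- function(img, vectors = hdab_stain_vectors(),
                             eps = 1e-3) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (abs(det(vectors)) < 1e-12) stop("singular stain vector matrix")
  d <- dim(img)
  od <- -log10(pmax(img, eps) / 255)
  odm <- matrix(od, ncol = 3L)          # pixels x RGB
  conc <- odm %*% solve(vectors)        # pixels x stains
  conc[conc < 0] <- 0
  out <- lapply(seq_len(ncol(conc)),
                function(j) matrix(conc[, j], d[1], d[2]))
  names(out) <- rownames(vectors)
  structure(out, class = "stain_channels", vectors = vectors)
}

#' Forward H-DAB image synthesis
#'
#' Inverse of [color_deconvolve()] for the hematoxylin + DAB model:
#' `I_c = 255 * 10^-(od_h * H_c + od_dab * D_c)`.  Continuous-valued (no
#' 8-bit quantization), so synth -> deconvolve round-trips to numerical
#' precision.
#'
#' @param od_h,od_dab H x W matrices of per-pixel stain optical densities.
#' @param vectors stain matrix as in [color_deconvolve()].
#' @return H x W x 3 array of intensities in \[0, 255\].
#' @export
synth_hdab_image <- function(od_h, od_dab, vectors = hdab_stain_vectors()) {
  stopifnot(all(dim(od_h) == dim(od_dab)))
  d <- c(dim(od_h), 3L)
  img <- array(0, dim = d)
  for (c in 1:3) {
    img[, , c] <- 255 * 10^-(od_h * vectors["hematoxylin", c] +
                               od_dab * vectors["dab", c])
  }
  img
}

#' Percent stained area of a region
#'
#' `100 * #(pixels with OD > threshold within mask) / #(mask pixels)`.
#'
#' @param dab H x W DAB OD matrix.
#' @param threshold DAB positivity threshold (OD, default 0.15).
#' @param mask logical H x W region mask (default whole image).
#' @return percentage in \[0, 100\].
#' @export
percent_stain_area <- function(dab, threshold = 0.15, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(dab), ncol(dab))
  n <- sum(mask)
  if (n == 0L) stop("empty region")
  100 * sum(dab[mask] > threshold) / n
}

#' Reciprocal staining intensity per unit area
#'
#' Operationalized as `(255 - mean 8-bit intensity of the region) /
#' area_mm2`; the definition is recorded in the result's `"definition"`
#' attribute because the underlying measure is conventionally named but
#' not standardized.
#'
#' @param img H x W intensity matrix (0-255), or a vector of region
#'   intensities.
#' @param area_mm2 region area in square millimetres.
#' @param mask optional logical region mask.
#' @return numeric intensity per mm^2.
#' @export
reciprocal_intensity <- function(img, area_mm2, mask = NULL) {
  vals <- if (is.null(mask)) as.numeric(img) else img[mask]
  if (!length(vals)) stop("empty region")
  structure((255 - mean(vals)) / area_mm2,
            definition = "(255 - mean intensity) / area_mm2")
}

#' Angle-resolved immunoreactivity profile
#'
#' Composes stain unmixing with angular registration: pixels within
#' `max_dist_px` of the glomerular-layer contour are assigned degree
#' positions and their DAB OD averaged per angular bin.
#'
#' @param dab H x W DAB OD matrix (from [color_deconvolve()]), or an
#'   H x W x 3 RGB image (deconvolved internally).
#' @param contour a [glomerular_contour()].
#' @param bin_deg bin width (default 1 deg).
#' @param max_dist_px contour acceptance distance in pixels (the 300-um
#'   default divided by the pixel pitch in callers).
#' @return class `"angular_profile"`.
#' @export
angular_immunoreactivity <- function(dab, contour, bin_deg = 1,
                                     max_dist_px = 4) {
  if (length(dim(dab)) == 3L) dab <- color_deconvolve(dab)$dab
  H <- nrow(dab); W <- ncol(dab)
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  centers <- cbind(as.vector(xs), as.vector(ys))
  ang <- assign_angle(centers, contour, max_dist = max_dist_px)
  build_profile(ang, as.vector(dab), plane = contour$plane,
                bin_deg = bin_deg)
}

#' WT-dorsal-normalized region ratios
#'
#' Dorsal and ventral means of a wild-type and a transgenic angular
#' profile, all divided by the WT dorsal mean (so WT dorsal reads 1.00).
#'
#' @param profile_wt,profile_tg [build_profile()] results on the same
#'   plane.
#' @return named numeric: `wt_dorsal`, `tg_dorsal`, `wt_ventral`,
#'   `tg_ventral`.
#' @export
region_ratio <- function(profile_wt, profile_tg) {
  wt <- profile_region_summary(profile_wt)
  tg <- profile_region_summary(profile_tg)
  ref <- wt["dorsal"]
  c(wt_dorsal = unname(wt["dorsal"] / ref),
    tg_dorsal = unname(tg["dorsal"] / ref),
    wt_ventral = unname(wt["ventral"] / ref),
    tg_ventral = unname(tg["ventral"] / ref))
}

#' Group summaries of a marker count table
#'
#' Mean, SD and SEM per marker x region x genotype; SEM and SD are `NA`
#' for single-animal cells.
#'
#' @param counts a `"count_table"` data frame (see
#'   [generate_count_tables()]): columns `genotype`, `region`, `marker`,
#'   `value`.
#' @return data frame with columns `marker`, `region`, `genotype`, `n`,
#'   `mean`, `sd`, `sem`, `unit`.
#' @export
summarize_counts <- function(counts) {
  key <- interaction(counts$marker, counts$region, counts$genotype,
                     drop = TRUE)
  parts <- lapply(split(counts, key), function(d) {
    n <- sum(!is.na(d$value))
    s <- if (n >= 2) stats::sd(d$value, na.rm = TRUE) else NA_real_
    data.frame(marker = d$marker[1], region = d$region[1],
               genotype = d$genotype[1], n = n,
               mean = mean(d$value, na.rm = TRUE),
               sd = s, sem = s / sqrt(n),
               unit = if ("unit" %in% names(d)) d$unit[1] else NA_character_)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$marker, out$region, out$genotype), ]
}
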