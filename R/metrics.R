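#' Volume of interest centred on the heart
#'
#' An axis-aligned cubic VOI (default 18x18x18, 5832 voxels) anchored on the
#' LV centroid, shifted as needed to lie fully inside the volume.
#'
#' @param center numeric triple, 1-based voxel coordinates of the anchor.
#' @param vol_dim integer triple, the volume dimensions.
#' @param size VOI edge length in voxels (default 18).
#' @return list of index vectors `ix`, `iy`, `iz`.
#' @export
voi_box <- function(center, vol_dim, size = 18L) {
  if (any(vol_dim < size)) stop("volume is smaller than the VOI")
  lo <- pmin(pmax(round(center) - size %/% 2, 1L), vol_dim - size + 1L)
  list(ix = seq.int(lo[1], length.out = size),
       iy = seq.int(lo[2], length.out = size),
       iz = seq.int(lo[3], length.out = size))
}

crop_voi <- function(img, voi) {
  img <- if (inherits(img, "recon_volume")) img$image else as.array(img)
  if (is.null(voi)) img else img[voi$ix, voi$iy, voi$iz]
}

#' Voxel-level error indices over the heart VOI
#'
#' `nmse()` is `sum((I_D - I_FT)^2) / sum(I_FT^2)`; `ssim_voi()` is a single
#' global structural-similarity value over the VOI using VOI-wide moments
#' and the constants C1 = 0.01, C2 = 0.02; `psnr()` is
#' `10 log10(MAX_FT / MSE)` with `MAX_FT` the reference maximum over the VOI
#' (`convention = "standard"` uses `MAX_FT^2`). Identical images give
#' `nmse = 0`, `ssim = 1` and `psnr = Inf`.
#'
#' @param i_d test (e.g. denoised, reconstructed) volume or `recon_volume`.
#' @param i_ft reference (filtered full-time) volume.
#' @param voi a [voi_box()], or `NULL` for the whole volume.
#' @return a scalar.
#' @export
nmse <- function(i_d, i_ft, voi = NULL) {
  a <- crop_voi(i_d, voi); b <- crop_voi(i_ft, voi)
  if (!identical(dim(a), dim(b))) stop("volume shapes differ")
  denom <- sum(b^2)
  if (denom <= 0) stop("reference has zero energy in the VOI")
  sum((a - b)^2) / denom
}

#' @rdname nmse
#' @param C1,C2 stability constants of the SSIM formula (0.01, 0.02).
#' @export
ssim_voi <- function(i_d, i_ft, voi = NULL, C1 = 0.01, C2 = 0.02) {
  a <- crop_voi(i_d, voi); b <- crop_voi(i_ft, voi)
  if (!identical(dim(a), dim(b))) stop("volume shapes differ")
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- sum((a - mu_a)^2) / n
  vb <- sum((b - mu_b)^2) / n
  cab <- sum((a - mu_a) * (b - mu_b)) / n
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' @rdname nmse
#' @param convention `"paper"` uses MAX_FT in the numerator as printed in the
#'   protocol this package follows; `"standard"` uses MAX_FT^2.
#' @export
psnr <- function(i_d, i_ft, voi = NULL,
                 convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  a <- crop_voi(i_d, voi); b <- crop_voi(i_ft, voi)
  if (!identical(dim(a), dim(b))) stop("volume shapes differ")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  mx <- max(b)
  num <- if (convention == "paper") mx else mx^2
  10 * log10(num / mse)
}

#' Simplified polar (bull's-eye) map of LV wall uptake
#'
#' For each axial slice of the LV extent (apex to base mapped to rings) and
#' each angular sector, samples the maximum image value along the ray from
#' the LV long axis, the usual maximum-count circumferential profile. The
#' result is a `n_rings x n_angles` matrix; it is deterministic for a fixed
#' axis.
#'
#' @param v `recon_volume` or 3D array.
#' @param center in-plane LV centre, 1-based voxel coordinates `(cx, cy)`.
#' @param z_range inclusive axial slice range of the LV wall.
#' @param n_angles angular sectors (default 36).
#' @param r_max maximum sampling radius in voxels (default: to the volume
#'   edge).
#' @return matrix `[n_rings x n_angles]` with attribute `angles_rad`.
#' @export
polar_map <- function(v, center, z_range, n_angles = 36L, r_max = NULL) {
  img <- if (inherits(v, "recon_volume")) v$image else as.array(v)
  d <- dim(img)
  if (any(center < 1) || center[1] > d[1] || center[2] > d[2])
    stop("LV axis lies outside the volume")
  z_range <- as.integer(z_range)
  if (any(z_range < 1) || any(z_range > d[3]))
    stop("z_range outside the volume")
  r_max <- r_max %||% (min(d[1], d[2]) / 2 - 1)
  zs <- seq(z_range[1], z_range[2])
  angs <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  rs <- seq(0, r_max, by = 0.4)
  out <- matrix(0, length(zs), n_angles)
  for (zi in seq_along(zs)) {
    sl <- img[, , zs[zi]]
    for (ai in seq_len(n_angles)) {
      # nearest-voxel sampling along the ray, maximum-count profile;
      # interpolation would bias thin discretized walls low
      xs <- round(center[1] + rs * cos(angs[ai]))
      ys <- round(center[2] + rs * sin(angs[ai]))
      ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2]
      out[zi, ai] <- max(sl[cbind(xs[ok], ys[ok])])
    }
  }
  attr(out, "angles_rad") <- angs
  out
}

#' Defect and normal-region ROIs on a polar map
#'
#' Builds the pair of region masks used for the intensity ratio: `roi1`
#' covers the angular range of the (known or suspected) defect, `roi2` the
#' diametrically opposite sectors of the same rings. For subjects without a
#' defect a fixed default sector is used so that the same ROIs can be applied
#' to every method.
#'
#' @param map a [polar_map()].
#' @param phi0,dphi defect sector start and width in radians (defaults give a
#'   90-degree sector at 0).
#' @return list of logical matrices `roi1`, `roi2`.
#' @export
polar_rois <- function(map, phi0 = 0, dphi = pi / 2) {
  angs <- attr(map, "angles_rad")
  dang <- (angs - phi0) %% (2 * pi)
  in1 <- dang <= dphi
  in2 <- ((angs - (phi0 + pi)) %% (2 * pi)) <= dphi
  in2 <- in2 & !in1
  if (!any(in2)) in2 <- !in1
  nr <- nrow(map)
  rings <- seq_len(nr) > max(1, round(nr * 0.15)) # drop apex-most rings
  roi1 <- outer(rings, in1, `&`)
  roi2 <- outer(rings, in2, `&`)
  list(roi1 = roi1, roi2 = roi2)
}

#' Intensity ratio between defect and normal ROIs
#'
#' Mean polar-map value inside the defect ROI divided by the mean inside the
#' uniform normal ROI.
#'
#' @param map a [polar_map()].
#' @param rois a list with logical masks `roi1` (defect) and `roi2` (normal).
#' @return scalar intensity ratio.
#' @export
intensity_ratio <- function(map, rois) {
  if (!any(rois$roi1) || !any(rois$roi2)) stop("empty ROI")
  m2 <- mean(map[rois$roi2])
  if (m2 <= 0) stop("normal ROI has non-positive mean")
  mean(map[rois$roi1]) / m2
}

#' Threshold-based perfusion-defect-extent surrogate
#'
#' Percent of polar-map pixels falling below `threshold_fraction` times the
#' normal-region reference value, a documented stand-in for proprietary
#' clinical defect-size software (it is *not* that algorithm). The reference
#' is the mean of `rois$roi2` when ROIs are supplied, otherwise the median of
#' the map.
#'
#' @param map a [polar_map()] (or any numeric matrix).
#' @param threshold_fraction threshold in (0, 1), default 0.6.
#' @param rois optional [polar_rois()] supplying the normal region.
#' @return extent in percent of the map (0-100).
#' @export
defect_extent_surrogate <- function(map, threshold_fraction = 0.6,
                                    rois = NULL) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  ref <- if (!is.null(rois)) mean(map[rois$roi2]) else median(map)
  100 * mean(map < threshold_fraction * ref)
}

#' Bland-Altman limits of agreement
#'
#' Mean difference `a - b` with 95% limits of agreement
#' `mean_diff +/- 1.96 sd(diff)`.
#'
#' @param series_a,series_b paired measurements of equal length (n >= 2).
#' @return list with `mean_diff`, `lower95`, `upper95` and a data frame
#'   `points` of per-subject `(mean, diff)` for plotting.
#' @export
bland_altman <- function(series_a, series_b) {
  if (length(series_a) != length(series_b))
    stop("series must have equal length")
  if (length(series_a) < 2) stop("need at least two pairs")
  d <- series_a - series_b
  md <- mean(d)
  s <- sd(d)
  list(mean_diff = md, lower95 = md - 1.96 * s, upper95 = md + 1.96 * s,
       points = data.frame(mean = (series_a + series_b) / 2, diff = d))
}

#' Joint histogram and linear regression of pooled voxel values
#'
#' Ordinary least squares of the test values on the reference values
#' (reference on the x-axis), with R^2 the squared Pearson correlation, plus
#' a 2D joint histogram.
#'
#' @param i_ft_voxels reference voxel values (x-axis).
#' @param i_d_voxels test voxel values (y-axis).
#' @param n_bins histogram bins per axis (default 64).
#' @return list with `slope`, `intercept`, `r_squared`, `histogram`
#'   (counts matrix) and the bin `breaks`.
#' @export
joint_regression <- function(i_ft_voxels, i_d_voxels, n_bins = 64L) {
  x <- as.numeric(i_ft_voxels); y <- as.numeric(i_d_voxels)
  if (length(x) != length(y)) stop("voxel vectors must have equal length")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has no regression")
  fit <- lm(y ~ x)
  r2 <- suppressWarnings(stats::cor(x, y))^2
  rng <- range(c(x, y))
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- table(cut(x, br, include.lowest = TRUE),
             cut(y, br, include.lowest = TRUE))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, histogram = unclass(h), breaks = br)
}

#' Two-tailed paired t-test with Bonferroni correction
#'
#' The raw paired-t p-value is multiplied by `n_comparisons` and capped at 1.
#' Zero-variance differences are degenerate: the p-value is 1 when the
#' paired samples are identical and 0 when they differ by a constant, with a
#' warning.
#'
#' @param a,b paired samples of equal length.
#' @param n_comparisons number of simultaneous comparisons (default 1).
#' @return adjusted p-value.
#' @export
paired_test <- function(a, b, n_comparisons = 1L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  if (sd(d) == 0) {
    warning("zero-variance differences: degenerate paired test")
    return(if (mean(d) == 0) 1 else 0)
  }
  p <- t.test(a, b, paired = TRUE)$p.value
  min(1, p * n_comparisons)
}
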