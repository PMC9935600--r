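#' Acquisition specification
#'
#' Describes the SPECT acquisition geometry and count level: `n_views` views
#' spread over `arc_deg` degrees, `full_time_s` seconds per view at full time
#' (FT), and the mean counts per view the FT acquisition should contain (used
#' to calibrate the detector sensitivity).
#'
#' @param n_views number of projection views (default 60).
#' @param arc_deg angular arc covered by the views (default 180).
#' @param full_time_s full-time acquisition time per view in seconds
#'   (default 10).
#' @param mean_counts_per_view_at_full_time target mean total counts per view
#'   for the FT acquisition (default 2e4).
#' @param attenuation_on logical, model photon attenuation in the projector.
#' @param rng_seed integer seed for the counting-noise draws.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_views = 60L, arc_deg = 180,
                             full_time_s = 10,
                             mean_counts_per_view_at_full_time = 2e4,
                             attenuation_on = TRUE, rng_seed = 1L) {
  if (full_time_s <= 0) stop("full_time_s must be positive")
  if (mean_counts_per_view_at_full_time <= 0)
    stop("mean counts per view must be positive")
  structure(list(n_views = as.integer(n_views), arc_deg = arc_deg,
                 full_time_s = full_time_s,
                 mean_counts_per_view_at_full_time =
                   mean_counts_per_view_at_full_time,
                 attenuation_on = isTRUE(attenuation_on),
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_spec")
}

#' Construct a projection stack
#'
#' A projection stack holds the per-view count images as a 3D array with
#' dimensions `(n_views, n_bins, n_slices)` together with the view angles and
#' the per-view acquisition time.
#'
#' @param counts 3D array `(V, nx, nz)` of (expected or measured) counts.
#' @param angles_deg vector of view angles in degrees, one per view.
#' @param time_per_view_s acquisition time per view in seconds.
#' @param is_noisy logical, whether `counts` are Poisson-realized integers.
#' @param attenuation_on logical, whether attenuation was modelled.
#' @return an object of class `projection_stack`.
#' @export
projection_stack <- function(counts, angles_deg, time_per_view_s,
                             is_noisy = FALSE, attenuation_on = TRUE) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L) stop("counts must be a 3D array (V, nx, nz)")
  if (dim(counts)[1] != length(angles_deg))
    stop("first dimension of counts must match the number of angles")
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, angles_deg = as.numeric(angles_deg),
                 time_per_view_s = time_per_view_s,
                 is_noisy = isTRUE(is_noisy),
                 attenuation_on = isTRUE(attenuation_on)),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf(
    "<projection_stack> %d views x %dx%d, %.3g s/view, %stotal %.4g counts\n",
    dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3], x$time_per_view_s,
    if (x$is_noisy) "noisy, " else "noiseless, ", sum(x$counts)))
  invisible(x)
}

#' Parallel-beam projection operator (line integrals)
#'
#' The raw linear operator `A`: in-plane rotation of the volume per view
#' (bilinear interpolation) followed by summation along one axis, with
#' optional attenuation weighting `exp(-integral of mu)` along each ray.
#' [backproject_op()] is its exact matrix transpose, as required by OS-EM.
#'
#' @param vol 3D array `(nx, ny, nz)`, e.g. a phantom activity map.
#' @param angles_deg vector of view angles in degrees.
#' @param attenuation optional 3D attenuation map (cm^-1), same shape.
#' @param voxel_cm voxel size in cm (ray-length element).
#' @return 3D array `(V, nx, nz)` of line integrals.
#' @export
project_op <- function(vol, angles_deg, attenuation = NULL, voxel_cm = 1) {
  vol <- as.array(vol)
  d <- dim(vol)
  if (length(d) != 3L) stop("vol must be 3D")
  if (!is.null(attenuation) && !identical(dim(as.array(attenuation)), d))
    stop("activity/attenuation shape mismatch")
  out <- cpp_project_forward(as.numeric(vol), as.integer(d),
                             if (is.null(attenuation)) NULL
                             else as.numeric(attenuation),
                             angles_deg * pi / 180, voxel_cm)
  array(out, c(length(angles_deg), d[1], d[3]))
}

#' @rdname project_op
#' @param stack_arr 3D array `(V, nx, nz)` to backproject.
#' @param vol_dim integer triple, the volume grid.
#' @export
backproject_op <- function(stack_arr, vol_dim, angles_deg,
                           attenuation = NULL, voxel_cm = 1) {
  stack_arr <- as.array(stack_arr)
  vol_dim <- as.integer(vol_dim)
  if (!is.null(attenuation) &&
      !identical(dim(as.array(attenuation)), vol_dim))
    stop("attenuation/grid shape mismatch")
  out <- cpp_project_adjoint(as.numeric(stack_arr), vol_dim,
                             if (is.null(attenuation)) NULL
                             else as.numeric(attenuation),
                             angles_deg * pi / 180, voxel_cm)
  array(out, vol_dim)
}

#' Forward-project a phantom into a noiseless full-time projection stack
#'
#' Computes attenuated line integrals for the views of `spec` and scales them
#' to counts. With `sensitivity = NULL` (default) a detector sensitivity is
#' calibrated so the FT stack's mean counts per view equals
#' `spec$mean_counts_per_view_at_full_time`; passing an explicit sensitivity
#' keeps the operator strictly linear in the activity.
#'
#' @param p a `phantom_volume`.
#' @param spec an [acquisition_spec()].
#' @param sensitivity detector sensitivity (counts per line-integral unit per
#'   second), or `NULL` to auto-calibrate.
#' @return a noiseless `projection_stack`; the sensitivity used is stored in
#'   attribute `"sensitivity"`.
#' @export
forward_project <- function(p, spec, sensitivity = NULL) {
  stopifnot(inherits(p, "phantom_volume"), inherits(spec, "acquisition_spec"))
  V <- spec$n_views
  angles <- spec$arc_deg * (seq_len(V) - 1) / V
  mu <- if (spec$attenuation_on) p$attenuation else NULL
  li <- project_op(p$activity, angles, mu, p$voxel_size_cm)
  raw <- li * spec$full_time_s
  if (is.null(sensitivity)) {
    mpv <- sum(raw) / V
    if (mpv <= 0) sensitivity <- 1
    else sensitivity <- spec$mean_counts_per_view_at_full_time / mpv
  }
  st <- projection_stack(raw * sensitivity, angles, spec$full_time_s,
                         is_noisy = FALSE,
                         attenuation_on = spec$attenuation_on)
  attr(st, "sensitivity") <- sensitivity
  st
}

#' Apply Poisson counting noise to a noiseless stack
#'
#' Each bin is replaced by an independent Poisson draw with mean equal to the
#' noiseless bin value.
#'
#' @param stack a noiseless `projection_stack`.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return a noisy, integer-valued `projection_stack`.
#' @export
add_poisson <- function(stack, seed) {
  stopifnot(inherits(stack, "projection_stack"))
  if (stack$is_noisy) stop("stack is already noisy")
  counts <- with_seed(seed, {
    array(rpois(length(stack$counts), stack$counts), dim(stack$counts))
  })
  out <- stack
  out$counts <- counts
  out$is_noisy <- TRUE
  out
}

#' Reduce the acquisition time by binomial count thinning
#'
#' Emulates truncating list-mode data at `target_time_s / time_per_view_s` of
#' the events: each bin count n is replaced by a Binomial(n, p) draw with
#' p = target/full time. The result has exactly the marginal Poisson
#' statistics of a shorter acquisition.
#'
#' @param stack a noisy, integer-valued `projection_stack`.
#' @param target_time_s target acquisition time per view, `<= time_per_view_s`.
#' @param seed integer seed.
#' @return a `projection_stack` at the reduced time.
#' @export
thin_to_time <- function(stack, target_time_s, seed) {
  stopifnot(inherits(stack, "projection_stack"))
  if (!stack$is_noisy) stop("thinning requires a noisy (measured) stack")
  if (any(stack$counts != round(stack$counts)))
    stop("thinning requires integer counts")
  p <- target_time_s / stack$time_per_view_s
  if (p > 1) stop("target time exceeds the stack's time per view")
  if (p <= 0) stop("target time must be positive")
  if (p == 1) return(stack)
  counts <- with_seed(seed, {
    array(rbinom(length(stack$counts), size = as.integer(stack$counts),
                 prob = p), dim(stack$counts))
  })
  out <- stack
  out$counts <- counts
  out$time_per_view_s <- target_time_s
  out
}

#' Write / read a projection stack as NIfTI plus a JSON sidecar
#'
#' @param stack a `projection_stack`.
#' @param prefix output path prefix; writes `<prefix>.nii` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "projection_stack"))
  RNifti::writeNifti(RNifti::asNifti(stack$counts), paste0(prefix, ".nii"))
  jsonlite::write_json(list(angles_deg = stack$angles_deg,
                            time_per_view_s = stack$time_per_view_s,
                            is_noisy = stack$is_noisy,
                            attenuation_on = stack$attenuation_on),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  arr <- RNifti::readNifti(paste0(prefix, ".nii"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  projection_stack(array(as.numeric(arr), dim(arr)), meta$angles_deg,
                   meta$time_per_view_s, meta$is_noisy, meta$attenuation_on)
}
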