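#' Cohort specification for the synthetic cardiac phantom generator
#'
#' Describes a cohort of synthetic subjects: a truncated ellipsoidal-shell
#' left-ventricular myocardium with uniform tracer uptake inside a soft-tissue
#' body ellipse with low-attenuation lungs, an optional wedge-shaped perfusion
#' defect (reduced uptake), and a binary defect label. Defaults reproduce the
#' prevalence of perfusion defects typical of a clinical stress cohort (36%).
#'
#' All geometric quantities are sampled per subject from the stated intervals;
#' generation is a pure function of `(rng_seed, subject_index)`.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param defect_fraction probability that a subject carries a perfusion
#'   defect (default 0.36).
#' @param grid_shape integer triple, reconstruction/phantom grid (default
#'   64 x 64 x 24).
#' @param voxel_size_cm voxel edge length in cm (default 0.6096).
#' @param wall_radius_cm_range interval for the outer LV semi-axis (in-plane,
#'   cm).
#' @param wall_axis_ratio_range interval for the long-axis/short-axis ratio.
#' @param wall_thickness_cm_range interval for the myocardial wall thickness
#'   (cm).
#' @param orientation_jitter_deg maximum tilt of the LV long axis (degrees).
#' @param defect_extent_range interval for the target defect extent as a
#'   fraction of the wall.
#' @param defect_severity_range interval for the fractional uptake reduction
#'   inside the defect (1 = no uptake).
#' @param background_ratio background (soft tissue / blood pool) uptake
#'   relative to the myocardial wall.
#' @param liver_insert logical, add a moderate-uptake liver-like ellipsoid
#'   below the heart (off by default).
#' @param rng_seed integer seed controlling the whole cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50L,
                        defect_fraction = 0.36,
                        grid_shape = c(64L, 64L, 24L),
                        voxel_size_cm = 0.6096,
                        wall_radius_cm_range = c(2.6, 3.4),
                        wall_axis_ratio_range = c(1.4, 1.8),
                        wall_thickness_cm_range = c(0.9, 1.3),
                        orientation_jitter_deg = 8,
                        defect_extent_range = c(0.05, 0.25),
                        defect_severity_range = c(0.5, 1.0),
                        background_ratio = 0.1,
                        liver_insert = FALSE,
                        rng_seed = 1L) {
  if (any(grid_shape < 16L))
    stop("grid_shape must be at least 16 in every dimension")
  if (defect_fraction < 0 || defect_fraction > 1)
    stop("defect_fraction must lie in [0, 1]")
  if (any(defect_severity_range < 0) || any(defect_severity_range > 1))
    stop("defect severity must lie in [0, 1]")
  rngs <- list(wall_radius_cm_range, wall_axis_ratio_range,
               wall_thickness_cm_range, defect_extent_range,
               defect_severity_range)
  if (any(vapply(rngs, function(r) diff(range(r)) < 0 || any(!is.finite(r)),
                 logical(1))))
    stop("all sampling intervals must be finite and nonempty")
  structure(list(
    n_subjects = as.integer(n_subjects),
    defect_fraction = defect_fraction,
    grid_shape = as.integer(grid_shape),
    voxel_size_cm = voxel_size_cm,
    wall_radius_cm_range = wall_radius_cm_range,
    wall_axis_ratio_range = wall_axis_ratio_range,
    wall_thickness_cm_range = wall_thickness_cm_range,
    orientation_jitter_deg = orientation_jitter_deg,
    defect_extent_range = defect_extent_range,
    defect_severity_range = defect_severity_range,
    background_ratio = background_ratio,
    liver_insert = liver_insert,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_spec")
}

# attenuation coefficients at 140 keV, cm^-1
MU_SOFT <- 0.15
MU_LUNG <- 0.04

#' Generate one synthetic subject
#'
#' Produces paired activity and attenuation volumes with a ground-truth defect
#' mask. The myocardium is a truncated ellipsoidal shell with uniform uptake 1,
#' reduced by the sampled severity inside the defect wedge; background tissue
#' has uptake `background_ratio`. The attenuation map is a soft-tissue body
#' ellipse with two low-attenuation lung regions.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 0-based subject index, `< n_subjects`.
#' @return an object of class `phantom_volume` with fields `activity`,
#'   `attenuation`, `defect_mask`, `wall_mask`, `defect_label`,
#'   `voxel_size_cm`, `grid_shape`, `lv_center`, `defect_pars`, `z_extent`.
#' @export
make_phantom <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  subject_index <- as.integer(subject_index)
  if (subject_index < 0L || subject_index >= spec$n_subjects)
    stop("subject_index must lie in [0, n_subjects)")
  with_seed(subject_seed(spec$rng_seed, subject_index), {
    dims <- spec$grid_shape
    vx <- spec$voxel_size_cm
    runif_in <- function(r) runif(1, r[1], r[2])

    r_short <- runif_in(spec$wall_radius_cm_range)
    r_long <- r_short * runif_in(spec$wall_axis_ratio_range)
    thick <- runif_in(spec$wall_thickness_cm_range)
    tilt <- runif(1, -1, 1) * spec$orientation_jitter_deg * pi / 180

    has_defect <- runif(1) < spec$defect_fraction
    target_extent <- runif_in(spec$defect_extent_range)
    severity <- runif_in(spec$defect_severity_range)
    phi0 <- runif(1, 0, 2 * pi)
    # transmural full-length wedge: its angular share is its wall share
    dphi <- min(2 * pi, target_extent * 2 * pi)

    # physical coordinates centred on the grid
    cx <- (dims[1] - 1) / 2 + runif(1, -1, 1)
    cy <- (dims[2] - 1) / 2 + runif(1, -1, 1)
    cz <- (dims[3] - 1) / 2 + runif(1, -0.5, 0.5)
    xs <- (seq_len(dims[1]) - 1 - cx) * vx
    ys <- (seq_len(dims[2]) - 1 - cy) * vx
    zs <- (seq_len(dims[3]) - 1 - cz) * vx
    X <- array(rep(xs, times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(zs, each = dims[1] * dims[2]), dims)

    # tilt the long axis in the (y, z) plane
    Yt <- cos(tilt) * Y + sin(tilt) * Z
    Zt <- -sin(tilt) * Y + cos(tilt) * Z

    e_out <- (X / r_short)^2 + (Yt / r_short)^2 + (Zt / r_long)^2
    ri_s <- max(r_short - thick, 0.3)
    ri_l <- max(r_long - thick, 0.5)
    e_in <- (X / ri_s)^2 + (Yt / ri_s)^2 + (Zt / ri_l)^2
    trunc <- Zt <= 0.55 * r_long # open at the basal side
    wall <- e_out <= 1 & e_in >= 1 & trunc
    cavity <- e_in < 1 & trunc

    defect <- array(FALSE, dims)
    if (has_defect) {
      ang <- atan2(Yt, X) %% (2 * pi)
      dang <- (ang - phi0) %% (2 * pi)
      defect <- wall & dang <= dphi
    }

    activity <- array(0, dims)
    body_a <- (X / ((dims[1] / 2 - 1) * vx))^2 +
      (Y / ((dims[2] / 2 - 1) * vx))^2
    body <- body_a <= 1
    activity[body] <- spec$background_ratio
    activity[cavity] <- spec$background_ratio
    activity[wall] <- 1
    activity[defect] <- 1 - severity

    attenuation <- array(0, dims)
    attenuation[body] <- MU_SOFT
    lung_r <- 0.28 * dims[1] * vx
    lungL <- ((X - 0.30 * dims[1] * vx) / lung_r)^2 +
      ((Y + 0.15 * dims[2] * vx) / (1.3 * lung_r))^2
    lungR <- ((X + 0.30 * dims[1] * vx) / lung_r)^2 +
      ((Y + 0.15 * dims[2] * vx) / (1.3 * lung_r))^2
    attenuation[body & (lungL <= 1 | lungR <= 1)] <- MU_LUNG

    if (spec$liver_insert) {
      liv <- ((X + 0.25 * dims[1] * vx) / (0.25 * dims[1] * vx))^2 +
        ((Y - 0.25 * dims[2] * vx) / (0.2 * dims[2] * vx))^2
      activity[body & liv <= 1 & !wall] <- 0.5
    }

    zw <- which(apply(wall, 3, any))
    # slices with both wall and cavity: the well-defined polar-map rings
    zr <- which(apply(wall, 3, any) & apply(cavity, 3, any))
    structure(list(
      activity = activity,
      attenuation = attenuation,
      defect_mask = defect,
      wall_mask = wall,
      defect_label = as.integer(any(defect)),
      voxel_size_cm = vx,
      grid_shape = dims,
      lv_center = c(cx + 1, cy + 1, cz + 1), # 1-based voxel coordinates
      defect_pars = list(phi0 = phi0, dphi = dphi, severity = severity,
                         tilt = tilt),
      z_extent = if (length(zw)) range(zw) else c(NA_integer_, NA_integer_),
      ring_z_extent = if (length(zr)) range(zr)
                      else c(NA_integer_, NA_integer_),
      subject_index = subject_index
    ), class = "phantom_volume")
  })
}

#' Ground-truth defect extent of a phantom
#'
#' Defect volume as a percentage of the myocardial wall, the ground truth
#' against which the polar-map defect-extent surrogate is judged.
#'
#' @param p a `phantom_volume`.
#' @return extent in percent of the wall (0-100).
#' @export
defect_extent <- function(p) {
  stopifnot(inherits(p, "phantom_volume"))
  nw <- sum(p$wall_mask)
  if (nw == 0) stop("phantom has an empty myocardium")
  100 * sum(p$defect_mask) / nw
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf(
    "<phantom_volume> subject %d: %s grid, %.3f cm voxels, defect=%d (%.1f%% of wall)\n",
    x$subject_index, paste(x$grid_shape, collapse = "x"), x$voxel_size_cm,
    x$defect_label, if (x$defect_label) defect_extent(x) else 0))
  invisible(x)
}

#' Write / read a phantom as NIfTI plus a JSON sidecar
#'
#' The activity, attenuation and defect-mask volumes are written as three
#' NIfTI files `<prefix>_activity.nii`, `<prefix>_mu.nii`,
#' `<prefix>_defect.nii` (voxel size in the header) and the scalar metadata
#' (defect label, extent, subject index) as `<prefix>.json`.
#'
#' @param p a `phantom_volume`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_phantom <- function(p, prefix) {
  stopifnot(inherits(p, "phantom_volume"))
  pd <- rep(p$voxel_size_cm * 10, 3) # NIfTI pixdim in mm
  RNifti::writeNifti(RNifti::asNifti(p$activity, pixdim = pd),
                     paste0(prefix, "_activity.nii"))
  RNifti::writeNifti(RNifti::asNifti(p$attenuation, pixdim = pd),
                     paste0(prefix, "_mu.nii"))
  RNifti::writeNifti(RNifti::asNifti(p$defect_mask + 0, pixdim = pd),
                     paste0(prefix, "_defect.nii"))
  meta <- list(defect_label = p$defect_label,
               defect_extent_pct = if (sum(p$wall_mask)) defect_extent(p) else 0,
               voxel_size_cm = p$voxel_size_cm,
               lv_center = p$lv_center,
               z_extent = p$z_extent,
               subject_index = p$subject_index)
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(prefix) {
  act <- RNifti::readNifti(paste0(prefix, "_activity.nii"))
  mu <- RNifti::readNifti(paste0(prefix, "_mu.nii"))
  dm <- RNifti::readNifti(paste0(prefix, "_defect.nii"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  # full-uptake voxels plus defect voxels make up the wall
  wall <- array(as.array(act) == 1 | as.array(dm) > 0.5, dim(act))
  structure(list(
    activity = array(as.numeric(act), dim(act)),
    attenuation = array(as.numeric(mu), dim(mu)),
    defect_mask = array(as.array(dm) > 0.5, dim(dm)),
    wall_mask = wall,
    defect_label = as.integer(meta$defect_label),
    voxel_size_cm = meta$voxel_size_cm,
    grid_shape = dim(act),
    lv_center = meta$lv_center,
    defect_pars = NULL,
    z_extent = meta$z_extent,
    subject_index = meta$subject_index
  ), class = "phantom_volume")
}
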