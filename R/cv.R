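#' Five-fold cross-validation plan
#'
#' Deterministically partitions the subjects into 5 folds by a seeded shuffle
#' followed by contiguous test blocks; the five test sets partition the
#' cohort exactly. Within each fold the remaining subjects split into
#' validation and training with the 70/10/20 proportions of the study design
#' (35/5/10 for 50 subjects).
#'
#' @param subject_ids vector of unique subject identifiers; length divisible
#'   by 10.
#' @param seed integer seed for the shuffle.
#' @param n_folds number of folds (default 5).
#' @return list of `fold_plan` objects with `fold_id`, `train_ids`,
#'   `val_ids`, `test_ids`.
#' @export
make_folds <- function(subject_ids, seed = 1L, n_folds = 5L) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (n %% (2L * n_folds) != 0)
    stop("cohort size must divide into the 70/10/20 split")
  n_test <- n %/% n_folds
  n_val <- n %/% (2L * n_folds)
  ord <- with_seed(seed, sample(subject_ids))
  lapply(seq_len(n_folds) - 1L, function(k) {
    test <- ord[k * n_test + seq_len(n_test)]
    rest <- ord[!ord %in% test]
    val <- rest[seq_len(n_val)]
    train <- rest[-seq_len(n_val)]
    structure(list(fold_id = k, train_ids = train, val_ids = val,
                   test_ids = test, rng_seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' Build a synthetic cohort with projections, thinned stacks and references
#'
#' Generates `n` phantoms, forward-projects them at full time, applies
#' Poisson noise, thins the noisy stacks to each requested time level, and
#' reconstructs the filtered full-time reference and the raw fast
#' reconstructions. Defaults are the desk-scale study conditions used by the
#' package's experiments: 32^3 phantoms at 1.2 cm voxels, 8 views over 180
#' degrees, 10 s/view at 20,000 mean counts per view.
#'
#' @param n cohort size (default 50).
#' @param seed cohort seed (default 7); phantom geometry, counting noise and
#'   thinning all derive from it.
#' @param grid phantom grid (default `c(32, 32, 32)`).
#' @param voxel_cm voxel size in cm (default 1.2).
#' @param n_views projection views over 180 degrees (default 8).
#' @param time_levels_s fast acquisition times to thin to, in s/view
#'   (default 1).
#' @param full_time_s full acquisition time (default 10 s/view).
#' @param mean_counts_per_view FT count level (default 2e4).
#' @param defect_fraction cohort defect prevalence (default 0.36).
#' @param recon logical; precompute reference and fast reconstructions.
#' @return list of per-subject records (class `spect_cohort`): `phantom`,
#'   `ft` (noisy FT stack), `fast` (named list by time level), `ref` (filtered
#'   FT `recon_volume`), `fast_recon` (named list), `voi`, `norm_scale`.
#' @export
build_cohort <- function(n = 50L, seed = 7L, grid = c(32L, 32L, 32L),
                         voxel_cm = 1.2, n_views = 8L, time_levels_s = 1,
                         full_time_s = 10, mean_counts_per_view = 2e4,
                         defect_fraction = 0.36, recon = TRUE) {
  # the myocardium is proportionally enlarged relative to clinical anatomy
  # so that the wall stays resolvable (~2 voxels thick) on the coarse desk
  # grid; at the clinical 64 x 64 grid the anatomical defaults of
  # cohort_spec() apply
  cspec <- cohort_spec(n_subjects = n, defect_fraction = defect_fraction,
                       grid_shape = grid, voxel_size_cm = voxel_cm,
                       wall_radius_cm_range = c(4.0, 5.0) * voxel_cm / 1.2,
                       wall_thickness_cm_range = c(1.7, 2.2) * voxel_cm / 1.2,
                       rng_seed = seed)
  aspec <- acquisition_spec(n_views = n_views, full_time_s = full_time_s,
                            mean_counts_per_view_at_full_time =
                              mean_counts_per_view, rng_seed = seed)
  ref_settings <- recon_settings(postfilter_sigma_voxels = 0.6)
  fast_settings <- recon_settings(postfilter_sigma_voxels = 0)
  subjects <- lapply(seq_len(n) - 1L, function(i) {
    ph <- make_phantom(cspec, i)
    ft0 <- forward_project(ph, aspec)
    ft <- add_poisson(ft0, subject_seed(seed, i, salt = 1L))
    fast <- lapply(seq_along(time_levels_s), function(j) {
      thin_to_time(ft, time_levels_s[j], subject_seed(seed, i, salt = 1L + j))
    })
    names(fast) <- as.character(time_levels_s)
    rec <- list(ref = NULL, fast_recon = NULL)
    if (recon) {
      ref <- osem_reconstruct(ft, ref_settings, attenuation = ph$attenuation,
                              voxel_cm = voxel_cm)
      ref <- gaussian_postfilter(ref, 0.6)
      fr <- lapply(fast, function(st)
        osem_reconstruct(st, fast_settings, attenuation = ph$attenuation,
                         voxel_cm = voxel_cm))
      rec <- list(ref = ref, fast_recon = fr)
    }
    list(id = i, phantom = ph, ft = ft, fast = fast,
         ref = rec$ref, fast_recon = rec$fast_recon,
         voi = voi_box(ph$lv_center, grid),
         norm_scale = max(ft$counts))
  })
  structure(list(subjects = subjects, seed = seed, grid = grid,
                 voxel_cm = voxel_cm, n_views = n_views,
                 full_time_s = full_time_s, time_levels_s = time_levels_s,
                 ref_settings = ref_settings, fast_settings = fast_settings),
            class = "spect_cohort")
}

#' @export
print.spect_cohort <- function(x, ...) {
  nd <- sum(vapply(x$subjects, function(s) s$phantom$defect_label,
                   numeric(1)))
  cat(sprintf(
    "<spect_cohort> %d subjects (%d with defect), %s grid, %d views, levels %s s/view\n",
    length(x$subjects), nd, paste(x$grid, collapse = "x"), x$n_views,
    paste(x$time_levels_s, collapse = "/")))
  invisible(x)
}

# evaluate one reconstructed volume against the subject's reference
evaluate_subject <- function(subject, vol) {
  ph <- subject$phantom
  ref <- subject$ref
  voi <- subject$voi
  zr <- ph$ring_z_extent %||% ph$z_extent
  ctr <- ph$lv_center[1:2]
  dp <- ph$defect_pars
  phi0 <- if (!is.null(dp) && ph$defect_label == 1) dp$phi0 else 0
  dphi <- if (!is.null(dp) && ph$defect_label == 1) max(dp$dphi, pi / 6)
          else pi / 2
  map_ref <- polar_map(ref, ctr, zr)
  map_v <- polar_map(vol, ctr, zr)
  rois <- polar_rois(map_ref, phi0, dphi)
  ir_ref <- intensity_ratio(map_ref, rois)
  # a degenerate (near-empty) map from a poorly trained model must not
  # abort the experiment
  ir_v <- tryCatch(intensity_ratio(map_v, rois),
                   error = function(e) NA_real_)
  pds_ref <- defect_extent_surrogate(map_ref, rois = rois)
  pds_v <- if (mean(map_v[rois$roi2]) <= 0) 100
           else defect_extent_surrogate(map_v, rois = rois)
  c(nmse = nmse(vol, ref, voi),
    ssim = ssim_voi(vol, ref, voi),
    psnr = psnr(vol, ref, voi),
    ir_abs_err = abs(ir_v - ir_ref),
    pds = pds_v,
    pds_ref = pds_ref,
    pds_abs_err = abs(pds_v - pds_ref))
}

make_pairs <- function(cohort, ids, level) {
  lv <- as.character(level)
  lapply(ids, function(i) {
    s <- cohort$subjects[[i + 1L]]
    make_training_sample(s$fast[[lv]], s$ft, s$phantom$defect_label)
  })
}

# train one denoiser on the given cohort subjects; method in
# c("attgan", "attgan_def", "cgan", "unet")
train_method <- function(cohort, method, train_ids, val_ids, level, cfg,
                         n_levels = 3L, base_filters = 16L,
                         dropout_rate = 0.1) {
  defect_cond <- method == "attgan_def"
  spec <- generator_spec(
    n_levels = n_levels, base_filters = base_filters,
    dropout_rate = dropout_rate,
    attention_enabled = method %in% c("attgan", "attgan_def"))
  if (method == "unet") cfg$adversarial_weight <- 0
  fit <- train_denoiser(make_pairs(cohort, train_ids, level), cfg, spec,
                        val_pairs = if (length(val_ids))
                          make_pairs(cohort, val_ids, level),
                        defect_conditioned = defect_cond)
  attr(fit$net, "full_time_s") <- cohort$full_time_s
  attr(fit$net, "time_level_s") <- as.numeric(level)
  attr(fit$net, "train_ids") <- train_ids
  fit
}

#' Run the dose-specific cross-validation experiment
#'
#' For every fold, time level and method: train the denoiser on the training
#' subjects (skipped for the `"identity"` method, which passes the fast stack
#' through unchanged), denoise the test stacks, reconstruct them with OS-EM
#' without post-filter, and evaluate against the subject's filtered full-time
#' reference. Model training records its subject ids and evaluation refuses
#' test subjects seen in training (leakage guard).
#'
#' @param cohort a [build_cohort()] with reconstructions.
#' @param methods character vector from `"identity"`, `"attgan"`,
#'   `"attgan_def"`, `"cgan"`, `"unet"`.
#' @param time_levels_s time levels to evaluate (default: the cohort's).
#' @param folds a [make_folds()] plan, default a 5-fold plan seeded by the
#'   cohort seed.
#' @param cfg a [train_config()] for the learned methods.
#' @param n_levels,base_filters,dropout_rate generator hyper-parameters
#'   (desk-scale defaults: 3 levels, 16 filters, dropout 0.1; see the
#'   methods vignette for how they were selected).
#' @return tidy data frame with columns `subject`, `method`, `time_level`,
#'   `fold`, `metric`, `value`.
#' @export
run_experiment <- function(cohort, methods = "identity",
                           time_levels_s = NULL, folds = NULL,
                           cfg = train_config(),
                           n_levels = 3L, base_filters = 16L,
                           dropout_rate = 0.1) {
  stopifnot(inherits(cohort, "spect_cohort"))
  time_levels_s <- time_levels_s %||% cohort$time_levels_s
  ids <- vapply(cohort$subjects, `[[`, numeric(1), "id")
  folds <- folds %||% make_folds(ids, seed = cohort$seed)
  rows <- list()
  for (fold in folds) {
    for (level in time_levels_s) {
      lv <- as.character(level)
      for (method in methods) {
        model <- NULL
        if (method != "identity") {
          model <- train_method(cohort, method, fold$train_ids,
                                fold$val_ids, level, cfg,
                                n_levels, base_filters, dropout_rate)$net
          if (length(intersect(attr(model, "train_ids"), fold$test_ids)))
            stop("test-set leakage: test subjects appear in training ids")
        }
        for (id in fold$test_ids) {
          s <- cohort$subjects[[id + 1L]]
          st <- s$fast[[lv]]
          if (is.null(model)) {
            vol <- s$fast_recon[[lv]]
          } else {
            den <- denoise(st, model,
                           defect_label = s$phantom$defect_label,
                           norm_scale = s$norm_scale)
            vol <- osem_reconstruct(den, cohort$fast_settings,
                                    attenuation = s$phantom$attenuation,
                                    voxel_cm = cohort$voxel_cm)
          }
          met <- evaluate_subject(s, vol)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = id, method = method, time_level = level,
            fold = fold$fold_id, metric = names(met), value = unname(met))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Scaled-down denoising trial (single fold)
#'
#' The package's core experiment at desk scale: split the cohort 35/5/10
#' (train/validation/test) by a seeded shuffle, train the attention-gated GAN
#' at the given time level, denoise and reconstruct the test stacks, and
#' compare them with the raw fast reconstructions against the filtered
#' full-time reference.
#'
#' @param cohort a [build_cohort()] with reconstructions.
#' @param seed trial seed controlling the split, initialization and training
#'   stochasticity.
#' @param level time level in s/view (default 1).
#' @param method denoiser to train (default `"attgan"`).
#' @param cfg a [train_config()]; its `rng_seed` is overridden by `seed`.
#' @param n_levels,base_filters,dropout_rate generator hyper-parameters
#'   (desk-scale defaults: 3 levels, 16 filters, dropout 0.1).
#' @return list with per-subject metric data frame `per_subject`, the means
#'   `mean_nmse_fast`, `mean_nmse_denoised`, `mean_pds_err_fast`,
#'   `mean_pds_err_denoised`, the trained model and its training history.
#' @export
run_denoising_trial <- function(cohort, seed, level = 1,
                                method = "attgan", cfg = train_config(),
                                n_levels = 3L, base_filters = 16L,
                                dropout_rate = 0.1) {
  stopifnot(inherits(cohort, "spect_cohort"))
  n <- length(cohort$subjects)
  ids <- vapply(cohort$subjects, `[[`, numeric(1), "id")
  n_test <- round(n * 0.2); n_val <- round(n * 0.1)
  ord <- with_seed(seed, sample(ids))
  test_ids <- ord[seq_len(n_test)]
  val_ids <- ord[n_test + seq_len(n_val)]
  train_ids <- ord[-seq_len(n_test + n_val)]
  cfg$rng_seed <- as.integer(seed)
  fit <- train_method(cohort, method, train_ids, val_ids, level, cfg,
                      n_levels, base_filters, dropout_rate)
  lv <- as.character(level)
  per <- lapply(test_ids, function(id) {
    s <- cohort$subjects[[id + 1L]]
    den <- denoise(s$fast[[lv]], fit$net,
                   defect_label = s$phantom$defect_label,
                   norm_scale = s$norm_scale)
    vol <- osem_reconstruct(den, cohort$fast_settings,
                            attenuation = s$phantom$attenuation,
                            voxel_cm = cohort$voxel_cm)
    mf <- evaluate_subject(s, s$fast_recon[[lv]])
    md <- evaluate_subject(s, vol)
    data.frame(subject = id,
               nmse_fast = mf[["nmse"]], nmse_denoised = md[["nmse"]],
               ssim_fast = mf[["ssim"]], ssim_denoised = md[["ssim"]],
               psnr_fast = mf[["psnr"]], psnr_denoised = md[["psnr"]],
               pds_err_fast = mf[["pds_abs_err"]],
               pds_err_denoised = md[["pds_abs_err"]],
               ir_err_fast = mf[["ir_abs_err"]],
               ir_err_denoised = md[["ir_abs_err"]])
  })
  per <- do.call(rbind, per)
  list(per_subject = per,
       mean_nmse_fast = mean(per$nmse_fast),
       mean_nmse_denoised = mean(per$nmse_denoised),
       mean_pds_err_fast = mean(per$pds_err_fast),
       mean_pds_err_denoised = mean(per$pds_err_denoised),
       model = fit$net, history = fit$history,
       split = list(train_ids = train_ids, val_ids = val_ids,
                    test_ids = test_ids))
}
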