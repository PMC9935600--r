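test_that("OS-EM error to ground truth decreases over iterations (noiseless)", {
  act <- disk_phantom(24L)
  ang <- 180 * (0:7) / 8
  st <- projection_stack(project_op(act, ang, NULL, 1), ang, 10)
  err <- vapply(1:5, function(it) {
    rec <- osem_reconstruct(st, recon_settings(n_iterations = it,
                                               attenuation_on = FALSE),
                            voxel_cm = 1)
    # scale-free comparison: OS-EM reconstructs up to the acquisition scale
    img <- rec$image * sum(act) / sum(rec$image)
    sum((img - act)^2) / sum(act^2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("OS-EM preserves non-negativity and maps zero data to zero", {
  act <- disk_phantom(16L)
  ang <- 180 * (0:3) / 4
  st <- projection_stack(project_op(act, ang, NULL, 1), ang, 10)
  rec <- osem_reconstruct(st, recon_settings(attenuation_on = FALSE))
  expect_true(all(rec$image >= 0))
  z <- projection_stack(array(0, dim(st$counts)), ang, 10)
  rz <- osem_reconstruct(z, recon_settings(attenuation_on = FALSE))
  expect_true(all(rz$image <= 1e-8))
})

test_that("scaling the measured counts scales the reconstruction", {
  act <- disk_phantom(16L)
  ang <- 180 * (0:3) / 4
  st <- projection_stack(project_op(act, ang, NULL, 1), ang, 10)
  r1 <- osem_reconstruct(st, recon_settings(attenuation_on = FALSE))
  st3 <- st
  st3$counts <- 3 * st3$counts
  r3 <- osem_reconstruct(st3, recon_settings(attenuation_on = FALSE))
  expect_equal(r3$image, 3 * r1$image, tolerance = 1e-8)
})

test_that("one subset reduces OS-EM to MLEM", {
  # independent MLEM oracle written directly from the EM update
  act <- disk_phantom(16L)
  ang <- 180 * (0:3) / 4
  counts <- project_op(act, ang, NULL, 1)
  st <- projection_stack(counts, ang, 10)
  rec <- osem_reconstruct(st, recon_settings(n_iterations = 2L,
                                             n_subsets = 1L,
                                             attenuation_on = FALSE))
  gd <- c(16L, 16L, 16L)
  x <- array(1, gd)
  sens <- backproject_op(array(1, dim(counts)), gd, ang, NULL, 1)
  for (it in 1:2) {
    fwd <- project_op(x, ang, NULL, 1)
    bp <- backproject_op(counts / (fwd + 1e-12), gd, ang, NULL, 1)
    x <- x * ifelse(sens > 0, bp / pmax(sens, 1e-12), 0)
  }
  expect_equal(rec$image, x, tolerance = 1e-10)
})

test_that("subset ordering only perturbs the reconstruction slightly", {
  act <- disk_phantom(16L)
  ang <- 180 * (0:7) / 8
  st <- projection_stack(project_op(act, ang, NULL, 1), ang, 10)
  r1 <- osem_reconstruct(st, recon_settings(attenuation_on = FALSE))
  # reversed view order permutes the subsets' processing order
  st2 <- projection_stack(st$counts[8:1, , ], ang[8:1], 10)
  r2 <- osem_reconstruct(st2, recon_settings(attenuation_on = FALSE))
  nmse_perm <- sum((r1$image - r2$image)^2) / sum(r1$image^2)
  expect_lt(nmse_perm, 0.02)
})

test_that("views must divide into the subsets", {
  st <- projection_stack(array(1, c(6, 8, 8)), 180 * (0:5) / 6, 10)
  expect_error(osem_reconstruct(st, recon_settings(n_subsets = 4L,
                                                   attenuation_on = FALSE)),
               "divisible")
})

test_that("Gaussian post-filter is an identity at sigma 0 and mass-preserving", {
  set.seed(4)
  v <- array(runif(16^3), c(16, 16, 16))
  expect_identical(gaussian_postfilter(v, 0), v)
  sm <- gaussian_postfilter(v, 0.6)
  expect_equal(sum(sm), sum(v), tolerance = 1e-3)
  u <- array(1, c(12, 12, 12))
  expect_equal(gaussian_postfilter(u, 0.6), u, tolerance = 1e-10)
  expect_error(gaussian_postfilter(v, -1), "sigma")
})

test_that("post-filter impulse response matches the analytic Gaussian", {
  n <- 15L
  v <- array(0, c(n, n, n))
  v[8, 8, 8] <- 1
  sm <- gaussian_postfilter(v, 0.6)
  g1 <- exp(-(seq_len(n) - 8)^2 / (2 * 0.6^2))
  g1 <- g1 / sum(g1)
  expected <- outer(outer(g1, g1), g1)
  dim(expected) <- c(n, n, n)
  expect_lt(max(abs(sm - expected)) / max(expected), 0.01)
})
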