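test_that("backprojector is the exact adjoint of the projector", {
  set.seed(1)
  d <- c(16L, 16L, 16L)
  ang <- 180 * (0:7) / 8
  x <- array(runif(prod(d)), d)
  y <- array(runif(8 * 16 * 16), c(8, 16, 16))
  for (mu in list(NULL, array(runif(prod(d)) * 0.15, d))) {
    Ax <- project_op(x, ang, mu, 0.6)
    Aty <- backproject_op(y, d, ang, mu, 0.6)
    lhs <- sum(Ax * y)
    rhs <- sum(x * Aty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("projection is linear in the activity", {
  set.seed(2)
  d <- c(16L, 16L, 16L)
  ang <- 180 * (0:5) / 6
  x <- array(runif(prod(d)), d)
  expect_true(all(project_op(array(0, d), ang, NULL, 1) == 0))
  p1 <- project_op(x, ang, NULL, 1)
  p2 <- project_op(2 * x, ang, NULL, 1)
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  # with attenuation fixed, doubling activity still doubles every bin
  mu <- array(0.1, d)
  expect_equal(project_op(2 * x, ang, mu, 1), 2 * project_op(x, ang, mu, 1),
               tolerance = 1e-12)
})

test_that("opposed views of a hot voxel agree up to the detector flip", {
  # brute-force oracle: for a parallel-beam view at 0 degrees the projection
  # is the straight sum along y; at 180 degrees the same sums appear with
  # the transaxial axis mirrored
  d <- c(16L, 16L, 16L)
  x <- array(0, d)
  x[5, 9, 8] <- 1
  p <- project_op(x, c(0, 180), NULL, 1)
  v0 <- p[1, , ]
  v180 <- p[2, , ]
  oracle0 <- apply(x, c(1, 3), sum) # sums along y
  expect_equal(v0, oracle0, tolerance = 1e-9)
  # mirror about the rotation centre (nx - 1)/2 -> index nx + 1 - i for the
  # centred grid used here
  expect_equal(v180, oracle0[rev(seq_len(16)), ], tolerance = 1e-9)
})

test_that("attenuation never increases any projection bin", {
  set.seed(3)
  d <- c(16L, 16L, 16L)
  ang <- 180 * (0:5) / 6
  x <- array(runif(prod(d)), d)
  mu <- array(runif(prod(d)) * 0.2, d)
  expect_true(all(project_op(x, ang, mu, 1) <=
                    project_op(x, ang, NULL, 1) + 1e-12))
})

test_that("forward_project calibrates the FT mean counts per view", {
  spec <- cohort_spec(n_subjects = 1L, grid_shape = c(32L, 32L, 32L),
                      voxel_size_cm = 1.2, rng_seed = 7L)
  ph <- make_phantom(spec, 0L)
  acq <- acquisition_spec(n_views = 8L, mean_counts_per_view_at_full_time = 2e4)
  st <- forward_project(ph, acq)
  expect_equal(sum(st$counts) / 8, 2e4, tolerance = 1e-9)
  expect_false(st$is_noisy)
  # explicit sensitivity keeps the operator linear
  s1 <- forward_project(ph, acq, sensitivity = 1)
  s2 <- forward_project(ph, acq, sensitivity = 2)
  expect_equal(s2$counts, 2 * s1$counts, tolerance = 1e-12)
})

test_that("Poisson noise has the right moments and determinism", {
  spec <- cohort_spec(n_subjects = 1L, grid_shape = c(32L, 32L, 32L),
                      voxel_size_cm = 1.2, rng_seed = 7L)
  st <- forward_project(make_phantom(spec, 0L), acquisition_spec(n_views = 8L))
  n1 <- add_poisson(st, 42L)
  n2 <- add_poisson(st, 42L)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts[st$counts == 0] == 0))
  expect_true(all(n1$counts == round(n1$counts)))
  expect_error(add_poisson(n1, 1L), "already noisy")
  # Monte-Carlo check of the mean at lambda = 100
  flat <- projection_stack(array(100, c(4, 50, 50)), c(0, 45, 90, 135), 10)
  draws <- add_poisson(flat, 5L)$counts
  m <- length(draws)
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / m))
})

test_that("binomial thinning reproduces a shorter acquisition", {
  spec <- cohort_spec(n_subjects = 1L, grid_shape = c(32L, 32L, 32L),
                      voxel_size_cm = 1.2, rng_seed = 7L)
  ft <- add_poisson(forward_project(make_phantom(spec, 0L),
                                    acquisition_spec(n_views = 8L)), 42L)
  expect_identical(thin_to_time(ft, 10, 1L), ft) # p = 1
  th <- thin_to_time(ft, 1, 9L)
  expect_equal(th$time_per_view_s, 1)
  expect_true(all(th$counts <= ft$counts))
  tot <- sum(ft$counts)
  expect_lt(abs(sum(th$counts) - 0.1 * tot), 3 * sqrt(tot * 0.1 * 0.9))
  expect_error(thin_to_time(ft, 11, 1L), "exceeds")
  cont <- ft
  cont$counts <- cont$counts + 0.5
  expect_error(thin_to_time(cont, 1, 1L), "integer")
})

test_that("thinning in two stages equals thinning once (composition)", {
  # 5 s then 1 s (p = 0.2 of 0.5) has the same marginal mean as 1 s directly
  lam <- array(50, c(4, 12, 12))
  base <- projection_stack(lam, c(0, 45, 90, 135), 10)
  reps <- 300L
  tot2 <- tot1 <- numeric(reps)
  for (r in seq_len(reps)) {
    noisy <- add_poisson(base, 1000L + r)
    tot2[r] <- sum(thin_to_time(thin_to_time(noisy, 5, 2000L + r),
                                1, 3000L + r)$counts)
    tot1[r] <- sum(thin_to_time(noisy, 1, 4000L + r)$counts)
  }
  se <- sqrt(var(tot2) / reps + var(tot1) / reps)
  expect_lt(abs(mean(tot2) - mean(tot1)), 3 * se)
})

test_that("projection stacks survive the NIfTI + JSON round trip", {
  st <- projection_stack(array(rpois(4 * 8 * 8, 20), c(4, 8, 8)),
                         c(0, 45, 90, 135), 10, is_noisy = TRUE)
  pre <- file.path(tempdir(), "stk")
  write_stack(st, pre)
  rt <- read_stack(pre)
  expect_equal(rt$counts, st$counts, ignore_attr = TRUE)
  expect_equal(rt$angles_deg, st$angles_deg)
  expect_true(rt$is_noisy)
})
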