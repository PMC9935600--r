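test_that("phantom generation is a pure function of (seed, subject)", {
  spec <- cohort_spec(n_subjects = 5L, grid_shape = c(32L, 32L, 32L),
                      voxel_size_cm = 1.2, rng_seed = 7L)
  for (i in c(0L, 3L)) {
    a <- make_phantom(spec, i)
    b <- make_phantom(spec, i)
    expect_identical(a$activity, b$activity)
    expect_identical(a$attenuation, b$attenuation)
    expect_identical(a$defect_mask, b$defect_mask)
  }
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); r1 <- runif(3)
  set.seed(99); invisible(make_phantom(spec, 0L)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("phantom volumes satisfy their physical invariants", {
  spec <- cohort_spec(n_subjects = 8L, grid_shape = c(32L, 32L, 32L),
                      voxel_size_cm = 1.2, rng_seed = 3L)
  for (i in seq_len(8L) - 1L) {
    p <- make_phantom(spec, i)
    expect_true(all(p$activity >= 0))
    expect_true(all(p$attenuation >= 0))
    expect_gt(sum(p$activity), 0)
    # defect confined to the myocardium; label consistent with the mask
    expect_true(all(p$wall_mask[p$defect_mask]))
    expect_identical(p$defect_label, as.integer(any(p$defect_mask)))
  }
})

test_that("defect_fraction = 0 forces normal subjects everywhere", {
  spec <- cohort_spec(n_subjects = 10L, defect_fraction = 0,
                      grid_shape = c(32L, 32L, 32L), rng_seed = 11L)
  labs <- vapply(0:9, function(i) make_phantom(spec, i)$defect_label,
                 integer(1))
  expect_true(all(labs == 0L))
})

test_that("full-severity defects have zero uptake inside the mask", {
  spec <- cohort_spec(n_subjects = 20L, defect_fraction = 1,
                      defect_severity_range = c(1, 1),
                      grid_shape = c(32L, 32L, 32L), rng_seed = 5L)
  p <- make_phantom(spec, 0L)
  expect_gt(sum(p$defect_mask), 0)
  expect_true(all(p$activity[p$defect_mask] == 0))
})

test_that("cohort defect prevalence matches defect_fraction within 3 SE", {
  n <- 250L
  spec <- cohort_spec(n_subjects = n, defect_fraction = 0.36,
                      grid_shape = c(32L, 32L, 32L), rng_seed = 21L)
  labs <- vapply(seq_len(n) - 1L, function(i) make_phantom(spec, i)$defect_label,
                 integer(1))
  se <- sqrt(0.36 * 0.64 / n)
  expect_lt(abs(mean(labs) - 0.36), 3 * se)
})

test_that("defect_extent is the defect share of the wall in percent", {
  spec <- cohort_spec(n_subjects = 2L, defect_fraction = 1,
                      grid_shape = c(32L, 32L, 32L), rng_seed = 2L)
  p <- make_phantom(spec, 0L)
  expect_equal(defect_extent(p),
               100 * sum(p$defect_mask) / sum(p$wall_mask))
  p0 <- p
  p0$defect_mask[] <- FALSE
  expect_equal(defect_extent(p0), 0)
  pf <- p
  pf$defect_mask <- pf$wall_mask
  expect_equal(defect_extent(pf), 100)
  pe <- p
  pe$wall_mask[] <- FALSE
  expect_error(defect_extent(pe), "empty")
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(grid_shape = c(8L, 8L, 8L)), "at least 16")
  expect_error(cohort_spec(defect_severity_range = c(0.5, 1.2)),
               "severity")
  expect_error(make_phantom(cohort_spec(n_subjects = 2L), 2L), "subject_index")
})

test_that("NIfTI + JSON round trip preserves the phantom", {
  spec <- cohort_spec(n_subjects = 1L, defect_fraction = 1,
                      grid_shape = c(32L, 32L, 32L), rng_seed = 4L)
  p <- make_phantom(spec, 0L)
  pre <- file.path(tempdir(), "ph0")
  write_phantom(p, pre)
  q <- read_phantom(pre)
  expect_equal(q$activity, p$activity, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(which(q$defect_mask), which(p$defect_mask))
  expect_identical(q$defect_label, p$defect_label)
  expect_equal(q$voxel_size_cm, p$voxel_size_cm)
})
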