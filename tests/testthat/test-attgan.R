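test_that("attention map is a softmax over voxels and gates multiplicatively", {
  set.seed(20)
  N <- 6 * 6 * 4
  x <- matrix(rnorm(N * 8), N, 8)
  d <- matrix(rnorm(N * 16), N, 16)
  prm <- attspect:::gate_init(8L, 16L)
  prm$w <- 0.7; prm$b <- -0.2
  g <- attention_gate(x, d, prm)
  expect_equal(sum(g$r), 1, tolerance = 1e-12)
  expect_true(all(g$r >= 0))
  expect_equal(dim(g$att), dim(x))
  # per-voxel multiplicative gating: att_i = N r_i x_i
  expect_equal(g$att, (N * g$r) * x, tolerance = 1e-10)
})

test_that("Wf = 0 collapses the gate to its documented closed forms", {
  set.seed(21)
  N <- 4 * 4 * 4
  x <- matrix(rnorm(N * 4), N, 4)
  d <- matrix(rnorm(N * 8), N, 8)
  prm <- attspect:::gate_init(4L, 8L)
  prm$Wf[] <- 0
  prm$w <- 1.3; prm$b <- 0.4
  g <- attention_gate(x, d, prm)
  expect_equal(g$r, rep(1 / N, N), tolerance = 1e-12)
  # production convention: uniform r makes the gate a plain skip
  expect_equal(g$att, x, tolerance = 1e-10)
  gd <- attention_gate_dense(x, d, prm)
  expect_true(all(abs(gd$r - 1 / N) < 1e-12))
  # dense oracle: uniform r broadcasts the spatial mean
  expect_equal(gd$att,
               matrix(colMeans(x), N, 4, byrow = TRUE), tolerance = 1e-10)
})

test_that("dense oracle columns are softmax-normalized for random weights", {
  set.seed(22)
  N <- 4 * 4 * 4
  x <- matrix(rnorm(N * 4), N, 4)
  d <- matrix(rnorm(N * 4), N, 4)
  prm <- attspect:::gate_init(4L, 4L)
  prm$w <- 0.9
  gd <- attention_gate_dense(x, d, prm)
  expect_equal(colSums(gd$r), rep(1, N), tolerance = 1e-10)
})

test_that("generator forward pass keeps the input shape and non-negativity", {
  set.seed(23)
  net <- build_generator(generator_spec(3L, 16L, dropout_rate = 0))
  arr <- array(abs(rnorm(16 * 16 * 8)), c(16, 16, 8))
  y <- generator_forward(net, arr)
  expect_equal(dim(y), dim(arr))
  expect_true(all(y >= 0))
  expect_error(generator_forward(net, array(1, c(15, 16, 8))), "pad by")
})

test_that("gate-disabled generator is parameter-identical to the plain U-Net", {
  set.seed(24)
  att_off <- build_generator(generator_spec(3L, 16L, attention_enabled = FALSE))
  set.seed(24)
  unet <- build_generator(generator_spec(3L, 16L, attention_enabled = FALSE))
  expect_identical(att_off$params, unet$params)
  expect_null(att_off$params$gates)
  # with gates enabled the only extra parameters are the gates themselves
  set.seed(24)
  att_on <- build_generator(generator_spec(3L, 16L, attention_enabled = TRUE))
  # encoder draws precede any gate, so those weights coincide; the full
  # parameter sets differ only by the gate leaves (same shapes elsewhere)
  expect_identical(att_on$params$enc, att_off$params$enc)
  expect_identical(rapply(att_on$params[c("dec", "final")], dim, how = "list"),
                   rapply(att_off$params[c("dec", "final")], dim, how = "list"))
  expect_length(att_on$params$gates, 2L)
})

test_that("doubling base_filters roughly quadruples the conv parameters", {
  count_conv <- function(f) {
    net <- build_generator(generator_spec(3L, f))
    sum(vapply(net$params$enc, function(b) length(b$conv$W), numeric(1)))
  }
  r <- count_conv(16L) / count_conv(8L)
  expect_gt(r, 3.4) # below 4 only through the fixed 1-channel input layer
  expect_lt(r, 4.01)
})

test_that("discriminator logits are deterministic, finite scalars per sample", {
  set.seed(25)
  dn <- build_discriminator(base_filters = 8L, n_levels = 3L)
  dims <- c(16L, 16L, 8L)
  x <- matrix(abs(rnorm(2 * prod(dims) * 2)), ncol = 2)
  f1 <- attspect:::disc_forward(dn, x, dims, B = 2L, training = FALSE)
  f2 <- attspect:::disc_forward(dn, x, dims, B = 2L, training = FALSE)
  expect_identical(f1$logit, f2$logit)
  expect_length(f1$logit, 2L)
  expect_true(all(is.finite(f1$logit)))
})

test_that("pure-L1 training excludes the adversarial path entirely", {
  co <- toy_cohort()
  pairs <- attspect:::make_pairs(co, 0:3, 1)
  cfg <- train_config(epochs = 2L, adversarial_weight = 0, rng_seed = 1L)
  fit <- train_denoiser(pairs, cfg, generator_spec(2L, 8L, 0))
  expect_true(all(is.na(fit$history$l_d)))
  expect_true(all(fit$history$l_adv == 0))
})

test_that("a short adversarial run learns: L1 falls, D separates real from fake", {
  co <- toy_cohort()
  ids <- 0:9
  pairs <- attspect:::make_pairs(co, ids, 1)
  cfg <- train_config(epochs = 8L, rng_seed = 2L)
  fit <- train_denoiser(pairs[1:8], cfg, generator_spec(3L, 16L, 0.1),
                        val_pairs = pairs[9:10])
  expect_lt(tail(fit$history$l1, 1), fit$history$l1[1])
  # discriminator cross-entropy below ln(4) means real/fake are separated
  expect_lt(tail(fit$history$l_d, 1), 2 * log(2))
})

test_that("denoise wires normalization, the generator and de-normalization", {
  co <- toy_cohort()
  s <- co$subjects[[2]]
  set.seed(26)
  net <- build_generator(generator_spec(2L, 8L, dropout_rate = 0))
  attr(net, "full_time_s") <- 10
  den <- denoise(s$fast[["1"]], net, norm_scale = s$norm_scale)
  expect_s3_class(den, "projection_stack")
  expect_true(all(den$counts >= 0))
  expect_equal(dim(den$counts), dim(s$fast[["1"]]$counts))
  # equals the manual normalize -> forward -> denormalize chain
  nz <- normalize_stack(s$fast[["1"]], scale = s$norm_scale)
  manual <- denormalize_stack(
    pmax(attspect:::from_net_layout(
      generator_forward(net, attspect:::to_net_layout(nz$data))), 0),
    nz$scale)
  expect_equal(den$counts, manual, tolerance = 1e-12)
  # time-level mismatch between model and stack is flagged
  attr(net, "time_level_s") <- 2
  expect_warning(denoise(s$fast[["1"]], net, norm_scale = s$norm_scale),
                 "dose-specific")
})

test_that("defect-conditioned training embeds and strips the label block", {
  co <- toy_cohort()
  pairs <- attspect:::make_pairs(co, 0:2, 1)
  cfg <- train_config(epochs = 1L, rng_seed = 3L)
  fit <- train_denoiser(pairs, cfg, generator_spec(2L, 8L, 0),
                        defect_conditioned = TRUE)
  expect_true(fit$net$defect_conditioned)
  s <- co$subjects[[1]]
  den <- denoise(s$fast[["1"]], fit$net,
                 defect_label = s$phantom$defect_label,
                 norm_scale = s$norm_scale, full_time_s = 10)
  expect_equal(dim(den$counts), dim(s$fast[["1"]]$counts))
  expect_error(denoise(s$fast[["1"]], fit$net, norm_scale = s$norm_scale,
                       full_time_s = 10),
               "defect_label")
})
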