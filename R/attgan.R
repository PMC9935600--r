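#' Generator architecture specification
#'
#' A 3D U-Net generator: per encoding level one block of
#' convolution (3x3x3) - batch normalization - ReLU - dropout(rate), with
#' 2x2x2 max-pooling between levels; the deepest block acts as the
#' bottleneck. The decoder mirrors the encoder with nearest-neighbour
#' up-sampling, one (optionally attention-gated) skip connection per level,
#' channel concatenation and the same conv blocks. A final 3x3x3 convolution
#' with ReLU maps to one non-negative output channel.
#'
#' @param n_levels number of encoding levels (2-5).
#' @param base_filters filters in the first level (8, 16, 24, 32 or 40);
#'   deeper levels double the count.
#' @param dropout_rate dropout rate inside each block (default 0.5).
#' @param attention_enabled logical; gate the skip connections with attention
#'   (`FALSE` gives the plain U-Net / cGAN generator).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_levels = 3L, base_filters = 32L,
                           dropout_rate = 0.5, attention_enabled = TRUE) {
  if (!n_levels %in% 2:5) stop("n_levels must be in 2..5")
  if (!base_filters %in% c(8L, 16L, 24L, 32L, 40L))
    stop("base_filters must be one of 8, 16, 24, 32, 40")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(n_levels = as.integer(n_levels),
                 base_filters = as.integer(base_filters),
                 dropout_rate = dropout_rate,
                 attention_enabled = isTRUE(attention_enabled)),
            class = "generator_spec")
}

gate_init <- function(c_enc, c_dec) {
  k <- max(1L, c_enc %/% 2L)
  # psi weight/bias start at zero: the gate opens as an identity skip
  list(Wg = matrix(rnorm(c_enc * k, sd = sqrt(1 / c_enc)), c_enc, k),
       Wf = matrix(rnorm(c_dec * k, sd = sqrt(1 / c_dec)), c_dec, k),
       w = 0, b = 0)
}

#' Build the U-Net generator
#'
#' @param spec a [generator_spec()].
#' @param in_channels number of input channels (1 for projection stacks).
#' @return an object of class `generator_net` holding the parameter arrays.
#' @export
build_generator <- function(spec, in_channels = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  L <- spec$n_levels
  f <- spec$base_filters
  ch <- f * 2^(seq_len(L) - 1)
  params <- list(enc = vector("list", L))
  c_in <- in_channels
  for (i in seq_len(L)) {
    params$enc[[i]] <- convblock_init(c_in, ch[i])
    c_in <- ch[i]
  }
  params$dec <- vector("list", L - 1)
  if (spec$attention_enabled) params$gates <- vector("list", L - 1)
  for (i in seq_len(L - 1)) {
    c_skip <- ch[i]
    c_up <- ch[i + 1]
    params$dec[[i]] <- convblock_init(c_skip + c_up, c_skip)
    if (spec$attention_enabled) params$gates[[i]] <- gate_init(c_skip, c_up)
  }
  params$final <- conv_init(ch[1], 1L, 3L)
  # start the ReLU output layer in its active region: a zero or negative
  # pre-activation everywhere would have zero gradient and the L1 loss could
  # never revive it (dead-ReLU collapse)
  params$final$b[] <- 0.1
  structure(list(spec = spec, in_channels = as.integer(in_channels),
                 params = params),
            class = "generator_net")
}

#' @export
print.generator_net <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<generator_net> %d levels, %d base filters, attention %s, %d parameters\n",
              x$spec$n_levels, x$spec$base_filters,
              if (x$spec$attention_enabled) "on" else "off", np))
  invisible(x)
}

#' Attention gate on a skip connection
#'
#' The memory-linear gating convention used throughout this package: with
#' encoder features `x` and the (up-sampled) decoder features `d` at the same
#' spatial size, `g_i = Wg' x_i` and `f_i = Wf' d_i` are 1x1x1 projections,
#' the per-voxel inner product `alpha_i = <f_i, g_i>` passes through ReLU, a
#' 1x1x1 convolution (`w`, `b`) and a softmax over the spatial axis to give
#' the attention map `r` (which sums to one), and the gated output is
#' `Att_i = N * r_i * x_i`. With `Wf = 0` the map is uniform (`r_i = 1/N`)
#' and the gate reduces exactly to the plain skip `Att = x`.
#'
#' [attention_gate_dense()] is the brute-force dense counterpart
#' (`alpha_ij = f(d_i)' g(x_j)`, softmax over the contributing voxels, output
#' `Att_j = sum_i x_i r_ij`), quadratic in the voxel count and intended only
#' as a small-scale oracle; its `Wf = 0` closed form is the spatial mean of
#' `x` broadcast to every voxel. Both forms share the uniform attention map
#' in that degenerate case.
#'
#' @param enc_features matrix `[N x C_enc]`.
#' @param dec_features matrix `[N x C_dec]`, same spatial size.
#' @param params gate parameters: `Wg`, `Wf`, `w`, `b`.
#' @return list with `att` (gated features, shape of `enc_features`) and `r`
#'   (the attention map, summing to one).
#' @export
attention_gate <- function(enc_features, dec_features, params) {
  x <- as.matrix(enc_features)
  d <- as.matrix(dec_features)
  if (nrow(x) != nrow(d))
    stop("encoder/decoder feature maps must share their spatial size after resampling")
  r <- tz_gate_fwd(tz_new(x, TRUE), tz_new(d, TRUE), params$Wg, params$Wf,
                   params$w, params$b, 1L, TRUE)
  list(att = tz_get(r$att, TRUE), r = as.numeric(tz_get(r$r, TRUE)))
}

#' @rdname attention_gate
#' @export
attention_gate_dense <- function(enc_features, dec_features, params) {
  x <- as.matrix(enc_features)
  d <- as.matrix(dec_features)
  N <- nrow(x)
  if (N != nrow(d)) stop("feature maps must share their spatial size")
  if (N > 1024) stop("dense attention oracle is restricted to small maps")
  g <- x %*% params$Wg
  f <- d %*% params$Wf
  alpha <- f %*% t(g) # alpha[i, j] = <f_i, g_j>
  s <- params$w * pmax(alpha, 0) + params$b
  r <- apply(s, 2, function(col) { # softmax over contributing voxels i
    e <- exp(col - max(col))
    e / sum(e)
  })
  att <- t(r) %*% x # Att_j = sum_i r_ij x_i
  list(att = att, r = r)
}

check_divisible <- function(dims, L) {
  need <- 2^(L - 1)
  if (any(dims %% need != 0)) {
    pad <- (need - dims %% need) %% need
    stop(sprintf(
      "input dims (%s) must be divisible by %d for %d levels; pad by (%s)",
      paste(dims, collapse = ","), need, L, paste(pad, collapse = ",")))
  }
}

# full generator forward on a minibatch (xmat: [B*N x 1] double matrix);
# returns the prediction handle, caches for backprop, and the net with
# updated BN running statistics
gen_forward_full <- function(net, xmat, dims, B = 1L, training = FALSE,
                             dbl = FALSE) {
  spec <- net$spec
  L <- spec$n_levels
  check_divisible(dims, L)
  p <- net$params
  dr <- spec$dropout_rate
  cur <- tz_new(xmat, dbl)
  curdims <- as.integer(dims)
  enc_c <- vector("list", L); pool_c <- vector("list", L)
  skips <- vector("list", L)
  for (i in seq_len(L)) {
    cb <- convblock_fwd(p$enc[[i]], cur, curdims, B, dr, training, dbl)
    p$enc[[i]]$bn <- cb$p_bn
    enc_c[[i]] <- cb$cache
    cur <- cb$y
    if (i < L) {
      skips[[i]] <- cur
      mp <- tz_maxpool_fwd(cur, curdims, B, dbl)
      pool_c[[i]] <- list(idx = mp$idx, n = B * prod(curdims))
      cur <- mp$y; curdims <- mp$outdims
    }
  }
  gate_c <- vector("list", L); dec_c <- vector("list", L)
  up_dims <- vector("list", L)
  for (i in rev(seq_len(L - 1))) {
    up <- tz_upsample_fwd(cur, curdims, B, dbl)
    up_dims[[i]] <- curdims
    updims <- curdims * 2L
    if (spec$attention_enabled) {
      gp <- p$gates[[i]]
      gt <- tz_gate_fwd(skips[[i]], up, gp$Wg, gp$Wf, gp$w, gp$b, B, dbl)
      gate_c[[i]] <- c(gt, list(x = skips[[i]], d = up))
      att <- gt$att
    } else att <- skips[[i]]
    cat_x <- tz_concat(att, up, dbl)
    db <- convblock_fwd(p$dec[[i]], cat_x, updims, B, dr, training, dbl)
    p$dec[[i]]$bn <- db$p_bn
    dec_c[[i]] <- list(cache = db$cache,
                       c_skip = spec$base_filters * 2^(i - 1))
    cur <- db$y; curdims <- updims
  }
  fc <- conv_fwd(p$final, cur, curdims, B, 3L, 1L, 1L, dbl)
  rl <- relu_fwd(fc$y, dbl)
  net$params <- p
  list(y = rl$y, dims = curdims, net = net, B = B, dbl = dbl,
       caches = list(enc = enc_c, pool = pool_c, gates = gate_c,
                     dec = dec_c, up_dims = up_dims,
                     final = fc$cache, final_relu = rl$cache))
}

# dymat: [B*N x 1] double matrix of output gradients
gen_backward <- function(net, dymat, caches, B = 1L, dbl = FALSE) {
  spec <- net$spec
  L <- spec$n_levels
  p <- net$params
  genc <- vector("list", L)
  gdec <- vector("list", L - 1)
  ggates <- if (spec$attention_enabled) vector("list", L - 1)
  hdy <- relu_bwd(tz_new(dymat, dbl), caches$final_relu, dbl)
  fb <- conv_bwd(p$final, hdy, caches$final, dbl)
  dcur <- fb$dx
  dskip <- vector("list", L)
  for (i in seq_len(L - 1)) {
    db <- convblock_bwd(p$dec[[i]], dcur, caches$dec[[i]]$cache, dbl)
    gdec[[i]] <- db$grads
    sp <- tz_split(db$dx, caches$dec[[i]]$c_skip, dbl)
    datt <- sp$a
    dup <- sp$b
    if (spec$attention_enabled) {
      gp <- p$gates[[i]]
      gc <- caches$gates[[i]]
      gb <- tz_gate_bwd(datt, gc$x, gc$d, gc$g, gc$f, gc$alpha, gc$r,
                        gp$Wg, gp$Wf, gp$w, B, dbl)
      ggates[[i]] <- list(Wg = gb$dWg, Wf = gb$dWf, w = gb$dw, b = gb$db)
      dskip[[i]] <- gb$dx
      dup <- tz_add(dup, gb$dd, dbl)
    } else dskip[[i]] <- datt
    dcur <- tz_upsample_bwd(dup, as.integer(caches$up_dims[[i]]), B, dbl)
  }
  for (i in rev(seq_len(L))) {
    if (i < L) {
      dcur <- tz_maxpool_bwd(dcur, caches$pool[[i]]$idx,
                             caches$pool[[i]]$n, dbl)
      dcur <- tz_add(dcur, dskip[[i]], dbl)
    }
    eb <- convblock_bwd(p$enc[[i]], dcur, caches$enc[[i]], dbl,
                        need_dx = (i > 1L))
    genc[[i]] <- eb$grads
    dcur <- eb$dx
  }
  # grads in the same structural order as build_generator()'s params
  g <- list(enc = genc, dec = gdec)
  if (spec$attention_enabled) g$gates <- ggates
  g$final <- fb$grads
  list(grads = g)
}

#' Run the generator on a projection-stack array
#'
#' Low-level forward pass (no normalization); see [denoise()] for the full
#' inference path.
#'
#' @param net a `generator_net`.
#' @param arr 3D input array.
#' @param training logical; enables batch-statistics BN and dropout.
#' @return 3D array of the same shape.
#' @export
generator_forward <- function(net, arr, training = FALSE) {
  arr <- as.array(arr)
  out <- gen_forward_full(net, matrix(as.numeric(arr), ncol = 1L), dim(arr),
                          B = 1L, training = training)
  array(tz_get(out$y, FALSE), dim(arr))
}

#' Build the conditional discriminator
#'
#' A PatchGAN-style CNN on the channel-concatenated (condition, candidate)
#' pair: `n_levels` strided 3x3x3 convolutions (stride 2) with filters
#' doubling from `base_filters`, LeakyReLU(0.2), batch normalization from the
#' second level, then a 1x1x1 convolution to one channel whose spatial mean
#' is the real/fake logit.
#'
#' @param in_channels channels of the pair (2: condition + candidate).
#' @param base_filters filters in the first level (default 32).
#' @param n_levels number of strided levels (default 4).
#' @return an object of class `discriminator_net`.
#' @export
build_discriminator <- function(in_channels = 2L, base_filters = 32L,
                                n_levels = 4L) {
  ch <- base_filters * 2^(seq_len(n_levels) - 1)
  params <- list(levels = vector("list", n_levels))
  c_in <- in_channels
  for (i in seq_len(n_levels)) {
    params$levels[[i]] <- list(conv = conv_init(c_in, ch[i], 3L))
    if (i >= 2) params$levels[[i]]$bn <- bn_init(ch[i])
    c_in <- ch[i]
  }
  params$final <- conv_init(c_in, 1L, 1L)
  structure(list(n_levels = as.integer(n_levels),
                 in_channels = as.integer(in_channels),
                 base_filters = as.integer(base_filters), params = params),
            class = "discriminator_net")
}

# xmat: [B*N x C] double matrix; returns one logit per sample
disc_forward <- function(net, xmat, dims, B = 1L, training = FALSE,
                         dbl = FALSE) {
  p <- net$params
  cur <- tz_new(xmat, dbl)
  curdims <- as.integer(dims)
  lev_c <- vector("list", net$n_levels)
  for (i in seq_len(net$n_levels)) {
    cv <- conv_fwd(p$levels[[i]]$conv, cur, curdims, B, 3L, 2L, 1L, dbl)
    cache <- list(conv = cv$cache)
    y <- cv$y
    if (!is.null(p$levels[[i]]$bn)) {
      bn <- bn_fwd(p$levels[[i]]$bn, y, training, dbl)
      p$levels[[i]]$bn <- bn$p
      cache$bn <- bn$cache
      y <- bn$y
    }
    lr <- lrelu_fwd(y, 0.2, dbl)
    cache$lrelu <- lr$cache
    lev_c[[i]] <- cache
    cur <- lr$y; curdims <- cv$outdims
  }
  fc <- conv_fwd(p$final, cur, curdims, B, 1L, 1L, 0L, dbl)
  logit <- tz_sample_means(fc$y, B, dbl)
  net$params <- p
  list(logit = logit, net = net,
       caches = list(levels = lev_c, final = fc$cache,
                     n_out = prod(fc$outdims), B = B))
}

disc_backward <- function(net, dlogit, caches, dbl = FALSE,
                          need_dx = FALSE) {
  p <- net$params
  glev <- vector("list", net$n_levels)
  dy <- matrix(rep(dlogit / caches$n_out, each = caches$n_out), ncol = 1)
  fb <- conv_bwd(p$final, tz_new(dy, dbl), caches$final, dbl)
  dcur <- fb$dx
  for (i in rev(seq_len(net$n_levels))) {
    cache <- caches$levels[[i]]
    dcur <- lrelu_bwd(dcur, cache$lrelu, 0.2, dbl)
    gi <- list(conv = NULL)
    if (!is.null(cache$bn)) {
      bb <- bn_bwd(p$levels[[i]]$bn, dcur, cache$bn, dbl)
      gi$bn <- bb$grads
      dcur <- bb$dx
    }
    cb <- conv_bwd(p$levels[[i]]$conv, dcur, cache$conv, dbl,
                   need_dx = (i > 1L || need_dx))
    gi$conv <- cb$grads
    glev[[i]] <- gi
    dcur <- cb$dx
  }
  list(dx = dcur, grads = list(levels = glev, final = fb$grads))
}

sigmoid <- function(z) 1 / (1 + exp(-z))
softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))

#' Training configuration
#'
#' Defaults follow the training protocol of the underlying study (Adam,
#' initial learning rate 1e-4, adversarial weight 1 with lambda = 100 on the
#' L1 term); the epoch count is left to the caller (400 at full scale, 50 in
#' the desk-scale experiments shipped with the package).
#'
#' @param epochs number of passes over the training pairs.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size samples per parameter update (default 3; gradients are
#'   summed over the minibatch and the discriminator sees the fake and real
#'   pairs of a minibatch jointly).
#' @param lambda_l1 weight of the L1 term in the generator objective
#'   (default 100).
#' @param adversarial_weight weight of the adversarial term (default 1;
#'   0 trains a pure-L1 U-Net and skips the discriminator entirely).
#' @param rng_seed seed controlling initialization, shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 1e-4, batch_size = 3L,
                         lambda_l1 = 100, adversarial_weight = 1,
                         rng_seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), lambda_l1 = lambda_l1,
                 adversarial_weight = adversarial_weight,
                 rng_seed = as.integer(rng_seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# The network-internal tensor layout puts the view axis last,
# (nx, nz, V), so that the innermost kernel loops run along the detector
# bins; user-facing stacks are (V, nx, nz).
to_net_layout <- function(arr) aperm(as.array(arr), c(2, 3, 1))
from_net_layout <- function(arr) aperm(as.array(arr), c(3, 1, 2))

# strip/expand the defect-block slices (last along the view axis = axis 3
# in network layout) of a batched column vector
strip_block_b <- function(vec, xdims, tdims, B) {
  if (identical(xdims, tdims)) return(as.numeric(vec))
  a <- array(vec, c(xdims, B))
  as.numeric(a[, , seq_len(tdims[3]), , drop = FALSE])
}
expand_block_b <- function(dvec, xdims, tdims, B) {
  if (identical(xdims, tdims)) return(matrix(dvec, ncol = 1L))
  a <- array(0, c(xdims, B))
  a[, , seq_len(tdims[3]), ] <- array(dvec, c(tdims, B))
  matrix(as.numeric(a), ncol = 1L)
}

#' Train the denoising generator (AttGAN / cGAN / U-Net)
#'
#' Alternating generator/discriminator updates with Adam. The generator
#' minimizes `adversarial_weight * L_ADV + lambda_l1 * L1` against the
#' full-time target; the discriminator minimizes cross-entropy on real
#' (fast, FT) versus fake (fast, generated) pairs. With
#' `adversarial_weight = 0` this is plain L1 U-Net training (no adversarial
#' gradient reaches the generator and no discriminator is built); with
#' `spec$attention_enabled = FALSE` the generator is the cGAN/U-Net
#' architecture. When the model is defect-conditioned, the binary defect
#' block is embedded into the input and the label slices are stripped from
#' the output before any loss is computed.
#'
#' @param pairs list of training samples from [make_training_sample()].
#' @param cfg a [train_config()].
#' @param spec a [generator_spec()].
#' @param val_pairs optional validation samples; the returned model is the
#'   one with the best validation L1.
#' @param defect_conditioned logical; embed the binary defect block.
#' @return list with `net` (trained `generator_net`) and `history`
#'   (per-epoch data frame of `l1`, `l_adv`, `l_d`, `l1_val`).
#' @export
train_denoiser <- function(pairs, cfg = train_config(),
                           spec = generator_spec(),
                           val_pairs = NULL, defect_conditioned = FALSE) {
  stopifnot(length(pairs) >= 1L, inherits(cfg, "train_config"),
            inherits(spec, "generator_spec"))
  use_adv <- cfg$adversarial_weight > 0
  with_seed(cfg$rng_seed, {
    prep <- function(s) {
      x <- s$input
      if (defect_conditioned) x <- embed_defect_block(x, s$defect_label)
      x <- to_net_layout(x)
      tgt <- to_net_layout(s$target)
      list(x = as.numeric(x), xdims = dim(x),
           t = as.numeric(tgt), tdims = dim(tgt))
    }
    tr <- lapply(pairs, prep)
    va <- lapply(val_pairs %||% list(), prep)
    xdims <- tr[[1]]$xdims; tdims <- tr[[1]]$tdims
    if (!all(vapply(tr, function(s) identical(s$xdims, xdims), logical(1))))
      stop("all training stacks must share their shape")
    nvox_t <- prod(tdims)

    gnet <- build_generator(spec, in_channels = 1L)
    gstate <- list(m = adam_init_like(gnet$params),
                   v = adam_init_like(gnet$params))
    if (use_adv) {
      dnet <- build_discriminator(in_channels = 2L)
      dstate <- list(m = adam_init_like(dnet$params),
                     v = adam_init_like(dnet$params))
    }

    n <- length(tr)
    gt <- 0L; dt <- 0L; gt_gc <- 0L
    hist_rows <- vector("list", cfg$epochs)
    best_val <- Inf
    best_net <- NULL
    if (length(va)) {
      va_x <- matrix(unlist(lapply(va, `[[`, "x")), ncol = 1L)
      va_t <- unlist(lapply(va, `[[`, "t"))
    }
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      ep_l1 <- ep_adv <- ep_ld <- 0
      for (bt in batches) {
        B <- length(bt)
        xb <- matrix(unlist(lapply(tr[bt], `[[`, "x")), ncol = 1L)
        tb <- unlist(lapply(tr[bt], `[[`, "t"))
        fw <- gen_forward_full(gnet, xb, xdims, B, training = TRUE)
        gnet <- fw$net
        yhat <- strip_block_b(tz_get(fw$y, FALSE), xdims, tdims, B)
        resid <- yhat - tb
        l1 <- mean(abs(resid))
        if (!is.finite(l1)) stop(sprintf("NaN loss at epoch %d", ep))
        dy_s <- sign(resid) * (cfg$lambda_l1 / nvox_t)
        if (use_adv) {
          cond <- strip_block_b(xb, xdims, tdims, B)
          fake_in <- cbind(cond, yhat)
          df_f <- disc_forward(dnet, fake_in, tdims, B, training = TRUE)
          zf <- df_f$logit
          # generator's non-saturating gradient through the discriminator
          db_g <- disc_backward(df_f$net,
                                -sigmoid(-zf) * cfg$adversarial_weight,
                                df_f$caches, need_dx = TRUE)
          dy_s <- dy_s + as.numeric(tz_get(tz_split(db_g$dx, 1L, FALSE)$b,
                                           FALSE))
          ep_adv <- ep_adv + sum(softplus(-zf))
        }
        dy <- expand_block_b(dy_s, xdims, tdims, B)
        gb <- gen_backward(gnet, dy, fw$caches, B)
        gt <- gt + 1L
        up <- adam_step(gnet$params, gb$grads, gstate, cfg$learning_rate, gt)
        gnet$params <- up$p; gstate$m <- up$m; gstate$v <- up$v
        if (use_adv) {
          # discriminator step: one pass over the stacked (fake, real) batch
          both <- rbind(cbind(cond, yhat), cbind(cond, tb))
          df_b <- disc_forward(dnet, both, tdims, 2L * B, training = TRUE)
          dnet <- df_b$net
          zf2 <- df_b$logit[seq_len(B)]
          zr <- df_b$logit[B + seq_len(B)]
          db_b <- disc_backward(dnet, c(sigmoid(zf2), -sigmoid(-zr)),
                                df_b$caches)
          dt <- dt + 1L
          upd <- adam_step(dnet$params, db_b$grads, dstate,
                           cfg$learning_rate, dt)
          dnet$params <- upd$p; dstate$m <- upd$m; dstate$v <- upd$v
          ep_ld <- ep_ld + sum(softplus(-zr) + softplus(zf2))
        }
        ep_l1 <- ep_l1 + l1 * B
        # release the layer caches' native buffers periodically so their
        # pages are recycled warm instead of faulted in anew
        gt_gc <- gt_gc + 1L
        if (gt_gc >= 4L) { rm(fw, gb); gc(FALSE); gt_gc <- 0L }
      }
      l1v <- NA_real_
      if (length(va)) {
        fw <- gen_forward_full(gnet, va_x, xdims, length(va),
                               training = FALSE)
        l1v <- mean(abs(strip_block_b(tz_get(fw$y, FALSE), xdims, tdims,
                                      length(va)) - va_t))
        if (l1v < best_val) { best_val <- l1v; best_net <- gnet }
      }
      hist_rows[[ep]] <- data.frame(
        epoch = ep, l1 = ep_l1 / n, l_adv = ep_adv / n,
        l_d = if (use_adv) ep_ld / n else NA_real_, l1_val = l1v)
      if (cfg$verbose)
        message(sprintf("epoch %3d  L1 %.5f  Ladv %.4f  LD %.4f  val %.5f",
                        ep, ep_l1 / n, ep_adv / n,
                        if (use_adv) ep_ld / n else NA, l1v))
    }
    net <- best_net %||% gnet
    net$defect_conditioned <- defect_conditioned
    list(net = net, history = do.call(rbind, hist_rows))
  })
}

# elementwise sum of two structurally identical gradient lists
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) mapply(grads_add, a, b, SIMPLIFY = FALSE)
  else a + b
}

#' Denoise a fast projection stack with a trained generator
#'
#' Normalizes the stack to the model's 0-1 training scale, embeds the binary
#' defect block if the model is defect-conditioned, runs the generator in
#' evaluation mode, strips the block and de-normalizes back to the count
#' scale. The output is non-negative by construction (ReLU output layer).
#'
#' With `norm_scale = NULL` the full-time maximum is estimated from the fast
#' stack as `max(counts) / (time_per_view / full_time)`; pass the subject's
#' true FT normalization scale when it is available (as in the
#' cross-validation harness) to match the training statistics exactly.
#'
#' @param stack a fast `projection_stack`.
#' @param model a trained `generator_net` (from [train_denoiser()]).
#' @param defect_label binary label; required for defect-conditioned models.
#' @param norm_scale normalization scale, or `NULL` to estimate it.
#' @param full_time_s full acquisition time per view used in training
#'   (default from the model's `full_time_s` attribute or 10 s).
#' @return a denoised `projection_stack` (continuous-valued).
#' @export
denoise <- function(stack, model, defect_label = NULL, norm_scale = NULL,
                    full_time_s = NULL) {
  stopifnot(inherits(stack, "projection_stack"),
            inherits(model, "generator_net"))
  ft_s <- full_time_s %||% attr(model, "full_time_s") %||% 10
  tl <- attr(model, "time_level_s")
  if (!is.null(tl) && abs(tl - stack$time_per_view_s) > 1e-9)
    warning(sprintf(
      "model was trained at %.3g s/view but the stack is %.3g s/view (dose-specific training)",
      tl, stack$time_per_view_s))
  p <- stack$time_per_view_s / ft_s
  if (is.null(norm_scale)) norm_scale <- max(stack$counts) / p
  nz <- normalize_stack(stack, scale = norm_scale)
  x <- nz$data
  if (isTRUE(model$defect_conditioned)) {
    if (is.null(defect_label))
      stop("defect-conditioned model requires a defect_label")
    x <- embed_defect_block(x, defect_label)
  }
  y <- from_net_layout(generator_forward(model, to_net_layout(x),
                                         training = FALSE))
  if (isTRUE(model$defect_conditioned)) y <- strip_defect_block(y)
  out <- stack
  out$counts <- denormalize_stack(pmax(y, 0), nz$scale)
  out$is_noisy <- FALSE
  out
}
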