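# Internal neural-network layer primitives.
#
# Feature maps live on the C++ side as tensor handles (external pointers to
# single-precision matrices [B*N x C]: B samples of N voxels of a (d1,d2,d3)
# grid in column-major order, sample-major rows, C channels). R holds the
# (double) parameter arrays, the layer caches and the optimizer state, and
# converts to/from handles only at the network boundary. Every layer has a
# fwd() returning (out, cache) and a bwd() consuming the cache. `dbl = TRUE`
# runs every kernel in double precision (finite-difference gradient checks).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

conv_init <- function(c_in, c_out, k = 3L) {
  fan_in <- k^3 * c_in
  list(W = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = numeric(c_out))
}

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

conv_fwd <- function(p, hx, dims, B = 1L, k = 3L, s = 1L, pad = 1L,
                     dbl = FALSE) {
  hy <- tz_conv_fwd(hx, as.integer(dims), B, p$W, p$b, k, s, pad, dbl)
  o <- (dims + 2L * pad - k) %/% s + 1L
  list(y = hy, outdims = o,
       cache = list(x = hx, dims = as.integer(dims), B = B, k = k, s = s,
                    pad = pad))
}

conv_bwd <- function(p, hdy, cache, dbl = FALSE, need_dx = TRUE) {
  r <- tz_conv_bwd(cache$x, cache$dims, cache$B, p$W, hdy,
                   cache$k, cache$s, cache$pad, need_dx, dbl)
  list(dx = r$dx, grads = list(W = r$dW, b = r$db))
}

# batch normalization over all voxels of the minibatch, per channel
bn_fwd <- function(p, hx, training, dbl = FALSE) {
  r <- tz_bn_fwd(hx, p$gamma, p$beta, p$run_mean, p$run_var,
                 training, BN_MOMENTUM, BN_EPS, dbl)
  p$run_mean <- r$run_mean
  p$run_var <- r$run_var
  list(y = r$y, p = p, cache = list(xhat = r$xhat, istd = r$istd))
}

bn_bwd <- function(p, hdy, cache, dbl = FALSE) {
  r <- tz_bn_bwd(hdy, cache$xhat, p$gamma, cache$istd, dbl)
  list(dx = r$dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

relu_fwd <- function(hx, dbl = FALSE) {
  hy <- tz_lrelu_fwd(hx, 0, dbl)
  list(y = hy, cache = hy)
}
relu_bwd <- function(hdy, hy, dbl = FALSE) tz_lrelu_bwd(hdy, hy, 0, dbl)

lrelu_fwd <- function(hx, alpha = 0.2, dbl = FALSE) {
  hy <- tz_lrelu_fwd(hx, alpha, dbl)
  list(y = hy, cache = hy)
}
lrelu_bwd <- function(hdy, hy, alpha = 0.2, dbl = FALSE)
  tz_lrelu_bwd(hdy, hy, alpha, dbl)

# inverted dropout (mask drawn from R's RNG); identity when not training
dropout_fwd <- function(hx, rate, training, dbl = FALSE) {
  if (!training || rate <= 0) return(list(y = hx, cache = NULL))
  r <- tz_dropout_fwd(hx, rate, dbl)
  list(y = r$y, cache = r$mask)
}
dropout_bwd <- function(hdy, mask, dbl = FALSE) {
  if (is.null(mask)) hdy else tz_mul(hdy, mask, dbl)
}

# conv(3^3) -> BN -> ReLU -> dropout
convblock_init <- function(c_in, c_out) {
  list(conv = conv_init(c_in, c_out, 3L), bn = bn_init(c_out))
}

convblock_fwd <- function(p, hx, dims, B, dropout_rate, training,
                          dbl = FALSE) {
  cv <- conv_fwd(p$conv, hx, dims, B, 3L, 1L, 1L, dbl)
  bn <- bn_fwd(p$bn, cv$y, training, dbl)
  rl <- relu_fwd(bn$y, dbl)
  dp <- dropout_fwd(rl$y, dropout_rate, training, dbl)
  list(y = dp$y, dims = cv$outdims, p_bn = bn$p,
       cache = list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                    drop = dp$cache))
}

convblock_bwd <- function(p, hdy, cache, dbl = FALSE, need_dx = TRUE) {
  hdy <- dropout_bwd(hdy, cache$drop, dbl)
  hdy <- relu_bwd(hdy, cache$relu, dbl)
  bn <- bn_bwd(p$bn, hdy, cache$bn, dbl)
  cv <- conv_bwd(p$conv, bn$dx, cache$conv, dbl, need_dx)
  list(dx = cv$dx, grads = list(conv = cv$grads, bn = bn$grads))
}

# ---- Adam over nested parameter lists -------------------------------------

adam_init_like <- function(p) {
  if (is.list(p)) lapply(p, adam_init_like)
  else numeric(length(p))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in (names(p) %||% seq_along(p))) {
        if (is.null(g[[nm]])) next # untrained leaves (e.g. BN running stats)
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      tz_adam_leaf(p, g, m, v, lr, c1, c2, beta1, beta2, eps)
    }
  }
  walk(params, grads, state$m, state$v)
}
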