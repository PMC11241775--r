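# Neural-network layer drivers.  Heavy arithmetic (dense/conv GEMMs,
# batch-norm, leaky ReLU, RMSprop) lives in the compiled kernels; this file
# holds initialization, layer geometry and the thin R wrappers.
#
# Conv-stack activations travel as "cmat" matrices of shape
# (positions * batch) x channels, positions fastest within each sample.
# The first conv unit of each network instead takes the transposed output
# of a dense layer directly ("pm" layout, per-sample (h, w, c) blocks).

nn_init_dense <- function(n_in, n_out, act = c("lrelu", "tanh", "linear")) {
  act <- match.arg(act)
  sd <- if (act == "tanh") sqrt(1 / n_in) else sqrt(2 / n_in)
  list(W = matrix(rnorm(n_in * n_out, sd = sd), n_in, n_out),
       b = numeric(n_out))
}

nn_init_conv <- function(c_in, c_out, ksize = 3L) {
  k <- ksize * ksize * c_in
  list(W = matrix(rnorm(k * c_out, sd = sqrt(2 / k)), k, c_out),
       b = numeric(c_out))
}

nn_init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       rm = numeric(c_out), rv = rep(1, c_out))
}

# Spatial gather index for a 3x3 "same" convolution: (outH*outW) x 9 matrix
# of 1-based positions into the H x W input plane, 0 marking padding.
# Column order (dj outer, di inner) matches the kernel weight-row order.
conv_index <- function(H, W, stride) {
  outH <- if (stride == 2L) H %/% 2L else H
  outW <- if (stride == 2L) W %/% 2L else W
  p_i <- rep(seq_len(outH), times = outW)
  p_j <- rep(seq_len(outW), each = outH)
  sidx <- matrix(0L, outH * outW, 9L)
  col <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      col <- col + 1L
      hi <- (p_i - 1L) * stride + di
      wi <- (p_j - 1L) * stride + dj
      inside <- hi >= 1L & hi <= H & wi >= 1L & wi <= W
      v <- integer(length(hi))
      v[inside] <- hi[inside] + H * (wi[inside] - 1L)
      sidx[, col] <- v
    }
  }
  list(sidx = sidx, outH = outH, outW = outW)
}

conv_forward <- function(layer, par, x, N, input_pm = FALSE) {
  g <- layer$geom
  out <- cpp_conv_fwd(x, g$sidx, g$C, N, g$H * g$W, input_pm, par$W, par$b)
  list(out = out, x = x, pm = input_pm)
}

conv_backward <- function(layer, par, cache, dy, N) {
  g <- layer$geom
  r <- cpp_conv_bwd(cache$x, g$sidx, g$C, N, g$H * g$W, cache$pm, par$W, dy)
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

bn_forward <- function(par, x, train, momentum = 0.9, eps = 1e-5) {
  cpp_bn_fwd(x, par$gamma, par$beta, par$rm, par$rv, train, momentum, eps)
}

bn_backward <- function(par, cache, dy) {
  r <- cpp_bn_bwd(cache$xhat, cache$inv, par$gamma, dy)
  list(dx = r$dx, grads = list(gamma = r$gamma, beta = r$beta))
}

lrelu_forward <- function(x, slope = 0.2) {
  list(out = cpp_lrelu_fwd(x, slope))
}

lrelu_backward <- function(cache, dy, slope = 0.2) {
  cpp_lrelu_bwd(cache$out, dy, slope)
}

tanh_forward <- function(x) {
  y <- tanh(x)
  list(out = y, y = y)
}

tanh_backward <- function(cache, dy) dy * (1 - cache$y^2)

dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, mask = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

dense_forward <- function(par, x) {
  cpp_dense_fwd(x, par$W, par$b)
}

dense_backward <- function(par, x, dy) {
  r <- cpp_dense_bwd(x, par$W, dy)
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

# cmat -> N x (P*C) flat features (per-sample order p within c)
flatten_cmat <- function(x, P, C, N) {
  dim(x) <- c(P, N, C)
  x <- aperm(x, c(1, 3, 2))
  dim(x) <- c(P * C, N)
  t(x)
}

unflatten_grad <- function(d, P, C, N) {
  d <- t(d)
  dim(d) <- c(P, C, N)
  d <- aperm(d, c(1, 3, 2))
  dim(d) <- c(P * N, C)
  d
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

# RMSprop over a nested parameter list; `state` mirrors the structure.
rmsprop_update <- function(params, grads, state, lr = 2e-4, rho = 0.9, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.list(g)) {
      upd <- rmsprop_update(params[[nm]], g, state[[nm]], lr = lr, rho = rho, eps = eps)
      params[[nm]] <- upd$params
      state[[nm]] <- upd$state
    } else {
      s <- state[[nm]]
      if (is.null(s)) s <- g * 0
      r <- cpp_rmsprop(params[[nm]], s, g, lr, rho, eps)
      params[[nm]] <- r$p
      state[[nm]] <- r$s
    }
  }
  list(params = params, state = state)
}

# copy refreshed batch-norm running statistics out of a training-forward
# cache back into the network parameters
apply_bn_updates <- function(net, cache) {
  for (u in 1:4) {
    bn <- cache[[paste0("u", u)]]$bn
    nm <- paste0("bn", u)
    net$params[[nm]]$rm <- bn$rm
    net$params[[nm]]$rv <- bn$rv
  }
  net
}
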