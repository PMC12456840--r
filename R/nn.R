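# Minimal convolutional-network engine.
#
# Activations are 4-D arrays (channels, height, width, batch).
# Convolutions are im2col + GEMM (kernels in src/nn_kernels.cpp) with
# manual backpropagation; single-threaded and fully deterministic given
# the R RNG state at initialization.  Trainable parameters live under
# each layer's `$par` element; gradients are accumulated into an
# environment keyed by dotted parameter paths (e.g. "stem.conv.W"),
# which is also the addressing scheme of the Adam updater.

conv_layer <- function(c_in, c_out, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_in <- c_in * k * k
  list(par = list(W = matrix(rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)),
                             c_out, fan_in)),
       c_in = c_in, c_out = c_out, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

bn_layer <- function(C, momentum = 0.1, eps = 1e-5) {
  list(par = list(gamma = rep(1, C), beta = rep(0, C)),
       running_mean = rep(0, C), running_var = rep(1, C),
       momentum = momentum, eps = eps)
}

fc_layer <- function(n_in, n_out, w_scale = sqrt(2 / n_in)) {
  list(par = list(W = matrix(rnorm(n_out * n_in, 0, w_scale), n_out, n_in),
                  b = rep(0, n_out)))
}

conv_fwd <- function(layer, x) {
  d <- dim(x)
  Ho <- (d[2] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  Wo <- (d[3] + 2L * layer$pad - layer$k) %/% layer$stride + 1L
  cols <- cpp_im2col(as.vector(x), d[1], d[2], d[3], d[4],
                     layer$k, layer$stride, layer$pad)
  out <- array(layer$par$W %*% cols, c(layer$c_out, Ho, Wo, d[4]))
  list(out = out, cache = list(cols = cols, xdim = d))
}

conv_bwd <- function(layer, cache, dout, grads, prefix) {
  d <- cache$xdim
  dmat <- matrix(dout, layer$c_out)
  grads[[paste0(prefix, ".W")]] <- tcrossprod(dmat, cache$cols)
  dcols <- crossprod(layer$par$W, dmat)
  dx <- cpp_col2im(dcols, d[1], d[2], d[3], d[4],
                   layer$k, layer$stride, layer$pad)
  array(dx, d)
}

bn_fwd <- function(layer, x, training) {
  C <- dim(x)[1]
  xm <- matrix(x, C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_std <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - mu) * inv_std
  out <- array(layer$par$gamma * xhat + layer$par$beta, dim(x))
  list(out = out, layer = layer,
       cache = list(xhat = xhat, inv_std = inv_std, xdim = dim(x),
                    training = training))
}

bn_bwd <- function(layer, cache, dout, grads, prefix) {
  C <- cache$xdim[1]
  dmat <- matrix(dout, C)
  M <- ncol(dmat)
  xhat <- cache$xhat
  grads[[paste0(prefix, ".gamma")]] <- rowSums(dmat * xhat)
  grads[[paste0(prefix, ".beta")]] <- rowSums(dmat)
  dxhat <- dmat * layer$par$gamma
  if (cache$training) {
    dx <- (cache$inv_std / M) *
      (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dx <- dxhat * cache$inv_std
  }
  array(dx, cache$xdim)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_bwd <- function(cache, dout) dout * cache

lrelu_fwd <- function(x, alpha = 0.2) {
  mask <- x > 0
  list(out = ifelse(mask, x, alpha * x), cache = mask, alpha = alpha)
}
lrelu_bwd <- function(cache, dout, alpha = 0.2) {
  ifelse(cache, dout, alpha * dout)
}

# Global (adaptive 1x1) average pooling: (C,H,W,N) -> (C,N).
gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  out <- colMeans(aperm(array(x, c(d[1], hw, d[4])), c(2, 1, 3)))
  if (is.null(dim(out))) out <- matrix(out, d[1], d[4])
  list(out = out, cache = d)
}
gap_bwd <- function(cache, dout) {
  d <- cache
  hw <- d[2] * d[3]
  array(apply(dout / hw, 2, rep, times = hw), d)
}

fc_fwd <- function(layer, x) {
  list(out = layer$par$W %*% x + layer$par$b, cache = x)
}
fc_bwd <- function(layer, cache, dout, grads, prefix) {
  grads[[paste0(prefix, ".W")]] <- tcrossprod(dout, cache)
  grads[[paste0(prefix, ".b")]] <- rowSums(dout)
  crossprod(layer$par$W, dout)
}

# ---- parameter flattening / Adam ------------------------------------------

# Collect every layer's `$par` entries into a flat named list.
flatten_pars <- function(obj, prefix = "") {
  out <- list()
  if (!is.list(obj)) return(out)
  if (!is.null(obj$par)) {
    for (nm in names(obj$par))
      out[[paste0(prefix, ".", nm)]] <- obj$par[[nm]]
  }
  for (nm in setdiff(names(obj), "par")) {
    if (is.list(obj[[nm]]))
      out <- c(out, flatten_pars(obj[[nm]], paste0(prefix, ".", nm)))
  }
  out
}

# Write flat parameters (named as by flatten_pars) back into the model.
set_pars <- function(obj, flat, prefix = "") {
  if (!is.list(obj)) return(obj)
  if (!is.null(obj$par)) {
    for (nm in names(obj$par)) {
      key <- paste0(prefix, ".", nm)
      if (!is.null(flat[[key]])) obj$par[[nm]] <- flat[[key]]
    }
  }
  for (nm in setdiff(names(obj), "par")) {
    if (is.list(obj[[nm]]))
      obj[[nm]] <- set_pars(obj[[nm]], flat, paste0(prefix, ".", nm))
  }
  obj
}

adam_state_init <- function(flat) {
  list(t = 0L,
       m = lapply(flat, function(p) p * 0),
       v = lapply(flat, function(p) p * 0))
}

adam_apply <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(flat = flat, state = state)
}

# ---- residual network (regressor backbone) --------------------------------

# Build a residual regression network: stem conv + 4 stages of basic
# blocks (two 3x3 convs + BN + ReLU each, identity skip; stride-2 entry
# with 1x1 projection from stage 2 on), global average pooling, and a
# fully connected head.  Consumes the R RNG stream for initialization.
resnet_build <- function(input_planes, widths, blocks_per_stage, output_dim) {
  stopifnot(length(widths) >= 1)
  net <- list(stem = list(conv = conv_layer(input_planes, widths[1], 3L),
                          bn = bn_layer(widths[1])),
              stages = list(), fc = NULL,
              input_planes = input_planes, widths = widths,
              blocks_per_stage = blocks_per_stage, output_dim = output_dim)
  c_in <- widths[1]
  for (s in seq_along(widths)) {
    blocks <- list()
    for (j in seq_len(blocks_per_stage)) {
      stride <- if (s > 1 && j == 1) 2L else 1L
      c_out <- widths[s]
      need_proj <- (stride != 1L || c_in != c_out)
      blk <- list(conv1 = conv_layer(c_in, c_out, 3L, stride = stride),
                  bn1 = bn_layer(c_out),
                  conv2 = conv_layer(c_out, c_out, 3L),
                  bn2 = bn_layer(c_out),
                  stride = stride)
      if (need_proj)
        blk$proj <- list(conv = conv_layer(c_in, c_out, 1L, stride = stride,
                                           pad = 0L),
                         bn = bn_layer(c_out))
      blocks[[j]] <- blk
      c_in <- c_out
    }
    net$stages[[s]] <- list(blocks = blocks)
  }
  net$fc <- fc_layer(c_in, output_dim, w_scale = sqrt(1 / c_in))
  # stage/block lists get stable names so gradient paths match
  # flatten_pars() addressing
  names(net$stages) <- as.character(seq_along(net$stages))
  for (s in seq_along(net$stages))
    names(net$stages[[s]]$blocks) <-
      as.character(seq_along(net$stages[[s]]$blocks))
  net
}

block_fwd <- function(blk, x, training) {
  c1 <- conv_fwd(blk$conv1, x)
  b1 <- bn_fwd(blk$bn1, c1$out, training); blk$bn1 <- b1$layer
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(blk$conv2, r1$out)
  b2 <- bn_fwd(blk$bn2, c2$out, training); blk$bn2 <- b2$layer
  if (!is.null(blk$proj)) {
    p <- conv_fwd(blk$proj$conv, x)
    pb <- bn_fwd(blk$proj$bn, p$out, training); blk$proj$bn <- pb$layer
    idn <- pb$out
    proj_cache <- list(conv = p$cache, bn = pb$cache)
  } else {
    idn <- x
    proj_cache <- NULL
  }
  r2 <- relu_fwd(b2$out + idn)
  list(out = r2$out, blk = blk,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    proj = proj_cache))
}

block_bwd <- function(blk, cache, dout, grads, prefix) {
  ds <- relu_bwd(cache$r2, dout)
  # main branch
  db2 <- bn_bwd(blk$bn2, cache$b2, ds, grads, paste0(prefix, ".bn2"))
  dc2 <- conv_bwd(blk$conv2, cache$c2, db2, grads, paste0(prefix, ".conv2"))
  dr1 <- relu_bwd(cache$r1, dc2)
  db1 <- bn_bwd(blk$bn1, cache$b1, dr1, grads, paste0(prefix, ".bn1"))
  dx_main <- conv_bwd(blk$conv1, cache$c1, db1, grads,
                      paste0(prefix, ".conv1"))
  # identity branch
  if (!is.null(blk$proj)) {
    dpb <- bn_bwd(blk$proj$bn, cache$proj$bn, ds, grads,
                  paste0(prefix, ".proj.bn"))
    dx_id <- conv_bwd(blk$proj$conv, cache$proj$conv, dpb, grads,
                      paste0(prefix, ".proj.conv"))
  } else {
    dx_id <- ds
  }
  dx_main + dx_id
}

resnet_fwd <- function(net, x, training = FALSE) {
  c0 <- conv_fwd(net$stem$conv, x)
  b0 <- bn_fwd(net$stem$bn, c0$out, training); net$stem$bn <- b0$layer
  r0 <- relu_fwd(b0$out)
  h <- r0$out
  stage_caches <- vector("list", length(net$stages))
  for (s in seq_along(net$stages)) {
    blocks <- net$stages[[s]]$blocks
    bc <- vector("list", length(blocks))
    for (j in seq_along(blocks)) {
      fw <- block_fwd(blocks[[j]], h, training)
      blocks[[j]] <- fw$blk
      bc[[j]] <- fw$cache
      h <- fw$out
    }
    net$stages[[s]]$blocks <- blocks
    stage_caches[[s]] <- bc
  }
  gp <- gap_fwd(h)
  fo <- fc_fwd(net$fc, gp$out)
  list(out = fo$out, net = net,
       cache = list(c0 = c0$cache, b0 = b0$cache, r0 = r0$cache,
                    stages = stage_caches, gap = gp$cache, fc = fo$cache))
}

resnet_bwd <- function(net, cache, dout) {
  grads <- new.env(parent = emptyenv())
  dh <- fc_bwd(net$fc, cache$fc, dout, grads, ".fc")
  dh <- gap_bwd(cache$gap, dh)
  for (s in rev(seq_along(net$stages))) {
    blocks <- net$stages[[s]]$blocks
    for (j in rev(seq_along(blocks))) {
      dh <- block_bwd(blocks[[j]], cache$stages[[s]][[j]], dh, grads,
                      sprintf(".stages.%d.blocks.%d", s, j))
    }
  }
  dr0 <- relu_bwd(cache$r0, dh)
  db0 <- bn_bwd(net$stem$bn, cache$b0, dr0, grads, ".stem.bn")
  conv_bwd(net$stem$conv, cache$c0, db0, grads, ".stem.conv")
  as.list(grads, all.names = TRUE)
}
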