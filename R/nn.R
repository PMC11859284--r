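# Minimal neural-network compute core: dense, ReLU, 2-D convolution,
# residual blocks, global average pooling, with explicit forward/backward
# passes and Adam/AdamW optimizers. Layers operate on minibatches; dense
# layers on (n x d) matrices, convolutional layers on (n, C, H, W) arrays.
# Weight initialization draws from the current RNG stream, so callers seed
# construction explicitly.

nn_dense <- function(d_in, d_out, init = c("he", "zero", "identity")) {
  init <- match.arg(init)
  W <- switch(init,
    he = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
    zero = matrix(0, d_in, d_out),
    identity = diag(1, d_in, d_out))
  structure(list(type = "dense", W = W, b = numeric(d_out)),
            class = "nn_layer")
}

nn_relu <- function() structure(list(type = "relu"), class = "nn_layer")

# (n x 30) matrix -> (n, 1, H, W) single-channel grid; row j of the default
# 10 x 3 grid holds the (x, y, z) triplet of landmark j.
nn_reshape <- function(layout) {
  structure(list(type = "reshape", layout = as.integer(layout)),
            class = "nn_layer")
}

nn_conv <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    init = c("he", "zero")) {
  init <- match.arg(init)
  fan_in <- in_ch * k * k
  W <- array(if (init == "he") stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in))
             else 0,
             dim = c(out_ch, in_ch, k, k))
  structure(list(type = "conv", W = W, b = numeric(out_ch),
                 stride = as.integer(stride), pad = as.integer(pad)),
            class = "nn_layer")
}

nn_gap <- function() structure(list(type = "gap"), class = "nn_layer")

# Basic residual block: conv3x3(stride) -> relu -> conv3x3, identity (or
# 1x1-projection) skip, final relu.
nn_resblock <- function(in_ch, out_ch, stride = 1L) {
  proj <- if (in_ch != out_ch || stride != 1L)
    nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L)
  structure(list(type = "resblock",
                 conv1 = nn_conv(in_ch, out_ch, 3L, stride),
                 conv2 = nn_conv(out_ch, out_ch, 3L, 1L),
                 proj = proj),
            class = "nn_layer")
}

# Bottleneck residual block (1x1 reduce -> 3x3 -> 1x1 expand, expansion 4).
nn_bottleneck <- function(in_ch, mid_ch, stride = 1L) {
  out_ch <- 4L * mid_ch
  proj <- if (in_ch != out_ch || stride != 1L)
    nn_conv(in_ch, out_ch, k = 1L, stride = stride, pad = 0L)
  structure(list(type = "bottleneck",
                 conv1 = nn_conv(in_ch, mid_ch, 1L, 1L, 0L),
                 conv2 = nn_conv(mid_ch, mid_ch, 3L, stride),
                 conv3 = nn_conv(mid_ch, out_ch, 1L, 1L, 0L),
                 proj = proj),
            class = "nn_layer")
}

# --- convolution via im2col ------------------------------------------------

# Within-sample flat offsets (0-based) of every patch element; rows index
# output positions (i fastest), columns index (channel, ki, kj), channel
# fastest — the same ordering used to flatten the weight array.
conv_offsets <- function(C, Hp, Wp, Ho, Wo, k, stride) {
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  h0 <- (i - 1L) * stride
  w0 <- (j - 1L) * stride
  cc <- rep(seq_len(C), times = k * k)
  ki <- rep(rep(seq_len(k), each = C), times = k)
  kj <- rep(seq_len(k), each = C * k)
  Oh <- outer(h0, ki, "+")                      # 1-based row into padded grid
  Ow <- outer(w0, kj, "+")
  Oc <- matrix(cc, Ho * Wo, C * k * k, byrow = TRUE)
  (Oc - 1) + C * ((Oh - 1) + Hp * (Ow - 1))
}

conv_fwd <- function(x, layer) {
  dn <- dim(x); n <- dn[1]; C <- dn[2]; H <- dn[3]; Wd <- dn[4]
  W <- layer$W; k <- dim(W)[3]; OC <- dim(W)[1]
  stride <- layer$stride; pad <- layer$pad
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  if (Ho < 1 || Wo < 1) stop("conv input too small for kernel", call. = FALSE)
  xp <- if (pad > 0) {
    tmp <- array(0, c(n, C, Hp, Wp))
    tmp[, , pad + seq_len(H), pad + seq_len(Wd)] <- x
    tmp
  } else x
  off <- conv_offsets(C, Hp, Wp, Ho, Wo, k, stride)
  idx <- outer(seq_len(n), n * as.vector(off), "+")
  cols <- matrix(xp[idx], n * Ho * Wo, C * k * k)
  Wmat <- matrix(aperm(W, c(2, 3, 4, 1)), C * k * k, OC)
  om <- cols %*% Wmat
  om <- om + rep(layer$b, each = nrow(om))
  out <- aperm(array(om, c(n, Ho, Wo, OC)), c(1, 4, 2, 3))
  list(out = out,
       cache = list(cols = cols, off = off, n = n, C = C, H = H, Wd = Wd,
                    Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo))
}

conv_bwd <- function(dout, layer, cache) {
  W <- layer$W; k <- dim(W)[3]; OC <- dim(W)[1]
  n <- cache$n; C <- cache$C; Ho <- cache$Ho; Wo <- cache$Wo
  dmat <- matrix(aperm(dout, c(1, 3, 4, 2)), n * Ho * Wo, OC)
  db <- colSums(dmat)
  dWmat <- crossprod(cache$cols, dmat)
  dW <- aperm(array(dWmat, c(C, k, k, OC)), c(4, 1, 2, 3))
  Wmat <- matrix(aperm(W, c(2, 3, 4, 1)), C * k * k, OC)
  dcols <- dmat %*% t(Wmat)
  # scatter-add patch gradients back into the padded input grid
  iv <- as.vector(outer(seq_len(n), n * as.vector(cache$off), "+"))
  acc <- rowsum(as.vector(dcols), iv)
  dxp_flat <- numeric(n * C * cache$Hp * cache$Wp)
  dxp_flat[as.numeric(rownames(acc))] <- acc
  dxp <- array(dxp_flat, c(n, C, cache$Hp, cache$Wp))
  pad <- layer$pad
  dx <- if (pad > 0)
    dxp[, , pad + seq_len(cache$H), pad + seq_len(cache$Wd), drop = FALSE]
  else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

# --- per-layer dispatch ----------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$W + rep(layer$b, each = nrow(x))
      list(out = out, cache = list(x = x))
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = list(mask = x > 0))
    },
    reshape = {
      n <- nrow(x); H <- layer$layout[1]; Wd <- layer$layout[2]
      # row-major fill: grid[h, w] = x[, (h-1)*Wd + w]
      a <- aperm(array(t(x), c(Wd, H, n)), c(3, 2, 1))
      dim(a) <- c(n, 1L, H, Wd)
      list(out = a, cache = list(n = n))
    },
    gap = {
      dn <- dim(x)
      out <- matrix(rowMeans(matrix(x, dn[1] * dn[2])), dn[1], dn[2])
      list(out = out, cache = list(dims = dn))
    },
    conv = conv_fwd(x, layer),
    resblock = {
      f1 <- conv_fwd(x, layer$conv1)
      r1 <- pmax(f1$out, 0)
      f2 <- conv_fwd(r1, layer$conv2)
      sk <- if (is.null(layer$proj)) list(out = x, cache = NULL)
            else conv_fwd(x, layer$proj)
      pre <- f2$out + sk$out
      list(out = pmax(pre, 0),
           cache = list(c1 = f1$cache, m1 = f1$out > 0, c2 = f2$cache,
                        csk = sk$cache, mout = pre > 0))
    },
    bottleneck = {
      f1 <- conv_fwd(x, layer$conv1); r1 <- pmax(f1$out, 0)
      f2 <- conv_fwd(r1, layer$conv2); r2 <- pmax(f2$out, 0)
      f3 <- conv_fwd(r2, layer$conv3)
      sk <- if (is.null(layer$proj)) list(out = x, cache = NULL)
            else conv_fwd(x, layer$proj)
      pre <- f3$out + sk$out
      list(out = pmax(pre, 0),
           cache = list(c1 = f1$cache, m1 = f1$out > 0, c2 = f2$cache,
                        m2 = f2$out > 0, c3 = f3$cache, csk = sk$cache,
                        mout = pre > 0))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    dense = list(dx = dout %*% t(layer$W),
                 grads = list(W = crossprod(cache$x, dout),
                              b = colSums(dout))),
    relu = list(dx = dout * cache$mask, grads = NULL),
    reshape = {
      n <- cache$n
      dx <- t(matrix(aperm(array(dout, dim(dout)[-2]), c(3, 2, 1)),
                     ncol = n))
      list(dx = dx, grads = NULL)
    },
    gap = {
      dn <- cache$dims
      dx <- array(rep(as.vector(dout) / (dn[3] * dn[4]), dn[3] * dn[4]), dn)
      list(dx = dx, grads = NULL)
    },
    conv = conv_bwd(dout, layer, cache),
    resblock = {
      dpre <- dout * cache$mout
      b2 <- conv_bwd(dpre, layer$conv2, cache$c2)
      b1 <- conv_bwd(b2$dx * cache$m1, layer$conv1, cache$c1)
      if (is.null(layer$proj)) {
        dx <- b1$dx + dpre
        proj_g <- NULL
      } else {
        bp <- conv_bwd(dpre, layer$proj, cache$csk)
        dx <- b1$dx + bp$dx
        proj_g <- bp$grads
      }
      list(dx = dx, grads = list(conv1 = b1$grads, conv2 = b2$grads,
                                 proj = proj_g))
    },
    bottleneck = {
      dpre <- dout * cache$mout
      b3 <- conv_bwd(dpre, layer$conv3, cache$c3)
      b2 <- conv_bwd(b3$dx * cache$m2, layer$conv2, cache$c2)
      b1 <- conv_bwd(b2$dx * cache$m1, layer$conv1, cache$c1)
      if (is.null(layer$proj)) {
        dx <- b1$dx + dpre
        proj_g <- NULL
      } else {
        bp <- conv_bwd(dpre, layer$proj, cache$csk)
        dx <- b1$dx + bp$dx
        proj_g <- bp$grads
      }
      list(dx = dx, grads = list(conv1 = b1$grads, conv2 = b2$grads,
                                 conv3 = b3$grads, proj = proj_g))
    },
    stop("unknown layer type: ", layer$type))
}

layer_params <- function(layer) {
  switch(layer$type,
    dense = , conv = list(W = layer$W, b = layer$b),
    resblock = list(conv1 = layer_params(layer$conv1),
                    conv2 = layer_params(layer$conv2),
                    proj = if (!is.null(layer$proj)) layer_params(layer$proj)),
    bottleneck = list(conv1 = layer_params(layer$conv1),
                      conv2 = layer_params(layer$conv2),
                      conv3 = layer_params(layer$conv3),
                      proj = if (!is.null(layer$proj)) layer_params(layer$proj)),
    NULL)
}

layer_set_params <- function(layer, params) {
  if (is.null(params)) return(layer)
  switch(layer$type,
    dense = , conv = { layer$W <- params$W; layer$b <- params$b },
    resblock = {
      layer$conv1 <- layer_set_params(layer$conv1, params$conv1)
      layer$conv2 <- layer_set_params(layer$conv2, params$conv2)
      if (!is.null(layer$proj))
        layer$proj <- layer_set_params(layer$proj, params$proj)
    },
    bottleneck = {
      layer$conv1 <- layer_set_params(layer$conv1, params$conv1)
      layer$conv2 <- layer_set_params(layer$conv2, params$conv2)
      layer$conv3 <- layer_set_params(layer$conv3, params$conv3)
      if (!is.null(layer$proj))
        layer$proj <- layer_set_params(layer$proj, params$proj)
    })
  layer
}

# --- network ---------------------------------------------------------------

nn_network <- function(layers) {
  structure(list(layers = layers), class = "nn_network")
}

nn_forward <- function(net, x, keep = FALSE) {
  caches <- if (keep) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    f <- layer_forward(net$layers[[i]], x)
    x <- f$out
    if (keep) caches[[i]] <- f$cache
  }
  if (keep) list(out = x, caches = caches) else x
}

nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- layer_backward(net$layers[[i]], caches[[i]], dout)
    grads[i] <- list(b$grads)   # keep NULL slots for paramless layers
    dout <- b$dx
  }
  list(dx = dout, grads = grads)
}

nn_params <- function(net) lapply(net$layers, layer_params)

nn_set_params <- function(net, params) {
  for (i in seq_along(net$layers))
    net$layers[[i]] <- layer_set_params(net$layers[[i]], params[[i]])
  net
}

nn_n_params <- function(net) {
  n <- 0
  rapply(nn_params(net), function(p) n <<- n + length(p), how = "unlist")
  n
}

# --- nested-list ("tree") arithmetic over parameter structures -------------

tree_map <- function(f, a) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) return(lapply(a, function(ai) tree_map(f, ai)))
  f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

# --- optimizers ------------------------------------------------------------

# Adam with decoupled weight decay (AdamW when weight_decay > 0). State holds
# first/second moment estimates and the step counter.
adamw_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0)
    params <- tree_map(function(p) p - lr * weight_decay * p, params)
  list(params = params, state = state)
}

# Learning-rate schedules (epoch is 1-based).
lr_cosine <- function(base_lr, epoch, total_epochs) {
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1) / max(1, total_epochs)))
}

lr_multistep <- function(base_lr, epoch, milestones = c(50, 75),
                         gamma = 0.1) {
  base_lr * gamma^sum(epoch > milestones)
}
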