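# Forward/backward primitives for the tile classifier. Feature maps are
# (H, W, C, N) arrays; kernels are (k, k, Cin, Cout). Batch norm keeps
# biased batch statistics and exponential running statistics; fusion
# later uses the running statistics (inference semantics).

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.conv_fwd <- function(x, K, bias = NULL, stride = 1L, pad = 1L) {
  if (dim(x)[3L] != dim(K)[3L]) {
    .shape_error(sprintf("conv: input has %d channels, kernel expects %d",
                         dim(x)[3L], dim(K)[3L]))
  }
  .cpp_conv_fwd(x, K, bias, as.integer(stride), as.integer(pad))
}

.conv_bwd <- function(x, K, gout, stride, pad, has_bias, want_gx = TRUE) {
  .cpp_conv_bwd(x, K, gout, as.integer(stride), as.integer(pad), has_bias,
                want_gx)
}

.bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       mean = rep(0, C), var = rep(1, C))
}

# Batch-norm forward. In training mode normalizes by biased batch
# statistics and returns updated running statistics; in inference mode
# uses the stored running statistics.
.bn_fwd <- function(x, p, training) {
  d <- dim(x)
  m <- d[1L] * d[2L] * d[4L]
  if (training) {
    mom <- .cpp_ch_moments(x)
    mu <- mom$s1 / m
    va <- pmax(mom$s2 / m - mu^2, 0)
    stats <- list(
      mean = (1 - .BN_MOMENTUM) * p$mean + .BN_MOMENTUM * mu,
      var  = (1 - .BN_MOMENTUM) * p$var + .BN_MOMENTUM * va
    )
  } else {
    mu <- p$mean
    va <- p$var
    stats <- NULL
  }
  istd <- 1 / sqrt(va + .BN_EPS)
  r <- .cpp_bn_apply(x, mu, istd, p$gamma, p$beta)
  list(y = r$y, cache = list(xhat = r$xhat, istd = istd), stats = stats)
}

.bn_bwd <- function(gy, cache, gamma) {
  r <- .cpp_bn_bwd(gy, cache$xhat, gamma, cache$istd)
  list(gx = r$gx, g = list(gamma = r$ggamma, beta = r$gbeta))
}

# --- channel attention -------------------------------------------------

.gct_new <- function(C, eps = 1e-5) {
  list(kind = "gct", alpha = rep(1, C), beta = rep(0, C),
       gamma = rep(0, C), eps = eps)
}

.se_new <- function(C, r, seed_offset = 0L) {
  Cr <- C %/% r
  # small random bottleneck weights (He-style), biases zero
  list(kind = "se",
       W1 = matrix(rnorm(Cr * C, sd = sqrt(2 / C)), Cr, C),
       b1 = rep(0, Cr),
       W2 = matrix(rnorm(C * Cr, sd = sqrt(2 / Cr)), C, Cr),
       b2 = rep(0, C),
       r = r)
}

#' Gated channel transformation
#'
#' Channel attention built from an l2 channel embedding, l2 channel
#' normalization and a tanh gate: per sample and channel c,
#' `s_c = alpha_c * sqrt(sum(x_c^2) + eps)`,
#' `shat_c = s_c * sqrt(C) / sqrt(sum_c(s_c^2) + eps)`,
#' `out_c = x_c * (1 + tanh(gamma_c * shat_c + beta_c))`.
#' With `gamma = beta = 0` (the initialization) the module is an exact
#' identity.
#'
#' @param x feature-map array of dim (H, W, C, N).
#' @param params list with `alpha`, `beta`, `gamma` (each length C) and
#'   scalar `eps`, as produced inside [buildModel()].
#' @return Array of the same shape as `x`.
#' @export
#' @examples
#' x <- array(rnorm(2 * 2 * 3 * 1), c(2, 2, 3, 1))
#' p <- list(alpha = rep(1, 3), beta = rep(0, 3), gamma = rep(0, 3),
#'           eps = 1e-5)
#' stopifnot(identical(gctForward(x, p), x))
gctForward <- function(x, params) {
  .gct_fwd(x, params)$y
}

# Gate computation only (one read of x); the caller applies the gate,
# optionally fused with the following ReLU.
.gct_gate <- function(x, p) {
  d <- dim(x)
  C <- d[3L]
  if (length(p$alpha) != C) {
    .shape_error(sprintf("gct: input has %d channels, params expect %d",
                         C, length(p$alpha)))
  }
  nrm <- sqrt(.ch_sum(x, x) + p$eps)           # C x N
  s <- nrm * p$alpha
  u <- .colSums(s * s, C, d[4L]) + p$eps       # length N
  tmat <- s * rep(sqrt(C / u), each = C)
  th <- tanh(p$gamma * tmat + p$beta)
  list(x = x, nrm = nrm, s = s, u = u, tmat = tmat, th = th,
       gate = 1 + th)
}

.gct_fwd <- function(x, p) {
  g <- .gct_gate(x, p)
  list(y = .ch_mul(x, g$gate), cache = g)
}

.gct_bwd <- function(gy, cache, p) {
  x <- cache$x
  d <- dim(x)
  C <- d[3L]
  ggate <- .ch_sum(gy, x)
  dpre <- ggate * (1 - cache$th^2)
  dt <- dpre * p$gamma
  A <- .colSums(dt * cache$s, C, d[4L])
  ds <- sqrt(C) * (dt * rep(1 / sqrt(cache$u), each = C) -
                   cache$s * rep(A / cache$u^1.5, each = C))
  dn <- ds * p$alpha
  gx <- .cpp_two_affine_add(gy, as.vector(cache$gate),
                            x, as.vector(dn / cache$nrm))
  list(gx = gx,
       g = list(alpha = rowSums(ds * cache$nrm),
                beta  = rowSums(dpre),
                gamma = rowSums(dpre * cache$tmat)))
}

#' Squeeze-and-excitation attention
#'
#' Global average pooling per channel, a two-layer bottleneck
#' (reduction `r`) with ReLU, and a sigmoid gate in (0, 1) multiplied
#' back onto the channels.
#'
#' @param x feature-map array of dim (H, W, C, N).
#' @param params list with `W1` (C/r x C), `b1`, `W2` (C x C/r), `b2`.
#' @return Array of the same shape as `x`.
#' @export
seForward <- function(x, params) {
  .se_fwd(x, params)$y
}

.se_gate <- function(x, p) {
  d <- dim(x)
  C <- d[3L]
  if (ncol(p$W1) != C) {
    .shape_error(sprintf("se: input has %d channels, params expect %d",
                         C, ncol(p$W1)))
  }
  HW <- d[1L] * d[2L]
  z <- .ch_sum(x) / HW                       # C x N
  h <- pmax(p$W1 %*% z + p$b1, 0)            # C/r x N
  a <- .sigmoid(p$W2 %*% h + p$b2)           # C x N
  list(x = x, z = z, h = h, a = a, HW = HW, gate = a)
}

.se_fwd <- function(x, p) {
  g <- .se_gate(x, p)
  list(y = .ch_mul(x, g$a), cache = g)
}

.se_bwd <- function(gy, cache, p) {
  x <- cache$x
  ga <- .ch_sum(gy, x)
  d2 <- ga * cache$a * (1 - cache$a)
  dh <- crossprod(p$W2, d2)
  d1 <- dh * (cache$h > 0)
  dz <- crossprod(p$W1, d1)
  gx <- .ch_affine(gy, as.vector(cache$a), as.vector(dz) / cache$HW)
  list(gx = gx,
       g = list(W1 = tcrossprod(d1, cache$z), b1 = rowSums(d1),
                W2 = tcrossprod(d2, cache$h), b2 = rowSums(d2)))
}

.att_bwd <- function(gy, cache, att) {
  if (is.null(att)) return(list(gx = gy, g = NULL))
  switch(att$kind,
    gct = .gct_bwd(gy, cache, att),
    se  = .se_bwd(gy, cache, att)
  )
}

# --- layers ------------------------------------------------------------

# One layer forward. Returns y, a cache for backward, and (training
# mode) updated BN running statistics.
.layer_fwd <- function(layer, x, training = FALSE) {
  cache <- list()
  stats <- NULL
  if (layer$type == "ecm") {
    c3 <- .conv_fwd(x, layer$b3$K, NULL, layer$stride, 1L)
    r3 <- .bn_fwd(c3, layer$b3$bn, training)
    c1 <- .conv_fwd(x, layer$b1$K, NULL, layer$stride, 0L)
    r1 <- .bn_fwd(c1, layer$b1$bn, training)
    rid <- NULL
    if (!is.null(layer$bid)) {
      rid <- .bn_fwd(x, layer$bid, training)
      s <- .cpp_add(r3$y, r1$y, rid$y)
    } else {
      s <- .cpp_add(r3$y, r1$y, NULL)
    }
    if (training) {
      stats <- list(b3 = r3$stats, b1 = r1$stats,
                    bid = if (is.null(rid)) NULL else rid$stats)
    }
    cache$bn3 <- r3$cache
    cache$bn1 <- r1$cache
    cache$bnid <- if (is.null(rid)) NULL else rid$cache
  } else if (layer$type == "conv") {
    s <- .conv_fwd(x, layer$K, layer$b, layer$stride, 1L)
  } else {                                   # plain (baseline) layer
    s <- .conv_fwd(x, layer$K, NULL, layer$stride, 1L)
  }
  if (is.null(layer$att)) {
    y <- .cpp_relu(s)
  } else {
    g <- switch(layer$att$kind, gct = .gct_gate(s, layer$att),
                se = .se_gate(s, layer$att))
    y <- .cpp_ch_mul_relu(s, as.vector(g$gate))
    cache$att <- g
  }
  cache$y <- y
  list(y = y, cache = cache, stats = stats)
}

# One layer backward. `x` is the layer input that produced `cache`;
# `need_gx = FALSE` (first layer) skips the input gradient entirely.
.layer_bwd <- function(layer, x, cache, gy, need_gx = TRUE) {
  gy <- .cpp_mask_pos(gy, cache$y)
  ab <- .att_bwd(gy, cache$att, layer$att)
  gs <- ab$gx
  gx <- NULL
  if (layer$type == "ecm") {
    g3 <- .bn_bwd(gs, cache$bn3, layer$b3$bn$gamma)
    c3 <- .conv_bwd(x, layer$b3$K, g3$gx, layer$stride, 1L, FALSE, need_gx)
    g1 <- .bn_bwd(gs, cache$bn1, layer$b1$bn$gamma)
    c1 <- .conv_bwd(x, layer$b1$K, g1$gx, layer$stride, 0L, FALSE, need_gx)
    grads <- list(b3 = list(K = c3$gw, bn = g3$g),
                  b1 = list(K = c1$gw, bn = g1$g))
    if (!is.null(layer$bid)) {
      gid <- .bn_bwd(gs, cache$bnid, layer$bid$gamma)
      if (need_gx) gx <- .cpp_add(c3$gx, c1$gx, gid$gx)
      grads$bid <- gid$g
    } else if (need_gx) {
      gx <- .cpp_add(c3$gx, c1$gx, NULL)
    }
  } else if (layer$type == "conv") {
    cb <- .conv_bwd(x, layer$K, gs, layer$stride, 1L, TRUE, need_gx)
    if (need_gx) gx <- cb$gx
    grads <- list(K = cb$gw, b = cb$gb)
  } else {
    cb <- .conv_bwd(x, layer$K, gs, layer$stride, 1L, FALSE, need_gx)
    if (need_gx) gx <- cb$gx
    grads <- list(K = cb$gw)
  }
  if (!is.null(ab$g)) grads$att <- ab$g
  list(gx = gx, grads = grads)
}

# Head: global average pool then linear map to logits (N x K).
.head_fwd <- function(head, y) {
  d <- dim(y)
  z <- .ch_sum(y) / (d[1L] * d[2L])          # C x N
  feats <- t(z)
  logits <- feats %*% t(head$W)
  logits <- sweep(logits, 2L, head$b, "+")
  list(logits = logits, cache = list(feats = feats, d = d))
}

.head_bwd <- function(head, cache, dlogits) {
  gW <- t(dlogits) %*% cache$feats
  gb <- colSums(dlogits)
  dz <- t(dlogits %*% head$W)                # C x N
  d <- cache$d
  gy <- .ch_affine(array(0, d), 0, dz / (d[1L] * d[2L]))
  list(gy = gy, grads = list(W = gW, b = gb))
}

# Softmax cross-entropy; `ylab` are 1-based class indices.
.ce_loss <- function(logits, ylab) {
  p <- .softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), ylab)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n)
}

# --- parameter-tree SGD ------------------------------------------------

# Recursively map over a nested parameter list, pairing with a grad tree
# of identical shape (driven by the grad tree, so non-learnable leaves
# like BN running stats are never touched). Weight decay is applied to
# convolution kernels and linear weights only.
.DECAY_NAMES <- c("K", "W", "W1", "W2")

.tree_zero <- function(g) {
  if (is.list(g)) return(lapply(g, .tree_zero))
  g * 0
}

.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) return(mapply(.tree_add, a, b, SIMPLIFY = FALSE))
  a + b
}

# One SGD-with-momentum step, in the style of the usual deep-learning
# update: v <- mu*v + (g + wd*p); p <- p - lr*v.
.sgd_step <- function(params, grads, vel, lr, momentum, wd, name = "") {
  if (is.list(grads)) {
    for (nm in names(grads)) {
      if (is.null(grads[[nm]]) || nm == "kind") next
      r <- .sgd_step(params[[nm]], grads[[nm]],
                     if (is.null(vel)) NULL else vel[[nm]],
                     lr, momentum, wd, nm)
      params[[nm]] <- r$p
      vel[[nm]] <- r$v
    }
    return(list(p = params, v = vel))
  }
  g <- grads
  if (name %in% .DECAY_NAMES && wd > 0) g <- g + wd * params
  v <- if (is.null(vel)) g else momentum * vel + g
  list(p = params - lr * v, v = v)
}
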