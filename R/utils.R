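# Internal helpers: classed conditions, seed scoping, channel algebra on
# (H, W, C, N) arrays.

.her2_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "her2_error")))
}
.config_error  <- function(msg) .her2_stop(msg, "her2_config_error")
.data_error    <- function(msg) .her2_stop(msg, "her2_data_error")
.shape_error   <- function(msg) .her2_stop(msg, "her2_shape_error")
.numeric_error <- function(msg) .her2_stop(msg, "her2_numeric_error")
.state_error   <- function(msg) .her2_stop(msg, "her2_state_error")
.notumor_error <- function(msg) .her2_stop(msg, "her2_notumor_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
.child_seeds <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# --- channel algebra on arrays of dim (H, W, C, N) ---------------------
# Thin wrappers over the fused C++ kernels (see src/channel_ops.cpp).

# Per-channel, per-sample sums of x (or x*y): returns a C x N matrix.
.ch_sum <- function(x, y = NULL) .cpp_ch_sum(x, y)

# x * scale[c] + shift[c]; scale/shift length C or a C x N matrix.
.ch_affine <- function(x, scale, shift = 0) {
  C <- dim(x)[3L]
  scale <- as.vector(scale)
  shift <- as.vector(shift)
  if (length(scale) == 1L) scale <- rep(scale, C)
  if (length(shift) == 1L) shift <- rep(shift, C)
  .cpp_ch_affine(x, scale, shift)
}

.ch_mul <- function(x, s) .ch_affine(x, s, 0)

.relu <- function(x) {
  if (is.array(x) && length(dim(x)) == 4L) return(.cpp_relu(x))
  x[x < 0] <- 0
  x
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Coerce an image-like object to a (H, W, 3) double array in [0, 1].
.as_rgb_array <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    return(img[, , 1:3, drop = FALSE] * 1.0)
  }
  if (is.matrix(img)) {
    return(array(rep(img, 3L), c(dim(img), 3L)))
  }
  .shape_error("expected an H x W x 3 image array")
}

# Stack a list of (H, W, 3) images into the network layout (H, W, C, N).
.stack_tiles <- function(imgs) {
  d <- dim(imgs[[1L]])
  out <- array(0, c(d[1L], d[2L], 3L, length(imgs)))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    if (!identical(dim(im)[1:2], d[1:2])) {
      .shape_error("all tiles in a batch must share the same size")
    }
    out[, , , i] <- im[, , 1:3]
  }
  out
}
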