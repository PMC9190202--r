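# Structural re-parameterization: exact algebraic conversion of the
# multi-branch training blocks into single 3x3 convolutions. Per output
# channel, folding a batch-norm with statistics (mu, sigma) and affine
# (gamma, beta) into the preceding convolution gives
#   K' = K * gamma / sigma,   b' = (b - mu) * gamma / sigma + beta,
# 1x1 kernels embed at the center of a zero 3x3 kernel, and the identity
# branch is a Dirac 3x3 kernel; branch sums merge by elementwise
# addition because convolution is linear in its kernel.

#' Fold a batch-norm layer into the preceding convolution
#'
#' @param kernel convolution kernel, array (k, k, Cin, Cout).
#' @param bias convolution bias (length Cout) or NULL (treated as zero).
#' @param bn list with `gamma`, `beta`, `mean`, `var` (per output
#'   channel); the standard deviation used is `sqrt(var + eps)`.
#' @param eps batch-norm epsilon (default 1e-5).
#' @return List with fused `K` and `b` such that
#'   `conv(x, K, b) == bn(conv(x, kernel, bias))` for every input.
#' @export
#' @examples
#' bn <- list(gamma = 3, beta = 1, mean = 0.5, var = 4 - 1e-5)
#' fuseConvBN(array(1, c(1, 1, 1, 1)), 0, bn)   # K' = 1.5, b' = 0.25
fuseConvBN <- function(kernel, bias = NULL, bn, eps = 1e-5) {
  d <- dim(kernel)
  if (length(d) != 4L || d[1L] != d[2L]) {
    .shape_error("kernel must be a (k, k, Cin, Cout) array")
  }
  cout <- d[4L]
  if (any(!is.finite(bn$var)) || any(bn$var + eps <= 0)) {
    .numeric_error("batch-norm standard deviation must be positive")
  }
  sigma <- sqrt(bn$var + eps)
  if (is.null(bias)) bias <- rep(0, cout)
  scale <- bn$gamma / sigma
  K <- kernel * rep(scale, each = d[1L] * d[2L] * d[3L])
  b <- (bias - bn$mean) * scale + bn$beta
  list(K = K, b = b)
}

#' Embed a 1x1 kernel at the center of a 3x3 kernel
#'
#' Convolving with the padded kernel at padding 1 equals convolving with
#' the original 1x1 kernel at padding 0.
#'
#' @param kernel1 array (1, 1, Cin, Cout).
#' @return Array (3, 3, Cin, Cout), zero except at the center.
#' @export
pad1x1To3x3 <- function(kernel1) {
  d <- dim(kernel1)
  if (length(d) != 4L || d[1L] != 1L || d[2L] != 1L) {
    .shape_error("kernel must be a (1, 1, Cin, Cout) array")
  }
  K <- array(0, c(3L, 3L, d[3L], d[4L]))
  K[2L, 2L, , ] <- kernel1[1L, 1L, , ]
  K
}

#' Dirac 3x3 kernel realizing the identity map
#'
#' `kernel[2, 2, i, i] = 1` and zero elsewhere, so that stride-1
#' convolution with padding 1 returns its input unchanged.
#'
#' @param C channel count.
#' @return Array (3, 3, C, C).
#' @export
identityTo3x3 <- function(C) {
  C <- as.integer(C)
  if (length(C) != 1L || is.na(C) || C < 1L) {
    .config_error("channel count must be a positive integer")
  }
  K <- array(0, c(3L, 3L, C, C))
  for (i in seq_len(C)) K[2L, 2L, i, i] <- 1
  K
}

#' Merge parallel convolution branches by elementwise addition
#'
#' @param branches list of lists, each with a 3x3 kernel `K` and bias
#'   `b`; all shapes must agree.
#' @return List with summed `K` and `b`.
#' @export
mergeBranches <- function(branches) {
  if (length(branches) < 1L) .shape_error("need at least one branch")
  d <- dim(branches[[1L]]$K)
  nb <- length(branches[[1L]]$b)
  for (br in branches) {
    if (!identical(dim(br$K), d) || length(br$b) != nb) {
      .shape_error("all branches must share kernel shape and bias length")
    }
  }
  list(K = Reduce(`+`, lapply(branches, `[[`, "K")),
       b = Reduce(`+`, lapply(branches, `[[`, "b")))
}

#' Fuse one multi-branch block into a single 3x3 convolution
#'
#' Pipeline: fold each branch's batch norm into its convolution, embed
#' the 1x1 branch into a 3x3 kernel, realize the identity branch as a
#' Dirac kernel folded with its own batch norm, then sum all branches.
#' Attention parameters sit outside the branch sum and pass through
#' untouched.
#'
#' @param layer an `"ecm"` layer parameter list (as held by a train-mode
#'   [TLCNModel-class]).
#' @return List with fused `K`, `b` and the untouched `att` parameters.
#' @export
reparameterizeBlock <- function(layer) {
  if (!identical(layer$type, "ecm")) {
    .state_error("only multi-branch (ecm) blocks can be re-parameterized")
  }
  branches <- list(
    fuseConvBN(layer$b3$K, NULL, layer$b3$bn),
    local({
      f <- fuseConvBN(layer$b1$K, NULL, layer$b1$bn)
      list(K = pad1x1To3x3(f$K), b = f$b)
    })
  )
  if (!is.null(layer$bid)) {
    branches[[3L]] <- fuseConvBN(identityTo3x3(layer$cout), NULL, layer$bid)
  }
  m <- mergeBranches(branches)
  list(K = m$K, b = m$b, att = layer$att)
}

#' Convert a training model into its fused deployment model
#'
#' Exact re-parameterization of every block; for any input, the fused
#' model's logits agree with the training model run in inference mode to
#' floating-point accumulation error, and the fused model always has
#' fewer learnable parameters.
#'
#' @param model a train-mode [TLCNModel-class] with populated batch-norm
#'   running statistics.
#' @return A deploy-mode [TLCNModel-class].
#' @export
#' @examples
#' tm <- buildModel(tlcnConfig(c(1, 1, 1, 1, 1), c(4, 4, 8, 8, 8),
#'                             attention = "none", mode = "train"),
#'                  seed = 1)
#' dm <- reparameterizeModel(tm)
#' countParams(dm) < countParams(tm)
reparameterizeModel <- function(model) {
  if (model@config@mode != "train") {
    .state_error("model is not in train mode; nothing to re-parameterize")
  }
  cfg <- model@config
  cfg@mode <- "deploy"
  layers <- lapply(model@layers, function(layer) {
    f <- reparameterizeBlock(layer)
    list(type = "conv", stride = layer$stride, cin = layer$cin,
         cout = layer$cout, K = f$K, b = f$b, att = f$att)
  })
  new("TLCNModel", config = cfg, layers = layers, head = model@head,
      classLabels = model@classLabels)
}
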