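# Backbone: build the tile classifier in train (multi-branch), deploy
# (fused plain conv) or baseline (plain chain, no bias/BN) mode, count
# its learnable parameters, and run the forward pass.

# Per-layer (cin, cout, stride) table implied by a config: the first
# layer of every stage has stride 2, the rest stride 1.
.layer_specs <- function(config, cin0 = 3L) {
  specs <- list()
  cin <- cin0
  for (s in seq_along(config@stageDepths)) {
    for (i in seq_len(config@stageDepths[s])) {
      cout <- config@stageWidths[s]
      specs[[length(specs) + 1L]] <-
        list(cin = cin, cout = cout, stride = if (i == 1L) 2L else 1L)
      cin <- cout
    }
  }
  specs
}

.kernel_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

.att_init <- function(config, C) {
  switch(config@attention,
    none = NULL,
    gct  = .gct_new(C),
    se   = .se_new(C, config@seReduction)
  )
}

#' Build a tile-classifier model
#'
#' Constructs the network pinned by a [TLCNConfig-class]: in `"train"`
#' mode each layer is a multi-branch block (bias-free 3x3 conv + BN,
#' bias-free 1x1 conv + BN, and an identity BN branch where stride is 1
#' and channel counts match), in `"deploy"` mode a single biased 3x3
#' convolution, and in `"baseline"` mode a plain 3x3 convolution with
#' neither bias nor normalization. Channel attention (if configured) and
#' ReLU follow each layer; the head is global average pooling plus one
#' linear layer.
#'
#' @param config a [TLCNConfig-class].
#' @param seed optional integer seed for the weight initialization.
#' @param inChannels input channel count (3 for RGB tiles).
#' @return A [TLCNModel-class].
#' @export
#' @examples
#' m <- buildModel(tlcnConfig(attention = "gct", mode = "deploy"), seed = 1)
#' countParams(m)
buildModel <- function(config, seed = NULL, inChannels = 3L) {
  if (!is(config, "TLCNConfig")) .config_error("config must be a TLCNConfig")
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) .config_error(paste(v, collapse = "; "))
  build <- function() {
    specs <- .layer_specs(config, as.integer(inChannels))
    layers <- lapply(specs, function(sp) {
      att <- .att_init(config, sp$cout)
      if (config@mode == "train") {
        list(type = "ecm", stride = sp$stride, cin = sp$cin, cout = sp$cout,
             b3 = list(K = .kernel_init(3L, sp$cin, sp$cout),
                       bn = .bn_new(sp$cout)),
             b1 = list(K = .kernel_init(1L, sp$cin, sp$cout),
                       bn = .bn_new(sp$cout)),
             bid = if (sp$stride == 1L && sp$cin == sp$cout)
                     .bn_new(sp$cout) else NULL,
             att = att)
      } else if (config@mode == "deploy") {
        list(type = "conv", stride = sp$stride, cin = sp$cin,
             cout = sp$cout, K = .kernel_init(3L, sp$cin, sp$cout),
             b = rep(0, sp$cout), att = att)
      } else {
        list(type = "plain", stride = sp$stride, cin = sp$cin,
             cout = sp$cout, K = .kernel_init(3L, sp$cin, sp$cout),
             att = att)
      }
    })
    Cw <- config@stageWidths[5L]
    head <- list(W = matrix(rnorm(config@nClasses * Cw, sd = sqrt(1 / Cw)),
                            config@nClasses, Cw),
                 b = rep(0, config@nClasses))
    labels <- if (config@nClasses == 6L) her2Classes()
              else paste0("class", seq_len(config@nClasses))
    new("TLCNModel", config = config, layers = layers, head = head,
        classLabels = labels)
  }
  if (is.null(seed)) build() else .with_seed(seed, build())
}

#' Count learnable parameters
#'
#' Enumerates every learnable array of a model and sums their lengths:
#' convolution kernels; convolution biases (deploy mode); batch-norm
#' scale and shift (train mode; running statistics are not learnable and
#' are not counted); attention parameters; head weights and bias.
#'
#' @param model a [TLCNModel-class].
#' @return Integer number of learnable scalars.
#' @export
setGeneric("countParams", function(model) standardGeneric("countParams"))

#' @rdname countParams
#' @export
setMethod("countParams", "TLCNModel", function(model) {
  n_att <- function(att) {
    if (is.null(att)) return(0L)
    if (att$kind == "gct") {
      length(att$alpha) + length(att$beta) + length(att$gamma)
    } else {
      length(att$W1) + length(att$b1) + length(att$W2) + length(att$b2)
    }
  }
  n <- 0L
  for (layer in model@layers) {
    n <- n + switch(layer$type,
      ecm = length(layer$b3$K) + length(layer$b3$bn$gamma) +
            length(layer$b3$bn$beta) +
            length(layer$b1$K) + length(layer$b1$bn$gamma) +
            length(layer$b1$bn$beta) +
            (if (is.null(layer$bid)) 0L
             else length(layer$bid$gamma) + length(layer$bid$beta)),
      conv = length(layer$K) + length(layer$b),
      plain = length(layer$K)
    )
    n <- n + n_att(layer$att)
  }
  n + length(model@head$W) + length(model@head$b)
})

# Fixed input scaling: images arrive in [0, 1]; the network consumes
# them centered on zero ([-1, 1]), in both training and deployment, so
# re-parameterization equivalence is unaffected.
.center_input <- function(x) .ch_affine(x, 2, -1)

#' Run the classifier forward
#'
#' Inference-mode forward pass: multi-branch blocks use their running
#' batch-norm statistics, so the output is a deterministic function of
#' the weights and the input. Inputs in `[0, 1]` are mapped to
#' `[-1, 1]` by a fixed affine transform before the first convolution.
#'
#' @param model a [TLCNModel-class].
#' @param x input array of dim (H, W, 3, N); H and W must survive five
#'   stride-2 layers (multiples of 32 are safe; tiles are 256 x 256).
#' @return Matrix of un-normalized logits, N x nClasses.
#' @export
modelForward <- function(model, x) {
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 4L) .shape_error("input must be (H, W, C, N)")
  x <- .center_input(x)
  for (layer in model@layers) {
    x <- .layer_fwd(layer, x, training = FALSE)$y
  }
  r <- .head_fwd(model@head, x)
  colnames(r$logits) <- model@classLabels
  r$logits
}
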