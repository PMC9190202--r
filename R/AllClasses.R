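#' Architecture configuration for the tile classifier
#'
#' Pins the network whose parameter accounting the package reproduces:
#' five stages of 3x3 convolutions, the first layer of each stage with
#' stride 2, optional channel attention after every convolution, global
#' average pooling and one linear head.
#'
#' @slot stageDepths integer(5), number of conv layers per stage.
#' @slot stageWidths integer(5), output channels per stage.
#' @slot nClasses number of output classes.
#' @slot attention one of `"none"`, `"gct"`, `"se"`.
#' @slot mode `"train"` (multi-branch blocks with batch norm),
#'   `"deploy"` (fused plain 3x3 convolutions with bias), or
#'   `"baseline"` (plain chain with neither bias nor normalization).
#' @slot seReduction bottleneck reduction of the SE attention.
#'
#' @export
setClass("TLCNConfig",
  representation(
    stageDepths = "integer",
    stageWidths = "integer",
    nClasses    = "integer",
    attention   = "character",
    mode        = "character",
    seReduction = "integer"
  )
)

setValidity("TLCNConfig", function(object) {
  msg <- character()
  if (length(object@stageDepths) != 5L || length(object@stageWidths) != 5L)
    msg <- c(msg, "stageDepths and stageWidths must both have length 5")
  if (any(object@stageDepths < 1L)) msg <- c(msg, "stage depths must be >= 1")
  if (any(object@stageWidths < 1L)) msg <- c(msg, "stage widths must be >= 1")
  if (length(object@nClasses) != 1L || object@nClasses < 1L)
    msg <- c(msg, "nClasses must be a positive integer")
  if (!object@attention %in% c("none", "gct", "se"))
    msg <- c(msg, "attention must be one of 'none', 'gct', 'se'")
  if (!object@mode %in% c("train", "deploy", "baseline"))
    msg <- c(msg, "mode must be one of 'train', 'deploy', 'baseline'")
  if (object@attention == "se") {
    if (object@seReduction < 1L)
      msg <- c(msg, "seReduction must be a positive integer")
    else if (any(object@stageWidths %% object@seReduction != 0L))
      msg <- c(msg, "every stage width must be divisible by seReduction")
  }
  if (length(msg)) msg else TRUE
})

#' Create a tile-classifier configuration
#'
#' Defaults pin the architecture used throughout: depths
#' `c(1, 2, 4, 14, 1)` (22 convolution layers), widths
#' `c(48, 48, 96, 192, 1280)`, six classes.
#'
#' @param stageDepths integer(5) conv layers per stage.
#' @param stageWidths integer(5) output channels per stage.
#' @param nClasses number of classes (6: 0, 1+, 2+, 3+, normal, noise).
#' @param attention `"none"`, `"gct"` or `"se"`.
#' @param mode `"train"`, `"deploy"` or `"baseline"`.
#' @param seReduction SE bottleneck reduction (default 16).
#' @return A [TLCNConfig-class] object.
#' @export
#' @examples
#' cfg <- tlcnConfig(attention = "gct", mode = "deploy")
#' cfg
tlcnConfig <- function(stageDepths = c(1L, 2L, 4L, 14L, 1L),
                       stageWidths = c(48L, 48L, 96L, 192L, 1280L),
                       nClasses = 6L,
                       attention = c("gct", "se", "none"),
                       mode = c("train", "deploy", "baseline"),
                       seReduction = 16L) {
  attention <- match.arg(attention)
  mode <- match.arg(mode)
  bad <- function(x) any(!is.finite(x)) || any(x != as.integer(x)) || any(x < 1)
  if (length(nClasses) != 1L || bad(nClasses))
    .config_error("nClasses must be a positive integer")
  if (bad(stageDepths) || bad(stageWidths))
    .config_error("stage depths and widths must be positive integers")
  tryCatch(
    new("TLCNConfig",
        stageDepths = as.integer(stageDepths),
        stageWidths = as.integer(stageWidths),
        nClasses    = as.integer(nClasses),
        attention   = attention,
        mode        = mode,
        seReduction = as.integer(seReduction)),
    error = function(e) .config_error(conditionMessage(e))
  )
}

setMethod("show", "TLCNConfig", function(object) {
  cat("TLCNConfig:", sum(object@stageDepths), "conv layers,",
      "widths", paste(object@stageWidths, collapse = "/"),
      "\n  attention:", object@attention,
      " mode:", object@mode,
      " classes:", object@nClasses, "\n")
})

#' Tile-level classification network
#'
#' Holds the layer parameters (multi-branch blocks in train mode, fused
#' plain convolutions in deploy mode), the linear head and the class
#' vocabulary.
#'
#' @slot config the [TLCNConfig-class] the model was built from.
#' @slot layers list of per-layer parameter lists.
#' @slot head list with linear head weight `W` and bias `b`.
#' @slot classLabels character vector of class names in logit order.
#' @export
setClass("TLCNModel",
  representation(
    config      = "TLCNConfig",
    layers      = "list",
    head        = "list",
    classLabels = "character"
  )
)

setMethod("show", "TLCNModel", function(object) {
  cat("TLCNModel (", object@config@mode, " mode, attention=",
      object@config@attention, ")\n", sep = "")
  cat("  ", length(object@layers), " conv layers, ",
      format(countParams(object), big.mark = ","),
      " learnable parameters\n", sep = "")
  cat("  classes:", paste(object@classLabels, collapse = ", "), "\n")
})

#' Tile-class proportion vector of one slide
#'
#' Proportions of the four scored classes (0, 1+, 2+, 3+) among the
#' tiles of a slide that were predicted as one of those classes; normal
#' and noise tiles are excluded from both numerator and denominator.
#'
#' @slot p numeric(4), proportions in class order 0, 1+, 2+, 3+.
#' @slot nTumorTiles number of tiles predicted as a scored class.
#' @slot nTotalTiles total tiles in the slide.
#' @export
setClass("CategoryVector",
  representation(p = "numeric", nTumorTiles = "integer",
                 nTotalTiles = "integer")
)

setValidity("CategoryVector", function(object) {
  msg <- character()
  if (length(object@p) != 4L) msg <- c(msg, "p must have length 4")
  if (any(object@p < 0)) msg <- c(msg, "proportions must be non-negative")
  if (object@nTumorTiles > 0L && abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CategoryVector", function(object) {
  cat("CategoryVector (", object@nTumorTiles, " tumor /",
      object@nTotalTiles, "total tiles )\n")
  print(stats::setNames(round(object@p, 4), her2TumorClasses()))
})

#' Scored slide record
#'
#' @slot slideId slide identifier.
#' @slot tilePredictions data.frame with one row per tile: `row`, `col`,
#'   `class` and the six class probabilities.
#' @slot categoryVector the [CategoryVector-class], or NULL when the
#'   slide has no tumor tiles.
#' @slot trueScore reference HER2 score if known (`NA` otherwise).
#' @slot score4 predicted 4-class score (0/1+/2+/3+; `NA` if unscorable).
#' @slot score3 predicted 3-class group, always the Table-style merge of
#'   `score4`, never predicted independently.
#' @slot scorable FALSE when no tile was predicted as a tumor class.
#' @export
setClass("SlideRecord",
  representation(
    slideId        = "character",
    tilePredictions = "data.frame",
    categoryVector = "ANY",
    trueScore      = "character",
    score4         = "character",
    score3         = "character",
    scorable       = "logical"
  )
)

setMethod("show", "SlideRecord", function(object) {
  cat("SlideRecord", object@slideId, "-",
      nrow(object@tilePredictions), "tiles\n")
  if (object@scorable) {
    cat("  HER2 score:", object@score4, "(", object@score3, ")\n")
    print(object@categoryVector)
  } else {
    cat("  unscorable: no tiles predicted as tumor classes\n")
  }
  if (!is.na(object@trueScore))
    cat("  reference score:", object@trueScore, "\n")
})

#' In-memory tile dataset
#'
#' @slot images list of 256 x 256 x 3 arrays in `[0, 1]`.
#' @slot labels factor over the six tile classes.
#' @slot slideId source slide of each tile.
#' @slot split factor with levels train/val/test.
#' @export
setClass("TileSet",
  representation(images = "list", labels = "factor",
                 slideId = "character", split = "factor")
)

setValidity("TileSet", function(object) {
  msg <- character()
  n <- length(object@images)
  if (length(object@labels) != n || length(object@slideId) != n ||
      length(object@split) != n)
    msg <- c(msg, "images, labels, slideId and split must align")
  if (!all(levels(object@labels) %in% her2Classes()))
    msg <- c(msg, "labels must come from the six-class vocabulary")
  ok <- vapply(object@images, function(im) {
    is.array(im) && length(dim(im)) == 3L &&
      all(dim(im) == c(256L, 256L, 3L))
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "every tile must be a 256 x 256 x 3 array")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TileSet", function(object) {
  cat("TileSet:", length(object@images), "tiles\n")
  print(table(label = object@labels, split = object@split))
})

#' Slide-level HER2 score predictor
#'
#' Wraps either a fitted polynomial-kernel SVM or a small MLP mapping a
#' 4-dimensional [CategoryVector-class] to a HER2 score.
#'
#' @slot scheme `"svm"` or `"mlp"`.
#' @slot fit the fitted model object.
#' @slot levels score levels (0, 1+, 2+, 3+).
#' @slot config hyper-parameters used at fit time.
#' @export
setClass("WHSPNModel",
  representation(scheme = "character", fit = "ANY",
                 levels = "character", config = "list")
)

setMethod("show", "WHSPNModel", function(object) {
  cat("WHSPNModel (", object@scheme, ")\n", sep = "")
  cat("  scores:", paste(object@levels, collapse = ", "), "\n")
})
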