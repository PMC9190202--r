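# Tile-level classifier: training (SGD with momentum, cosine decay,
# cross-entropy), prediction with fixed tie-breaking, Monte-Carlo
# cross-validation, and checkpoint I/O.

#' Training configuration for the tile classifier
#'
#' Defaults follow the reference regime: SGD, initial learning rate
#' 0.1, weight decay 0.001, batch size 256, 200 epochs, cross-entropy
#' loss; momentum 0.9 and cosine decay to zero are the usual companions
#' of that optimizer family.
#'
#' @param lr initial learning rate.
#' @param weightDecay L2 penalty on convolution and linear weights.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param momentum SGD momentum.
#' @param seed integer seed controlling initialization and shuffling.
#' @return List of class `trainConfig`.
#' @export
trainConfig <- function(lr = 0.1, weightDecay = 0.001, batchSize = 256L,
                        epochs = 200L, momentum = 0.9, seed = 1L) {
  vals <- c(lr = lr, weightDecay = weightDecay, batchSize = batchSize,
            epochs = epochs)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .config_error("lr, weightDecay, batchSize and epochs must be positive")
  }
  structure(list(lr = lr, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

.check_tileset <- function(dataset) {
  if (!is(dataset, "TileSet")) .data_error("dataset must be a TileSet")
  v <- validObject(dataset, test = TRUE)
  if (!isTRUE(v)) .data_error(paste(v, collapse = "; "))
}

# Forward the whole stack once, keeping inputs and caches for backward.
.model_fwd_train <- function(model, x) {
  x <- .center_input(x)
  inputs <- vector("list", length(model@layers))
  caches <- vector("list", length(model@layers))
  stats <- vector("list", length(model@layers))
  for (i in seq_along(model@layers)) {
    inputs[[i]] <- x
    r <- .layer_fwd(model@layers[[i]], x, training = TRUE)
    caches[[i]] <- r$cache
    stats[[i]] <- r$stats
    x <- r$y
  }
  hr <- .head_fwd(model@head, x)
  list(logits = hr$logits, inputs = inputs, caches = caches,
       stats = stats, headCache = hr$cache)
}

.model_bwd <- function(model, fw, dlogits) {
  hb <- .head_bwd(model@head, fw$headCache, dlogits)
  gy <- hb$gy
  lg <- vector("list", length(model@layers))
  for (i in rev(seq_along(model@layers))) {
    r <- .layer_bwd(model@layers[[i]], fw$inputs[[i]], fw$caches[[i]], gy,
                    need_gx = i > 1L)
    lg[[i]] <- r$grads
    gy <- r$gx
  }
  list(layers = lg, head = hb$grads)
}

# Apply updated BN running statistics collected during a forward pass.
.apply_bn_stats <- function(model, stats) {
  for (i in seq_along(stats)) {
    st <- stats[[i]]
    if (is.null(st)) next
    if (!is.null(st$b3)) {
      model@layers[[i]]$b3$bn$mean <- st$b3$mean
      model@layers[[i]]$b3$bn$var <- st$b3$var
    }
    if (!is.null(st$b1)) {
      model@layers[[i]]$b1$bn$mean <- st$b1$mean
      model@layers[[i]]$b1$bn$var <- st$b1$var
    }
    if (!is.null(st$bid)) {
      model@layers[[i]]$bid$mean <- st$bid$mean
      model@layers[[i]]$bid$var <- st$bid$var
    }
  }
  model
}

.eval_accuracy <- function(model, images, labels, batchSize = 32L) {
  pred <- predictTiles(model, images, batchSize = batchSize)
  mean(pred$class == as.character(labels))
}

#' Train the tile classifier
#'
#' Minimizes softmax cross-entropy with SGD (momentum, weight decay on
#' convolution/linear weights, cosine learning-rate decay to zero).
#' The returned model is the checkpoint with the best validation
#' accuracy; the per-epoch log records training loss and validation
#' accuracy. Runs are reproducible given `config$seed`.
#'
#' @param dataset a [TileSet-class]; the train split must contain every
#'   class, tiles must be 256 x 256 (or at least of one common size).
#' @param modelConfig a train- or baseline-mode [TLCNConfig-class].
#' @param config a [trainConfig()].
#' @param verbose print per-epoch progress.
#' @return List with `model` (best checkpoint), `log` (data.frame with
#'   epoch, lr, loss, valAccuracy), `bestEpoch` and `config`.
#' @export
trainTLCN <- function(dataset, modelConfig, config = trainConfig(),
                      verbose = FALSE) {
  .check_tileset(dataset)
  if (modelConfig@mode == "deploy") {
    .config_error("training a fused deploy model is not supported")
  }
  classes <- her2Classes()[seq_len(modelConfig@nClasses)]
  tr <- which(dataset@split == "train")
  va <- which(dataset@split == "val")
  if (length(tr) == 0L) .data_error("train split is empty")
  trLab <- as.character(dataset@labels[tr])
  missing <- setdiff(classes, unique(trLab))
  if (length(missing)) {
    .data_error(paste("classes absent from the training split:",
                      paste(missing, collapse = ", ")))
  }
  seeds <- .child_seeds(config$seed, 2L)
  model <- buildModel(modelConfig, seed = seeds[1L])
  yIdx <- match(trLab, classes)
  nTr <- length(tr)
  vel <- NULL
  log <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                    valAccuracy = numeric())
  best <- list(model = model, acc = -Inf, epoch = 0L)
  .with_seed(seeds[2L], {
    for (epoch in seq_len(config$epochs)) {
      lrE <- config$lr * 0.5 * (1 + cos(pi * (epoch - 1) / config$epochs))
      ord <- sample(nTr)
      nBatch <- ceiling(nTr / config$batchSize)
      epochLoss <- 0
      for (b in seq_len(nBatch)) {
        idx <- ord[((b - 1L) * config$batchSize + 1L):
                     min(b * config$batchSize, nTr)]
        x <- .stack_tiles(dataset@images[tr[idx]])
        fw <- .model_fwd_train(model, x)
        model <- .apply_bn_stats(model, fw$stats)
        ls <- .ce_loss(fw$logits, yIdx[idx])
        if (!is.finite(ls$loss)) .numeric_error("training loss diverged")
        epochLoss <- epochLoss + ls$loss * length(idx)
        g <- .model_bwd(model, fw, ls$dlogits)
        upL <- .sgd_step(model@layers, g$layers,
                         if (is.null(vel)) NULL else vel$layers,
                         lrE, config$momentum, config$weightDecay)
        upH <- .sgd_step(model@head, g$head,
                         if (is.null(vel)) NULL else vel$head,
                         lrE, config$momentum, config$weightDecay)
        model@layers <- upL$p
        model@head <- upH$p
        vel <- list(layers = upL$v, head = upH$v)
      }
      accV <- if (length(va)) {
        .eval_accuracy(model, dataset@images[va], dataset@labels[va])
      } else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, lr = lrE,
                                   loss = epochLoss / nTr,
                                   valAccuracy = accV))
      if (verbose) {
        message(sprintf("epoch %3d  lr %.4f  loss %.4f  val acc %s",
                        epoch, lrE, epochLoss / nTr,
                        ifelse(is.na(accV), "-", sprintf("%.3f", accV))))
      }
      track <- if (is.na(accV)) -log$loss[epoch] else accV
      if (track > best$acc) best <- list(model = model, acc = track,
                                         epoch = epoch)
    }
  })
  list(model = best$model, log = log, bestEpoch = best$epoch,
       config = config)
}

#' Predict tile classes and probabilities
#'
#' Softmax over the logits; the class call is the argmax with ties
#' broken toward the lowest class index in the canonical order
#' (0, 1+, 2+, 3+, normal, noise).
#'
#' @param model an inference-ready [TLCNModel-class] (train mode with
#'   populated statistics, or fused).
#' @param tiles a [TileSet-class], a list of H x W x 3 arrays, or one
#'   array.
#' @param batchSize tiles per forward batch.
#' @return data.frame with `class` and one probability column per class.
#' @export
predictTiles <- function(model, tiles, batchSize = 32L) {
  if (is(tiles, "TileSet")) tiles <- tiles@images
  if (is.array(tiles) && length(dim(tiles)) == 3L) tiles <- list(tiles)
  n <- length(tiles)
  probs <- matrix(NA_real_, n, length(model@classLabels))
  for (b in seq_len(ceiling(n / batchSize))) {
    idx <- ((b - 1L) * batchSize + 1L):min(b * batchSize, n)
    x <- .stack_tiles(tiles[idx])
    probs[idx, ] <- .softmax_rows(modelForward(model, x))
  }
  cls <- model@classLabels[apply(probs, 1L, which.max)]
  out <- data.frame(class = cls)
  colnames(probs) <- paste0("p_", model@classLabels)
  cbind(out, as.data.frame(probs))
}

#' Monte-Carlo cross-validation of the tile classifier
#'
#' Each round draws an independent random 8:1:1 train/val/test split at
#' tile level, trains from scratch, and evaluates on that round's test
#' split. Reports the per-metric mean and population standard deviation
#' over rounds.
#'
#' @param dataset a [TileSet-class] (its stored split is ignored; splits
#'   are redrawn each round).
#' @param modelConfig a train-mode [TLCNConfig-class].
#' @param config a [trainConfig()]; `config$seed` is the master seed
#'   from which the per-round seeds derive.
#' @param nRounds number of rounds (>= 1).
#' @return List with `summary` (data.frame of metric, mean, sd),
#'   `rounds` (per-round macro metrics plus overall accuracy) and
#'   `nRounds`.
#' @export
mcCrossValidate <- function(dataset, modelConfig, config = trainConfig(),
                            nRounds = 5L) {
  .check_tileset(dataset)
  nRounds <- as.integer(nRounds)
  if (is.na(nRounds) || nRounds < 1L) .config_error("nRounds must be >= 1")
  n <- length(dataset@images)
  seeds <- .child_seeds(config$seed, 2L * nRounds)
  rounds <- NULL
  for (r in seq_len(nRounds)) {
    splt <- .with_seed(seeds[r], {
      parts <- rep("test", n)
      ord <- sample(n)
      ntr <- floor(0.8 * n); nva <- floor(0.1 * n)
      parts[ord[seq_len(ntr)]] <- "train"
      parts[ord[ntr + seq_len(nva)]] <- "val"
      parts
    })
    ds <- new("TileSet", images = dataset@images, labels = dataset@labels,
              slideId = dataset@slideId,
              split = factor(splt, levels = c("train", "val", "test")))
    cfgR <- config
    cfgR$seed <- seeds[nRounds + r]
    fit <- trainTLCN(ds, modelConfig, cfgR)
    te <- which(ds@split == "test")
    pred <- predictTiles(fit$model, ds@images[te])
    cm <- confusionMatrix(as.character(ds@labels[te]), pred$class,
                          classOrder = fit$model@classLabels)
    met <- computeMetrics(cm)
    rounds <- rbind(rounds,
                    data.frame(round = r, t(met$macro),
                               overallAccuracy = met$overallAccuracy))
  }
  metrics <- setdiff(names(rounds), "round")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(rounds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) {
      v <- rounds[[m]]
      sqrt(mean((v - mean(v))^2))       # population sd
    }, numeric(1)),
    row.names = NULL
  )
  list(summary = summary, rounds = rounds, nRounds = nRounds)
}

#' Save / load a tile-classifier checkpoint
#'
#' Writes the weights as an RDS file plus a JSON sidecar recording the
#' architecture (depths, widths, attention, mode, class order).
#'
#' @param model a [TLCNModel-class].
#' @param path checkpoint path (`.rds`; the sidecar adds `.json`).
#' @return `path`, invisibly.
#' @export
saveTLCN <- function(model, path) {
  saveRDS(model, path)
  cfg <- model@config
  sidecar <- list(
    class = "TLCNModel",
    stageDepths = cfg@stageDepths, stageWidths = cfg@stageWidths,
    nClasses = cfg@nClasses, attention = cfg@attention, mode = cfg@mode,
    seReduction = cfg@seReduction, classLabels = model@classLabels,
    params = countParams(model)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveTLCN
#' @export
readTLCN <- function(path) {
  model <- readRDS(path)
  if (!is(model, "TLCNModel")) .data_error("not a TLCNModel checkpoint")
  model
}
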