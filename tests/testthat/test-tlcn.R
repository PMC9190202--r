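tinyTrainSetup <- function(nPerClass = 6, widths = c(2, 2, 4, 4, 8),
                           epochs = 2, batch = 18, seed = 51) {
  list(ds = generateDataset(nPerClass, seed = 52),
       mcfg = tlcnConfig(stageDepths = c(1, 1, 1, 1, 1),
                         stageWidths = widths, attention = "none",
                         mode = "train"),
       tcfg = trainConfig(lr = 0.05, batchSize = batch, epochs = epochs,
                          seed = seed))
}

test_that("training rejects malformed datasets and configs", {
  s <- tinyTrainSetup()
  expect_error(trainTLCN("not a tileset", s$mcfg, s$tcfg),
               class = "her2_data_error")
  # a class missing from the train split is a data error
  ds <- s$ds
  drop <- which(ds@labels == "noise" & ds@split == "train")
  ds@split[drop] <- "test"
  expect_error(trainTLCN(ds, s$mcfg, s$tcfg), class = "her2_data_error")
  expect_error(trainTLCN(s$ds, tlcnConfig(mode = "deploy"), s$tcfg),
               class = "her2_config_error")
  expect_error(trainConfig(epochs = 0), class = "her2_config_error")
})

test_that("training is reproducible and tracks the best checkpoint", {
  s <- tinyTrainSetup()
  f1 <- trainTLCN(s$ds, s$mcfg, s$tcfg)
  f2 <- trainTLCN(s$ds, s$mcfg, s$tcfg)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$log$valAccuracy, f2$log$valAccuracy)
  expect_true(all(is.finite(f1$log$loss)))
  # the returned checkpoint is never beaten by any logged epoch
  expect_equal(f1$log$valAccuracy[f1$bestEpoch],
               max(f1$log$valAccuracy))
  # the cosine schedule starts at the configured rate and decays
  expect_equal(f1$log$lr[1], s$tcfg$lr)
  expect_true(all(diff(f1$log$lr) < 0))
})

test_that("tile predictions are normalized with a fixed tie-break", {
  cfg <- smallConfig("none", "deploy")
  m <- buildModel(cfg, seed = 53)
  for (i in seq_along(m@layers)) m@layers[[i]]$K[] <- 0
  m@head$W[] <- 0
  m@head$b <- rep(0, 6)
  tiles <- replicate(3, array(runif(64 * 64 * 3), c(64, 64, 3)),
                     simplify = FALSE)
  pred <- predictTiles(m, tiles)
  # all-equal logits resolve to the lowest class index: "0"
  expect_true(all(pred$class == "0"))
  probs <- as.matrix(pred[, -1])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
})

test_that("fused and unfused models call every tile identically", {
  m <- randomizeModel(buildModel(smallConfig("gct", "train"), seed = 54),
                      seed = 54)
  d <- reparameterizeModel(m)
  tiles <- replicate(20, array(runif(64 * 64 * 3), c(64, 64, 3)),
                     simplify = FALSE)
  p1 <- predictTiles(m, tiles)
  p2 <- predictTiles(d, tiles)
  expect_identical(p1$class, p2$class)
  expect_lt(max(abs(as.matrix(p1[, -1]) - as.matrix(p2[, -1]))), 1e-4)
})

test_that("Monte-Carlo cross-validation aggregates over random splits", {
  s <- tinyTrainSetup(nPerClass = 5, epochs = 1, batch = 24)
  expect_error(mcCrossValidate(s$ds, s$mcfg, s$tcfg, nRounds = 0),
               class = "her2_config_error")
  r1 <- suppressWarnings(mcCrossValidate(s$ds, s$mcfg, s$tcfg, nRounds = 1))
  expect_true(all(r1$summary$sd == 0))
  r2 <- suppressWarnings(mcCrossValidate(s$ds, s$mcfg, s$tcfg, nRounds = 2))
  r2b <- suppressWarnings(mcCrossValidate(s$ds, s$mcfg, s$tcfg, nRounds = 2))
  expect_identical(r2$summary, r2b$summary)
  expect_equal(nrow(r2$rounds), 2L)
  expect_true(all(c("accuracy", "precision", "recall", "specificity",
                    "f1", "overallAccuracy") %in% r2$summary$metric))
  expect_true(all(r2$summary$sd >= 0))
})

test_that("checkpoints round-trip through disk with their sidecar", {
  m <- buildModel(smallConfig("se", "train"), seed = 55)
  p <- tempfile(fileext = ".rds")
  saveTLCN(m, p)
  m2 <- readTLCN(p)
  x <- randomInput(32, 32, 1, seed = 56)
  expect_identical(modelForward(m, x), modelForward(m2, x))
  sc <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(sc$attention, "se")
  expect_equal(sc$params, countParams(m))
})
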