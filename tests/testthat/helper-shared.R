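# Memoized heavyweight fixtures, trained once per test session and
# reused across files.

.shared_fixtures <- new.env(parent = emptyenv())

# The scaled-down study configuration: 600 synthetic tiles (100 per
# class), reduced widths, 15 epochs, batch 32, seed 7.
scaledStudy <- function() {
  if (is.null(.shared_fixtures$scaled)) {
    ds <- generateDataset(100, seed = 11)
    mcfg <- tlcnConfig(stageDepths = c(2, 2, 2, 2, 1),
                       stageWidths = c(8, 8, 16, 32, 64),
                       attention = "gct", mode = "train")
    fit <- trainTLCN(ds, mcfg,
                     trainConfig(lr = 0.1, batchSize = 32L, epochs = 15L,
                                 seed = 7L))
    .shared_fixtures$scaled <- list(fit = fit, dataset = ds,
                                    fused = reparameterizeModel(fit$model))
  }
  .shared_fixtures$scaled
}

# A slide scorer trained on rule-labeled synthetic proportion vectors.
scaledScorer <- function(scheme = "svm") {
  key <- paste0("whspn_", scheme)
  if (is.null(.shared_fixtures[[key]])) {
    d <- generateCategoryVectors(220, seed = 21)
    .shared_fixtures[[key]] <-
      trainWHSPN(d, d$label, whspnConfig(scheme, seed = 5))
  }
  .shared_fixtures[[key]]
}
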