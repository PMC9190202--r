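test_that("tile generation is deterministic under the seed", {
  a <- generateTile("2+", seed = 42)
  b <- generateTile("2+", seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generateTile("2+", seed = 43)))
  expect_equal(dim(a), c(256L, 256L, 3L))
  expect_true(all(a >= 0 & a <= 1))
  expect_error(generateTile("4+", seed = 1), class = "her2_config_error")
})

test_that("mean DAB-proxy intensity orders the scored classes", {
  cls <- her2TumorClasses()
  means <- vapply(cls, function(cl) {
    mean(vapply(1:12, function(i) dabProxy(generateTile(cl, seed = 100 + i)),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))       # 0 < 1+ < 2+ < 3+
  # matched seeds: a 0 tile is always fainter than its 1+ counterpart
  for (s in 1:5) {
    expect_lt(dabProxy(generateTile("0", seed = s)),
              dabProxy(generateTile("1+", seed = s)))
  }
})

test_that("a threshold oracle separates the four scored classes", {
  cls <- her2TumorClasses()
  score <- function(cl, seeds) {
    vapply(seeds, function(s) {
      log10(dabProxy(generateTile(cl, seed = s)) + 1e-5)
    }, numeric(1))
  }
  trainS <- 200 + 1:40
  testS <- 300 + 1:60
  mu <- vapply(cls, function(cl) mean(score(cl, trainS)), numeric(1))
  truth <- rep(1:4, each = length(testS))
  vals <- unlist(lapply(cls, score, seeds = testS))
  pred <- vapply(vals, function(v) which.min(abs(v - mu)), integer(1))
  expect_gte(mean(pred == truth), 0.95)
})

test_that("balanced datasets split 8:1:1 and reproduce under a seed", {
  ds <- generateDataset(10, seed = 44)
  expect_length(ds@images, 60L)
  expect_true(all(table(ds@labels) == 10))
  expect_equal(unname(table(ds@split)), array(c(48L, 6L, 6L)))
  per_class <- table(ds@labels, ds@split)
  expect_true(all(per_class[, "train"] == 8))
  ds2 <- generateDataset(10, seed = 44)
  expect_identical(ds@images, ds2@images)
  expect_identical(ds@split, ds2@split)
  ds3 <- generateDataset(10, seed = 45)
  expect_false(identical(ds@images[[1]], ds3@images[[1]]))
  expect_error(generateDataset(0, seed = 1), class = "her2_config_error")
})

test_that("slide ground truth follows the >10% tumor-tile rule", {
  expect_equal(her2RuleScore(c(0, 0, 0, 1)), "3+")
  expect_equal(her2RuleScore(c(0.95, 0, 0, 0.05)), "0")
  expect_equal(her2RuleScore(c(0.5, 0.39, 0.11, 0)), "2+")
  expect_equal(her2RuleScore(c(0.89, 0.11, 0, 0)), "1+")
  expect_error(her2RuleScore(c(0.5, 0.5)), class = "her2_data_error")

  sl <- generateSlide(4, 5, c("3+" = 0.5, normal = 0.5), seed = 46)
  expect_equal(sl$score, "3+")
  # tumor tiles here are the 0 and 3+ tiles; 3+ stays at 5% of them
  sl2 <- generateSlide(4, 5, c("0" = 0.95, "3+" = 0.05), seed = 47)
  expect_equal(sl2$score, "0")
  sl3 <- generateSlide(2, 2, c(normal = 1), seed = 48)
  expect_true(is.na(sl3$score))
  expect_error(generateSlide(2, 2, c("0" = 0.4, "3+" = 0.4), seed = 1),
               class = "her2_config_error")
})

test_that("tiling a composite slide recovers its tiles exactly", {
  sl <- generateSlide(2, 3, c("2+" = 0.5, "0" = 0.3, noise = 0.2),
                      seed = 49)
  grid <- tileSlide(sl$image)
  expect_length(grid@tiles, 6L)
  for (k in seq_along(grid@tiles)) {
    expect_identical(grid@tiles[[k]]$image, sl$tiles[[k]])
  }
  # stored mixture proportions respect the requested counts
  expect_equal(sum(sl$tileLabels == "2+"), 3)
  expect_equal(sum(sl$tileLabels == "0"), 2)
})

test_that("rule-labeled category vectors are balanced and consistent", {
  d <- generateCategoryVectors(40, seed = 50)
  expect_equal(nrow(d), 40L)
  expect_true(all(abs(rowSums(d[, 1:4]) - 1) < 1e-9))
  expect_true(all(table(d$label) == 10))
  relabel <- apply(as.matrix(d[, 1:4]), 1, her2RuleScore)
  expect_identical(unname(relabel), d$label)
  expect_identical(d, generateCategoryVectors(40, seed = 50))
})
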