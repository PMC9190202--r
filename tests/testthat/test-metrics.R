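test_that("confusion matrix counts and is order-invariant", {
  yt <- c("0", "0", "1+", "2+", "2+", "3+")
  yp <- c("0", "1+", "1+", "2+", "3+", "3+")
  cm <- confusionMatrix(yt, yp, classOrder = her2TumorClasses())
  expect_equal(sum(diag(cm)), 4)
  expect_equal(rowSums(cm), c("0" = 2, "1+" = 1, "2+" = 2, "3+" = 1))
  set.seed(23)
  ord <- sample(length(yt))
  expect_identical(confusionMatrix(yt[ord], yp[ord],
                                   classOrder = her2TumorClasses()), cm)
  expect_identical(confusionMatrix(yt, yt,
                                   classOrder = her2TumorClasses()),
                   diag(c(2L, 1L, 2L, 1L)) |>
                     `dimnames<-`(list(true = her2TumorClasses(),
                                       predicted = her2TumorClasses())))
  expect_error(confusionMatrix(c("0", "4+"), c("0", "0"),
                               classOrder = her2TumorClasses()),
               class = "her2_data_error")
})

test_that("the five metrics match the hand-computed example", {
  counts <- data.frame(class = "pos", TP = 3, FP = 1, TN = 5, FN = 1)
  m <- computeMetrics(counts)$perClass
  expect_equal(m$accuracy, 0.8, tolerance = 1e-12)
  expect_equal(m$precision, 0.75, tolerance = 1e-12)
  expect_equal(m$recall, 0.75, tolerance = 1e-12)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-12)
  expect_equal(m$f1, 0.75, tolerance = 1e-12)
})

test_that("a perfect classifier scores 1 on every metric", {
  cm <- diag(c(5L, 3L, 4L))
  dimnames(cm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  m <- computeMetrics(cm)
  expect_true(all(abs(as.matrix(m$perClass[, -1]) - 1) < 1e-12))
  expect_equal(unname(m$macro), rep(1, 5))
  expect_equal(m$overallAccuracy, 1)
})

test_that("zero denominators yield 0 with a warning, never NaN", {
  counts <- data.frame(class = "pos", TP = 0, FP = 0, TN = 5, FN = 2)
  expect_warning(expect_warning(m <- computeMetrics(counts), "precision"),
                 "F1")
  expect_equal(m$perClass$precision, 0)
  expect_false(any(is.nan(unlist(m$perClass[, -1]))))
  expect_error(computeMetrics(data.frame(class = "x", TP = -1, FP = 0,
                                         TN = 0, FN = 0)),
               class = "her2_data_error")
})

test_that("per-class metrics stay in [0,1] with F1 between P and R", {
  set.seed(24)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    cm <- matrix(rpois(k * k, 4), k)
    dimnames(cm) <- list(paste0("c", 1:k), paste0("c", 1:k))
    m <- suppressWarnings(computeMetrics(cm))$perClass
    vals <- as.matrix(m[, -1])
    expect_true(all(vals >= 0 & vals <= 1))
    ok <- m$precision > 0 & m$recall > 0
    expect_true(all(m$f1[ok] <= pmax(m$precision, m$recall)[ok] + 1e-12))
    expect_true(all(m$f1[ok] >= pmin(m$precision, m$recall)[ok] - 1e-12))
  }
})

test_that("score merging follows the clinical three-group map", {
  expect_equal(mergeClasses(c("0", "1+", "2+", "3+")),
               c("Negative", "Negative", "Equivocal", "Positive"))
  expect_equal(mergeClasses(character()), character())
  expect_equal(mergeClasses(c("normal", "noise")), c("normal", "noise"))
  expect_error(mergeClasses(c("0", "4+")), class = "her2_data_error")
})

test_that("merging 0 and 1+ never decreases accuracy", {
  set.seed(25)
  for (i in 1:25) {
    n <- 60
    yt <- sample(her2TumorClasses(), n, replace = TRUE)
    yp <- ifelse(runif(n) < 0.6, yt,
                 sample(her2TumorClasses(), n, replace = TRUE))
    acc4 <- mean(yt == yp)
    acc3 <- mean(mergeClasses(yt) == mergeClasses(yp))
    expect_gte(acc3, acc4)
  }
  # merging a diagonal 4-class matrix stays diagonal in 3 classes
  yt <- rep(her2TumorClasses(), 3)
  cm3 <- confusionMatrix(mergeClasses(yt), mergeClasses(yt),
                         classOrder = her2Groups())
  expect_equal(sum(cm3) - sum(diag(cm3)), 0)
})
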