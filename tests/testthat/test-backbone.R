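test_that("configuration validation rejects degenerate settings", {
  expect_error(tlcnConfig(nClasses = 0), class = "her2_config_error")
  expect_error(tlcnConfig(stageDepths = c(1, 2, 3)),
               class = "her2_config_error")
  expect_error(tlcnConfig(stageWidths = c(48, 48, 96, 192, 1281),
                          attention = "se"),
               class = "her2_config_error")
  expect_error(buildModel("not a config"), class = "her2_config_error")
})

test_that("layer count equals the sum of stage depths", {
  m <- buildModel(tlcnConfig(attention = "gct", mode = "deploy"), seed = 1)
  expect_length(m@layers, 22L)
  m2 <- buildModel(smallConfig(depths = c(2, 1, 3, 1, 1)), seed = 1)
  expect_length(m2@layers, 8L)
})

test_that("parameter accounting matches the closed form in every mode", {
  for (mode in c("train", "deploy", "baseline")) {
    for (att in c("none", "gct", "se")) {
      cfg <- smallConfig(att, mode, widths = c(4, 8, 8, 16, 16))
      m <- buildModel(cfg, seed = 1)
      expect_identical(
        countParams(m),
        as.integer(closedFormParams(cfg@stageDepths, cfg@stageWidths,
                                    6, att, mode, r = 4)),
        info = paste(mode, att))
    }
  }
  # non-uniform depths exercise the identity-branch eligibility rule
  cfg <- smallConfig("gct", "train", depths = c(1, 2, 4, 3, 1),
                     widths = c(4, 4, 8, 8, 16))
  expect_identical(countParams(buildModel(cfg, seed = 1)),
                   as.integer(closedFormParams(cfg@stageDepths,
                                               cfg@stageWidths, 6,
                                               "gct", "train", r = 4)))
})

test_that("the default architecture reproduces the published counts", {
  variants <- list(
    list(att = "gct", mode = "deploy", n = 7049558L),
    list(att = "gct", mode = "train", n = 7849142L),
    list(att = "none", mode = "train", n = 7835654L),
    list(att = "none", mode = "deploy", n = 7036070L),
    list(att = "se", mode = "deploy", n = 7315631L),
    list(att = "none", mode = "baseline", n = 7031574L),
    list(att = "gct", mode = "baseline", n = 7045062L)
  )
  for (v in variants) {
    m <- buildModel(tlcnConfig(attention = v$att, mode = v$mode), seed = 1)
    expect_identical(countParams(m), v$n, info = paste(v$att, v$mode))
    expect_identical(
      countParams(m),
      as.integer(closedFormParams(c(1, 2, 4, 14, 1),
                                  c(48, 48, 96, 192, 1280), 6,
                                  v$att, v$mode)),
      info = paste("closed form", v$att, v$mode))
  }
})

test_that("gct is an exact identity at initialization", {
  x <- randomInput(8, 8, 2, seed = 4)
  p <- list(alpha = rep(1, 3), beta = rep(0, 3), gamma = rep(0, 3),
            eps = 1e-5)
  expect_identical(gctForward(x, p), x)
  # zero embedding also passes the signal through (gate = 1 + tanh(beta))
  p0 <- list(alpha = rep(0, 3), beta = rep(0, 3), gamma = rnorm(3),
             eps = 1e-5)
  expect_equal(gctForward(x, p0), x, tolerance = 1e-12)
})

test_that("gct gate matches the hand-evaluated single-channel case", {
  # C = 1, alpha = 1, gamma = 1, beta = 0: shat = s/sqrt(s^2) = 1, so
  # the gate is 1 + tanh(1) up to the epsilon guard
  x <- randomInput(6, 6, 1, seed = 5)[, , 1, , drop = FALSE]
  p <- list(alpha = 1, beta = 0, gamma = 1, eps = 1e-12)
  y <- gctForward(x, p)
  expect_equal(y / x, array(1 + tanh(1), dim(x)), tolerance = 1e-6)
})

test_that("gct rejects channel mismatch", {
  x <- randomInput(8, 8, 1, seed = 6)
  p <- list(alpha = rep(1, 5), beta = rep(0, 5), gamma = rep(0, 5),
            eps = 1e-5)
  expect_error(gctForward(x, p), class = "her2_shape_error")
})

test_that("se gates are strictly inside (0, 1)", {
  set.seed(7)
  C <- 8
  x <- randomInput(8, 8, 2, seed = 7)
  x <- array(rnorm(8 * 8 * C * 2), c(8, 8, C, 2))
  p <- list(kind = "se",
            W1 = matrix(rnorm(2 * C), 2, C), b1 = rnorm(2),
            W2 = matrix(rnorm(C * 2), C, 2), b2 = rnorm(C), r = 4)
  y <- seForward(x, p)
  gate <- y / x
  expect_true(all(gate > 0 & gate < 1))
  # all-zero parameters give the sigmoid midpoint: out = x / 2
  p0 <- list(kind = "se", W1 = matrix(0, 2, C), b1 = rep(0, 2),
             W2 = matrix(0, C, 2), b2 = rep(0, C), r = 4)
  expect_equal(seForward(x, p0), x * 0.5, tolerance = 1e-14)
  expect_error(seForward(randomInput(8, 8, 1, seed = 1), p),
               class = "her2_shape_error")
})

test_that("se parameter count follows the bottleneck arithmetic", {
  cfg <- tlcnConfig(stageDepths = c(1, 1, 1, 1, 1),
                    stageWidths = rep(64L, 5), attention = "se",
                    mode = "deploy", seReduction = 16L)
  m <- buildModel(cfg, seed = 1)
  att <- m@layers[[1]]$att
  n <- length(att$W1) + length(att$b1) + length(att$W2) + length(att$b2)
  expect_identical(n, 2L * 64L * 4L + 4L + 64L)   # 580
})

test_that("a 256px tile reaches an 8x8 map after five stride-2 stages", {
  m <- buildModel(smallConfig("none", "deploy"), seed = 11)
  x <- array(runif(256 * 256 * 3), c(256, 256, 3, 1))
  for (layer in m@layers) x <- her2quant:::.layer_fwd(layer, x)$y
  expect_equal(dim(x), c(8L, 8L, 16L, 1L))
})

test_that("forward pass honors the shape and zero-weight contracts", {
  cfg <- smallConfig("gct", "deploy")
  m <- buildModel(cfg, seed = 8)
  for (i in seq_along(m@layers)) m@layers[[i]]$K[] <- 0
  m@head$W[] <- 0
  m@head$b <- rnorm(6)
  x <- array(0, c(64, 64, 3, 2))
  lg <- modelForward(m, x)
  expect_equal(dim(lg), c(2L, 6L))
  expect_equal(unname(lg), matrix(m@head$b, 2, 6, byrow = TRUE),
               tolerance = 1e-12)
  # deterministic given fixed weights and input
  m2 <- buildModel(cfg, seed = 9)
  x <- randomInput(64, 64, 2, seed = 10)
  expect_identical(modelForward(m2, x), modelForward(m2, x))
  expect_error(modelForward(m2, array(0, c(64, 64, 4, 1))),
               class = "her2_shape_error")
})
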