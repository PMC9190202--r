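# Fusion algebra: every primitive is checked against a direct
# composition oracle (convolve then normalize, at double precision).

conv_ref <- function(x, K, b = NULL, stride = 1, pad = 1) {
  her2quant:::.conv_fwd(x, K, b, stride, pad)
}

test_that("conv+BN fusion reproduces the identity and scalar cases", {
  K <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  idbn <- list(gamma = rep(1, 4), beta = rep(0, 4), mean = rep(0, 4),
               var = rep(1, 4))
  f <- fuseConvBN(K, NULL, idbn, eps = 0)
  expect_equal(f$K, K)
  expect_equal(f$b, rep(0, 4))
  # scalar: K=1, b=0, mu=0.5, sigma=2, gamma=3, beta=1
  f2 <- fuseConvBN(array(1, c(1, 1, 1, 1)), 0,
                   list(gamma = 3, beta = 1, mean = 0.5, var = 4), eps = 0)
  expect_equal(as.numeric(f2$K), 1.5)
  expect_equal(f2$b, 0.25)
  expect_error(fuseConvBN(K, NULL, list(gamma = 1, beta = 0, mean = 0,
                                        var = rep(-1, 4))),
               class = "her2_numeric_error")
})

test_that("fused conv equals BN-after-conv for random branches", {
  set.seed(11)
  for (rep in 1:5) {
    K <- array(rnorm(3 * 3 * 3 * 5), c(3, 3, 3, 5))
    bias <- rnorm(5)
    bn <- list(gamma = rnorm(5), beta = rnorm(5), mean = rnorm(5),
               var = runif(5, 0.2, 3))
    x <- array(rnorm(10 * 10 * 3 * 2), c(10, 10, 3, 2))
    composed <- bnReference(conv_ref(x, K, bias), bn)
    f <- fuseConvBN(K, bias, bn)
    fused <- conv_ref(x, f$K, f$b)
    expect_lt(max(abs(fused - composed)), 1e-9)
  }
})

test_that("1x1 kernels embed at the 3x3 center and convolve identically", {
  K1 <- array(rnorm(1 * 1 * 3 * 4), c(1, 1, 3, 4))
  K3 <- pad1x1To3x3(K1)
  expect_equal(dim(K3), c(3L, 3L, 3L, 4L))
  expect_equal(K3[2, 2, , ], K1[1, 1, , ])
  K3[2, 2, , ] <- 0
  expect_true(all(K3 == 0))
  # convolution oracle: padded kernel at pad 1 == 1x1 kernel at pad 0
  x <- randomInput(9, 9, 2, seed = 12)
  expect_lt(max(abs(conv_ref(x, pad1x1To3x3(K1), NULL, 1, 1) -
                    conv_ref(x, K1, NULL, 1, 0))), 1e-12)
  expect_equal(pad1x1To3x3(array(0, c(1, 1, 2, 2))),
               array(0, c(3, 3, 2, 2)))
  expect_error(pad1x1To3x3(array(0, c(3, 3, 2, 2))),
               class = "her2_shape_error")
})

test_that("the Dirac kernel realizes the identity convolution", {
  K <- identityTo3x3(2)
  expect_equal(K[2, 2, , ], diag(2))
  expect_equal(sum(K != 0), 2L)
  expect_equal(identityTo3x3(1)[, , 1, 1],
               matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3))
  x <- array(rnorm(9 * 9 * 5), c(9, 9, 5, 1))
  expect_equal(conv_ref(x, identityTo3x3(5), NULL, 1, 1), x)
  expect_error(identityTo3x3(0), class = "her2_config_error")
})

test_that("branch merging is the linearity of convolution", {
  set.seed(13)
  mk <- function() list(K = array(rnorm(3 * 3 * 3 * 3), c(3, 3, 3, 3)),
                        b = rnorm(3))
  b1 <- mk()
  expect_equal(mergeBranches(list(b1)), b1)
  neg <- list(K = -b1$K, b = -b1$b)
  z <- mergeBranches(list(b1, neg))
  expect_true(all(z$K == 0) && all(z$b == 0))
  b2 <- mk(); b3 <- mk()
  m <- mergeBranches(list(b1, b2, b3))
  x <- randomInput(8, 8, 2, seed = 14)
  lhs <- conv_ref(x, m$K, m$b)
  rhs <- conv_ref(x, b1$K, b1$b) + conv_ref(x, b2$K, b2$b) +
    conv_ref(x, b3$K, b3$b)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  b4 <- list(K = array(0, c(3, 3, 3, 5)), b = rnorm(5))
  expect_error(mergeBranches(list(b1, b4)), class = "her2_shape_error")
})

test_that("block fusion reduces to the 3x3 branch when others vanish", {
  m <- randomizeModel(buildModel(smallConfig("none", "train"), seed = 15),
                      seed = 15)
  L <- m@layers[[3]]                      # a stride-2 block: no identity
  expect_null(L$bid)
  L$b1$K[] <- 0
  L$b1$bn$mean <- rep(0, L$cout)
  L$b1$bn$beta <- rep(0, L$cout)
  f <- reparameterizeBlock(L)
  ref <- fuseConvBN(L$b3$K, NULL, L$b3$bn)
  expect_equal(f$K, ref$K)
  expect_equal(f$b, ref$b)
})

test_that("fused blocks match the multi-branch forward exactly", {
  for (att in c("none", "gct", "se")) {
    m <- randomizeModel(buildModel(smallConfig(att, "train"), seed = 16),
                        seed = 16 + match(att, c("none", "gct", "se")))
    d <- reparameterizeModel(m)
    for (i in seq_along(m@layers)) {
      cin <- m@layers[[i]]$cin
      x <- array(rnorm(12 * 12 * cin * 2), c(12, 12, cin, 2))
      y1 <- her2quant:::.layer_fwd(m@layers[[i]], x)$y
      y2 <- her2quant:::.layer_fwd(d@layers[[i]], x)$y
      expect_lt(max(abs(y1 - y2)), 1e-9)
    }
  }
})

test_that("model fusion preserves logits and shrinks the model", {
  for (att in c("none", "gct", "se")) {
    m <- randomizeModel(buildModel(smallConfig(att, "train"), seed = 17),
                        seed = 20 + match(att, c("none", "gct", "se")))
    d <- reparameterizeModel(m)
    x <- randomInput(64, 64, 2, seed = 18)
    expect_lt(max(abs(modelForward(m, x) - modelForward(d, x))), 1e-9)
    expect_lt(countParams(d), countParams(m))
    expect_error(reparameterizeModel(d), class = "her2_state_error")
  }
})

test_that("fusing a zero-weight model yields the head bias everywhere", {
  m <- buildModel(smallConfig("none", "train"), seed = 19)
  for (i in seq_along(m@layers)) {
    L <- m@layers[[i]]
    L$b3$K[] <- 0; L$b1$K[] <- 0
    L$b3$bn$gamma <- rep(0, L$cout); L$b1$bn$gamma <- rep(0, L$cout)
    if (!is.null(L$bid)) L$bid$gamma <- rep(0, L$cout)
    m@layers[[i]] <- L
  }
  m@head$W[] <- 0
  m@head$b <- rnorm(6)
  d <- reparameterizeModel(m)
  expect_true(all(vapply(d@layers, function(l) all(l$K == 0), logical(1))))
  lg <- modelForward(d, randomInput(32, 32, 1, seed = 20))
  expect_equal(unname(lg)[1, ], m@head$b, tolerance = 1e-12)
})

test_that("deployment is idempotent across save and reload", {
  m <- randomizeModel(buildModel(smallConfig("gct", "train"), seed = 21),
                      seed = 21)
  d <- reparameterizeModel(m)
  p <- tempfile(fileext = ".rds")
  saveTLCN(d, p)
  d2 <- readTLCN(p)
  x <- randomInput(32, 32, 2, seed = 22)
  expect_identical(modelForward(d, x), modelForward(d2, x))
  expect_true(file.exists(paste0(p, ".json")))
})
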