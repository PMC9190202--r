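# Shared fixtures: small architectures, randomized models with
# populated batch-norm statistics, and an independent closed-form
# parameter-count oracle (pure arithmetic, no package internals).

smallConfig <- function(attention = "none", mode = "train",
                        depths = c(1, 1, 1, 1, 1),
                        widths = c(4, 4, 8, 8, 16), r = 4L) {
  tlcnConfig(stageDepths = depths, stageWidths = widths,
             attention = attention, mode = mode, seReduction = r)
}

# Give a model non-trivial weights and batch-norm statistics so that
# fusion tests exercise the full algebra (not the identity-stats case).
randomizeModel <- function(model, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    rbn <- function(bn) {
      n <- length(bn$gamma)
      list(gamma = rnorm(n, sd = 1), beta = rnorm(n, sd = 0.5),
           mean = rnorm(n, sd = 0.5), var = runif(n, 0.2, 3))
    }
    for (i in seq_along(model@layers)) {
      L <- model@layers[[i]]
      if (L$type == "ecm") {
        L$b3$K[] <- rnorm(length(L$b3$K), sd = 0.3)
        L$b1$K[] <- rnorm(length(L$b1$K), sd = 0.3)
        L$b3$bn <- rbn(L$b3$bn)
        L$b1$bn <- rbn(L$b1$bn)
        if (!is.null(L$bid)) L$bid <- rbn(L$bid)
      } else {
        L$K[] <- rnorm(length(L$K), sd = 0.3)
        if (!is.null(L$b)) L$b <- rnorm(length(L$b), sd = 0.3)
      }
      if (!is.null(L$att) && L$att$kind == "gct") {
        L$att$alpha <- rnorm(length(L$att$alpha), 1, 0.3)
        L$att$beta <- rnorm(length(L$att$beta), sd = 0.3)
        L$att$gamma <- rnorm(length(L$att$gamma), sd = 0.3)
      }
      model@layers[[i]] <- L
    }
    model@head$W[] <- rnorm(length(model@head$W), sd = 0.3)
    model@head$b <- rnorm(length(model@head$b), sd = 0.3)
    model
  })
}

# Independent oracle: closed-form learnable-parameter count from the
# architecture arithmetic alone.
closedFormParams <- function(depths, widths, nClasses = 6, attention = "none",
                             mode = "deploy", r = 16, cin0 = 3) {
  total <- 0
  cin <- cin0
  for (s in seq_along(depths)) {
    for (i in seq_len(depths[s])) {
      cout <- widths[s]
      stride1 <- i > 1            # first layer of each stage has stride 2
      if (mode == "deploy") {
        total <- total + cout * cin * 9 + cout
      } else if (mode == "baseline") {
        total <- total + cout * cin * 9
      } else {                    # train: 3x3+BN, 1x1+BN, identity BN
        total <- total + cout * cin * 9 + 2 * cout
        total <- total + cout * cin * 1 + 2 * cout
        if (stride1 && cin == cout) total <- total + 2 * cout
      }
      if (attention == "gct") total <- total + 3 * cout
      if (attention == "se") {
        cr <- cout / r
        total <- total + 2 * cout * cr + cr + cout
      }
      cin <- cout
    }
  }
  total + widths[5] * nClasses + nClasses
}

randomInput <- function(h = 32, w = 32, n = 2, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3 * n), c(h, w, 3, n))
}

# Inference-mode batch norm applied directly from stored parameters —
# the reference composition for fusion oracles.
bnReference <- function(x, bn, eps = 1e-5) {
  d <- dim(x)
  s <- bn$gamma / sqrt(bn$var + eps)
  x * rep(s, each = d[1] * d[2]) +
    rep(bn$beta - bn$mean * s, each = d[1] * d[2])
}
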