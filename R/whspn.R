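# Slide-level HER2 score prediction from category vectors: either a
# polynomial-kernel SVM (gamma 10, cost 2, degree 3) or a four-layer
# MLP (widths 4-32-16-8-4, ReLU after the hidden layers, softmax
# output).

#' Configuration of the slide-level scorer
#'
#' @param scheme `"svm"` or `"mlp"`.
#' @param gamma,cost,degree,coef0 polynomial-kernel SVM parameters
#'   (defaults gamma 10, cost 2, degree 3, coef0 0).
#' @param hidden MLP hidden-layer widths.
#' @param lr,epochs,momentum MLP full-batch SGD parameters.
#' @param seed seed for the MLP initialization (the SVM fit is
#'   deterministic).
#' @return List of class `whspnConfig`.
#' @importFrom e1071 svm
#' @export
whspnConfig <- function(scheme = c("svm", "mlp"), gamma = 10, cost = 2,
                        degree = 3L, coef0 = 0,
                        hidden = c(32L, 16L, 8L), lr = 0.03,
                        epochs = 500L, momentum = 0.9, seed = 1L) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, gamma = gamma, cost = cost,
                 degree = as.integer(degree), coef0 = coef0,
                 hidden = as.integer(hidden), lr = lr,
                 epochs = as.integer(epochs), momentum = momentum,
                 seed = as.integer(seed)),
            class = "whspnConfig")
}

.as_vector_matrix <- function(vectors) {
  if (is(vectors, "CategoryVector")) {
    return(matrix(vectors@p, 1L, 4L,
                  dimnames = list(NULL, c("p0", "p1", "p2", "p3"))))
  }
  if (is.list(vectors) && !is.data.frame(vectors) &&
      all(vapply(vectors, is, logical(1), "CategoryVector"))) {
    return(do.call(rbind, lapply(vectors, function(v) v@p)))
  }
  if (is.data.frame(vectors)) {
    cols <- c("p0", "p1", "p2", "p3")
    if (!all(cols %in% names(vectors))) {
      .data_error("data.frame vectors need columns p0, p1, p2, p3")
    }
    return(as.matrix(vectors[, cols]))
  }
  if (is.numeric(vectors) && is.null(dim(vectors))) {
    return(matrix(vectors, 1L))
  }
  as.matrix(vectors)
}

.check_vectors <- function(X) {
  if (ncol(X) != 4L) .data_error("category vectors must have 4 columns")
  bad <- abs(rowSums(X) - 1) > 1e-6
  if (any(bad)) {
    .data_error(sprintf(
      "%d category vector(s) do not sum to 1 (max deviation %.3g)",
      sum(bad), max(abs(rowSums(X) - 1))))
  }
  invisible(X)
}

.mlp_init <- function(widths) {
  lapply(seq_len(length(widths) - 1L), function(i) {
    list(W = matrix(rnorm(widths[i + 1L] * widths[i],
                          sd = sqrt(2 / widths[i])),
                    widths[i + 1L], widths[i]),
         b = rep(0, widths[i + 1L]))
  })
}

.mlp_fwd <- function(layers, X) {
  # X: n x 4; hidden activations ReLU, output linear (softmax in loss)
  a <- t(X)
  acts <- list(a)
  for (i in seq_along(layers)) {
    z <- layers[[i]]$W %*% a + layers[[i]]$b
    a <- if (i < length(layers)) .relu(z) else z
    acts[[i + 1L]] <- a
  }
  list(logits = t(a), acts = acts)
}

.mlp_train <- function(X, yIdx, cfg) {
  nCls <- 4L
  widths <- c(4L, cfg$hidden, nCls)
  .with_seed(cfg$seed, {
    layers <- .mlp_init(widths)
    vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
    n <- nrow(X)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- .mlp_fwd(layers, X)
      ls <- .ce_loss(fw$logits, yIdx)
      delta <- t(ls$dlogits)                 # nCls x n
      for (i in rev(seq_along(layers))) {
        gW <- delta %*% t(fw$acts[[i]])
        gb <- rowSums(delta)
        if (i > 1L) {
          delta <- crossprod(layers[[i]]$W, delta) * (fw$acts[[i]] > 0)
        }
        vel[[i]]$W <- cfg$momentum * vel[[i]]$W + gW
        vel[[i]]$b <- cfg$momentum * vel[[i]]$b + gb
        layers[[i]]$W <- layers[[i]]$W - cfg$lr * vel[[i]]$W
        layers[[i]]$b <- layers[[i]]$b - cfg$lr * vel[[i]]$b
      }
    }
    layers
  })
}

#' Train the slide-level HER2 scorer
#'
#' @param vectors category vectors: a matrix/data.frame with columns
#'   p0..p3, or a list of [CategoryVector-class] objects.
#' @param labels HER2 scores (0, 1+, 2+, 3+), one per vector; all four
#'   classes must be present.
#' @param config a [whspnConfig()].
#' @return A [WHSPNModel-class].
#' @export
#' @examples
#' d <- generateCategoryVectors(40, seed = 1)
#' m <- trainWHSPN(d, d$label, whspnConfig("svm"))
#' predictWHSPN(m, c(0, 0, 0, 1))
trainWHSPN <- function(vectors, labels, config = whspnConfig()) {
  X <- .check_vectors(.as_vector_matrix(vectors))
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) {
    .data_error("labels must align with vectors")
  }
  lev <- her2TumorClasses()
  if (!all(labels %in% lev)) {
    .data_error("labels must be HER2 scores 0, 1+, 2+, 3+")
  }
  missing <- setdiff(lev, unique(labels))
  if (length(missing)) {
    .data_error(paste("classes absent from training labels:",
                      paste(missing, collapse = ", ")))
  }
  y <- factor(labels, levels = lev)
  fit <- if (config$scheme == "svm") {
    e1071::svm(x = X, y = y, kernel = "polynomial", gamma = config$gamma,
               cost = config$cost, degree = config$degree,
               coef0 = config$coef0, scale = FALSE)
  } else {
    .mlp_train(X, as.integer(y), config)
  }
  new("WHSPNModel", scheme = config$scheme, fit = fit, levels = lev,
      config = unclass(config))
}

#' Predict slide-level HER2 scores
#'
#' Returns the 4-class score and its 3-class clinical group; the group
#' is always derived from the 4-class score by [mergeClasses()], never
#' predicted independently. Vectors must sum to 1 (tolerance 1e-6).
#'
#' @param model a fitted [WHSPNModel-class].
#' @param vectors category vectors (see [trainWHSPN()]); a single
#'   numeric(4) is accepted.
#' @return data.frame with columns `score` and `group`.
#' @export
predictWHSPN <- function(model, vectors) {
  X <- .check_vectors(.as_vector_matrix(vectors))
  score <- if (model@scheme == "svm") {
    as.character(predict(model@fit, X))
  } else {
    lg <- .mlp_fwd(model@fit, X)$logits
    model@levels[apply(lg, 1L, which.max)]
  }
  data.frame(score = score, group = mergeClasses(score))
}

#' Save / load a slide-scorer checkpoint
#'
#' @param model a [WHSPNModel-class].
#' @param path checkpoint path (`.rds`; the sidecar adds `.json`).
#' @return `path`, invisibly.
#' @export
saveWHSPN <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(class = "WHSPNModel", scheme = model@scheme,
         levels = model@levels,
         config = model@config[setdiff(names(model@config), "hidden")],
         hidden = model@config$hidden),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveWHSPN
#' @export
readWHSPN <- function(path) {
  model <- readRDS(path)
  if (!is(model, "WHSPNModel")) .data_error("not a WHSPNModel checkpoint")
  model
}
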