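# Synthetic IHC-like tiles and composite slides. Tiles emulate the
# staining semantics of the HER2 guideline: cell-boundary rings rendered
# in DAB-like brown over an eosin-pink field, with membrane intensity
# and completeness rising with score (0 ~ unstained, 1+ faint/partial,
# 2+ moderate, 3+ strong/complete); "normal" renders small unstained
# cells and "noise" renders blank/blur/fold artifacts. Brown is drawn
# directly in RGB (no stain-unmixing model) since the classifier
# consumes RGB.

.DAB_BROWN <- c(0.45, 0.29, 0.12)
.EOSIN_PINK <- c(0.96, 0.79, 0.84)
.HEMATOXYLIN <- c(0.38, 0.30, 0.58)

# Class-conditioned staining parameters: membrane DAB intensity range
# and stained fraction of each cell boundary. Intensity ranges of the
# four scored classes are disjoint; class 0 is unstained ("no
# reactivity": gray membrane only).
.SYNTH_PARAMS <- list(
  "0"    = list(int = c(0, 0), comp = c(0, 0),
                cells = c(22L, 38L), radius = c(9, 14)),
  "1+"   = list(int = c(0.10, 0.25), comp = c(0.3, 0.6),
                cells = c(22L, 38L), radius = c(9, 14)),
  "2+"   = list(int = c(0.35, 0.55), comp = c(0.6, 0.9),
                cells = c(22L, 38L), radius = c(9, 14)),
  "3+"   = list(int = c(0.70, 0.95), comp = c(0.9, 1.0),
                cells = c(22L, 38L), radius = c(9, 14)),
  normal = list(int = c(0, 0), comp = c(0, 0),
                cells = c(10L, 18L), radius = c(5, 8))
)

# Render one cell (nucleus disc + membrane ring) into img in place.
.draw_cell <- function(img, cx, cy, r, ringAlpha, comp,
                       phase, nucleusScale = 0.45, tumor = TRUE) {
  t2 <- 1.6                      # membrane half-thickness in px
  lo_x <- max(1L, floor(cx - r - t2)); hi_x <- min(256L, ceiling(cx + r + t2))
  lo_y <- max(1L, floor(cy - r - t2)); hi_y <- min(256L, ceiling(cy + r + t2))
  xs <- lo_x:hi_x; ys <- lo_y:hi_y
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  dist <- sqrt(dx^2 + dy^2)

  # cytoplasm: slightly translucent wash inside the cell
  inside <- dist <= r - 1
  if (any(inside)) {
    idx <- which(inside, arr.ind = TRUE)
    pix <- cbind(xs[idx[, 1L]], ys[idx[, 2L]])
    for (ch in 1:3) {
      cyto <- if (tumor) c(0.90, 0.70, 0.80) else c(0.93, 0.78, 0.84)
      img[cbind(pix, ch)] <- 0.6 * img[cbind(pix, ch)] + 0.4 * cyto[ch]
    }
  }
  # nucleus
  nuc <- dist <= r * nucleusScale
  if (any(nuc)) {
    idx <- which(nuc, arr.ind = TRUE)
    pix <- cbind(xs[idx[, 1L]], ys[idx[, 2L]])
    nc <- if (tumor) .HEMATOXYLIN * 0.85 else .HEMATOXYLIN
    for (ch in 1:3) {
      img[cbind(pix, ch)] <- 0.25 * img[cbind(pix, ch)] + 0.75 * nc[ch]
    }
  }
  # membrane: tumor cells carry a faint gray-blue outline (visible even
  # with zero DAB), overlaid by a brown arc of fraction `comp` at
  # intensity `ringAlpha`
  ring <- abs(dist - r) <= t2
  if (any(ring) && tumor) {
    idx <- which(ring, arr.ind = TRUE)
    pix <- cbind(xs[idx[, 1L]], ys[idx[, 2L]])
    # neutral gray: visible, but without the R>G>B hue of DAB
    for (ch in 1:3) {
      img[cbind(pix, ch)] <- 0.6 * img[cbind(pix, ch)] + 0.4 * 0.70
    }
  }
  if (any(ring) && comp > 0 && ringAlpha > 0.01) {
    ang <- (atan2(dy, dx) - phase) %% (2 * pi)
    arc <- ring & (ang <= comp * 2 * pi)
    if (any(arc)) {
      idx <- which(arc, arr.ind = TRUE)
      pix <- cbind(xs[idx[, 1L]], ys[idx[, 2L]])
      feather <- 1 - abs(dist[arc] - r) / (t2 + 0.5)
      a <- ringAlpha * pmin(1, pmax(0, feather * 1.6))
      for (ch in 1:3) {
        img[cbind(pix, ch)] <- img[cbind(pix, ch)] * (1 - a) +
          .DAB_BROWN[ch] * a
      }
    }
  }
  img
}

.noise_tile <- function() {
  kind <- sample(c("blank", "blur", "fold"), 1L)
  img <- array(0, c(256L, 256L, 3L))
  if (kind == "blank") {
    level <- runif(1, 0.93, 1.0)
    for (ch in 1:3) img[, , ch] <- level + rnorm(256 * 256, sd = 0.01)
  } else if (kind == "blur") {
    # smooth low-frequency grayish wash
    gx <- seq(0, 1, length.out = 256)
    f <- outer(sin(gx * runif(1, 1, 4) * pi + runif(1, 0, pi)),
               cos(gx * runif(1, 1, 4) * pi + runif(1, 0, pi)))
    base <- runif(1, 0.6, 0.85)
    for (ch in 1:3) img[, , ch] <- base + 0.08 * f + rnorm(256 * 256, sd = 0.01)
  } else {
    # tissue fold: dark oriented streaks over pale tissue
    for (ch in 1:3) img[, , ch] <- 0.9 + rnorm(256 * 256, sd = 0.02)
    xs <- matrix(rep(1:256, 256), 256)
    ys <- t(xs)
    for (i in seq_len(sample(3:6, 1L))) {
      a <- runif(1, -1.2, 1.2); b <- runif(1, -100, 300)
      w <- runif(1, 3, 9)
      mask <- abs(ys - (a * xs + b)) < w
      dark <- runif(1, 0.15, 0.4)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- plane[mask] * dark
        img[, , ch] <- plane
      }
    }
  }
  img
}

.render_tile <- function(classLabel, nCells = NULL) {
  if (classLabel == "noise") return(.noise_tile())
  par <- .SYNTH_PARAMS[[classLabel]]
  img <- array(0, c(256L, 256L, 3L))
  for (ch in 1:3) {
    img[, , ch] <- .EOSIN_PINK[ch] + rnorm(256 * 256, sd = 0.015)
  }
  tumor <- classLabel != "normal"
  if (is.null(nCells)) nCells <- sample(par$cells[1L]:par$cells[2L], 1L)
  for (i in seq_len(nCells)) {
    cx <- runif(1, 8, 248); cy <- runif(1, 8, 248)
    r <- runif(1, par$radius[1L], par$radius[2L])
    int <- runif(1, par$int[1L], par$int[2L])
    comp <- runif(1, par$comp[1L], par$comp[2L])
    phase <- runif(1, 0, 2 * pi)
    img <- .draw_cell(img, cx, cy, r, int, comp, phase, tumor = tumor)
  }
  img
}

#' Generate one synthetic IHC-like tile
#'
#' Deterministic under `seed`: the same call yields a bit-identical
#' 8-bit-quantized image.
#'
#' @param classLabel one of the six tile classes (see [her2Classes()]).
#' @param seed integer seed.
#' @param nCells optional cell count override.
#' @return A 256 x 256 x 3 array in `[0, 1]`, quantized to 8 bits.
#' @export
#' @examples
#' img <- generateTile("3+", seed = 1)
#' dim(img)
generateTile <- function(classLabel, seed, nCells = NULL) {
  classLabel <- as.character(classLabel)
  if (!classLabel %in% her2Classes()) {
    .config_error(paste0("unknown tile class '", classLabel, "'"))
  }
  img <- .with_seed(seed, .render_tile(classLabel, nCells))
  img <- pmin(pmax(img, 0), 1)
  round(img * 255) / 255
}

#' Mean DAB-proxy staining intensity of a tile
#'
#' A scalar brown-stain score: per pixel, `R - B` gated on the brown
#' hue ordering (`R - G > 0.02` and `G - B > 0.02`), averaged over the
#' tile. Eosin pink, hematoxylin blue and neutral gray all fail the
#' gate, so the score isolates DAB-stained membrane; tile means order
#' the four scored classes.
#'
#' @param img an H x W x 3 array in `[0, 1]`.
#' @return Scalar intensity.
#' @export
dabProxy <- function(img) {
  img <- .as_rgb_array(img)
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  brown <- (r - g > 0.02) & (g - b > 0.02)
  mean((r - b) * brown)
}

#' Generate a balanced six-class tile dataset
#'
#' Produces `nPerClass` tiles per class with an 8:1:1 train/val/test
#' split drawn at tile level, plus synthetic source-slide ids.
#'
#' @param nPerClass tiles per class (>= 1).
#' @param seed master seed; everything downstream is reproducible.
#' @return A [TileSet-class].
#' @export
#' @examples
#' ds <- generateDataset(2, seed = 1)
#' table(ds@labels, ds@split)
generateDataset <- function(nPerClass, seed) {
  nPerClass <- as.integer(nPerClass)
  if (is.na(nPerClass) || nPerClass < 1L) {
    .config_error("nPerClass must be >= 1")
  }
  classes <- her2Classes()
  n <- nPerClass * length(classes)
  seeds <- .child_seeds(seed, n + length(classes))
  images <- vector("list", n)
  labels <- character(n)
  slide <- character(n)
  split <- character(n)
  i <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    ntr <- floor(0.8 * nPerClass)
    nva <- floor(0.1 * nPerClass)
    parts <- c(rep("train", ntr), rep("val", nva),
               rep("test", nPerClass - ntr - nva))
    parts <- .with_seed(seeds[n + ci], sample(parts))
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      images[[i]] <- generateTile(cl, seed = seeds[i])
      labels[i] <- cl
      slide[i] <- sprintf("synthslide%02d", 1L + (j - 1L) %% 10L)
      split[i] <- parts[j]
    }
  }
  new("TileSet", images = images,
      labels = factor(labels, levels = classes),
      slideId = slide,
      split = factor(split, levels = c("train", "val", "test")))
}

#' Slide-level HER2 score from tumor-class proportions
#'
#' The guideline rule transposed to tiles: the score is the highest
#' class among 3+, 2+, 1+ whose proportion among tumor tiles exceeds
#' 10%, and 0 otherwise.
#'
#' @param p numeric(4) proportions over (0, 1+, 2+, 3+), summing to 1.
#' @return One of "0", "1+", "2+", "3+".
#' @export
#' @examples
#' her2RuleScore(c(0.95, 0, 0, 0.05))   # "0": 3+ stays below 10%
her2RuleScore <- function(p) {
  if (length(p) != 4L || any(p < 0)) {
    .data_error("p must be 4 non-negative proportions")
  }
  if (p[4L] > 0.1) "3+" else if (p[3L] > 0.1) "2+"
  else if (p[2L] > 0.1) "1+" else "0"
}

.score_from_labels <- function(labels) {
  tumor <- labels[labels %in% her2TumorClasses()]
  if (length(tumor) == 0L) return(NA_character_)
  p <- as.numeric(table(factor(tumor, levels = her2TumorClasses()))) /
    length(tumor)
  her2RuleScore(p)
}

#' Generate a synthetic composite slide
#'
#' Builds a (gridRows*256) x (gridCols*256) RGB image out of
#' independently generated tiles whose classes follow `mixture`;
#' [tileSlide()] recovers the constituent tiles exactly. The stored
#' ground-truth score applies the >10%-of-tumor-tiles rule; a slide
#' without tumor tiles gets score `NA` (unscorable).
#'
#' @param gridRows,gridCols grid dimensions (>= 1).
#' @param mixture named numeric of tile-class proportions summing to 1.
#' @param seed master seed.
#' @return List with `image`, `score`, `tileLabels` (gridRows x
#'   gridCols character matrix), `tiles` (the constituent tile images,
#'   row-major), `gridRows`, `gridCols`.
#' @export
#' @examples
#' sl <- generateSlide(2, 2, c("3+" = 0.5, normal = 0.5), seed = 1)
#' sl$score
generateSlide <- function(gridRows, gridCols, mixture, seed) {
  gridRows <- as.integer(gridRows); gridCols <- as.integer(gridCols)
  if (gridRows < 1L || gridCols < 1L) {
    .config_error("grid dimensions must be >= 1")
  }
  if (is.null(names(mixture)) || !all(names(mixture) %in% her2Classes())) {
    .config_error("mixture must be named with tile classes")
  }
  if (abs(sum(mixture) - 1) > 1e-6) {
    .config_error("mixture proportions must sum to 1")
  }
  nt <- gridRows * gridCols
  # largest-remainder apportionment of tile counts
  raw <- mixture * nt
  cnt <- floor(raw)
  rem <- nt - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1L
  }
  labels <- rep(names(cnt), cnt)
  seeds <- .child_seeds(seed, nt + 1L)
  labels <- .with_seed(seeds[nt + 1L], sample(labels))
  img <- array(0, c(gridRows * 256L, gridCols * 256L, 3L))
  lab <- matrix(labels, gridRows, gridCols)
  tiles <- vector("list", nt)
  k <- 0L
  for (r in seq_len(gridRows)) {
    for (cc in seq_len(gridCols)) {
      k <- k + 1L
      tl <- generateTile(lab[r, cc], seed = seeds[k])
      img[(r - 1L) * 256L + 1:256, (cc - 1L) * 256L + 1:256, ] <- tl
      tiles[[k]] <- tl
    }
  }
  list(image = img, score = .score_from_labels(labels), tileLabels = lab,
       tiles = tiles, gridRows = gridRows, gridCols = gridCols)
}

#' Generate labeled category vectors under the >10% rule
#'
#' Samples 4-class proportion vectors from a flat Dirichlet, stratified
#' so the four rule-implied scores are balanced, and labels each vector
#' with [her2RuleScore()]. These emulate the tile-class proportion
#' vectors the slide scorer is trained on.
#'
#' @param n number of vectors.
#' @param seed integer seed.
#' @return data.frame with columns `p0`, `p1`, `p2`, `p3`, `label`.
#' @export
generateCategoryVectors <- function(n, seed) {
  .with_seed(seed, {
    target <- rep(her2TumorClasses(), length.out = n)
    out <- matrix(0, n, 4L)
    lab <- character(n)
    for (i in seq_len(n)) {
      repeat {
        g <- stats::rgamma(4L, shape = 1)
        p <- g / sum(g)
        if (her2RuleScore(p) == target[i]) break
      }
      out[i, ] <- p
      lab[i] <- target[i]
    }
    df <- as.data.frame(out)
    names(df) <- c("p0", "p1", "p2", "p3")
    df$label <- lab
    df
  })
}
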