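# Slide-to-tiles decomposition and aggregation of tile predictions into
# the 4-dimensional category-proportion vector, plus the end-to-end
# slide scorer.

#' Tile grid of one slide
#'
#' @slot slideId slide identifier.
#' @slot tiles list of entries with `row`, `col`, `x0`, `y0` (0-based
#'   top-left pixel origin) and `image` (256 x 256 x 3 array).
#' @slot tileSize tile edge in pixels.
#' @slot stride sliding-window stride in pixels.
#' @export
setClass("TileGrid",
  representation(slideId = "character", tiles = "list",
                 tileSize = "integer", stride = "integer")
)

setMethod("show", "TileGrid", function(object) {
  cat("TileGrid", object@slideId, "-", length(object@tiles), "tiles of",
      object@tileSize, "px (stride", object@stride, "px)\n")
})

#' Crop a slide image into a grid of tiles
#'
#' Non-overlapping sliding window by default (stride equal to tile
#' size); windows are half-open `[x0, x0 + size)` with a 0-based
#' top-left origin, and partial edge windows are dropped, so a stride
#' equal to the tile size yields `floor(H/size) * floor(W/size)` tiles.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param tileSize tile edge in pixels (default 256).
#' @param stride window stride in pixels (default `tileSize`).
#' @param slideId identifier stored in the grid.
#' @return A [TileGrid-class]; empty (with a warning) when the image is
#'   smaller than one tile.
#' @export
#' @examples
#' img <- array(0.5, c(512, 256, 3))
#' length(tileSlide(img)@tiles)   # 2
tileSlide <- function(image, tileSize = 256L, stride = tileSize,
                      slideId = "slide") {
  image <- .as_rgb_array(image)
  d <- dim(image)
  tileSize <- as.integer(tileSize)
  stride <- as.integer(stride)
  if (d[1L] < tileSize || d[2L] < tileSize) {
    warning("image smaller than one tile; returning an empty grid",
            call. = FALSE)
    return(new("TileGrid", slideId = slideId, tiles = list(),
               tileSize = tileSize, stride = stride))
  }
  nr <- (d[1L] - tileSize) %/% stride + 1L
  nc <- (d[2L] - tileSize) %/% stride + 1L
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      y0 <- (r - 1L) * stride
      x0 <- (cc - 1L) * stride
      k <- k + 1L
      tiles[[k]] <- list(row = r, col = cc, x0 = x0, y0 = y0,
                         image = image[y0 + seq_len(tileSize),
                                       x0 + seq_len(tileSize), ,
                                       drop = FALSE])
    }
  }
  new("TileGrid", slideId = slideId, tiles = tiles,
      tileSize = tileSize, stride = stride)
}

#' Aggregate tile predictions into a category vector
#'
#' Proportions of the four scored classes among tiles predicted as one
#' of them; normal and noise tiles are excluded from numerator and
#' denominator. A slide without any tumor-class tile raises a no-tumor
#' error (callers treat it as an unscorable verdict).
#'
#' @param predictions character vector of per-tile classes over the
#'   six-class vocabulary.
#' @return A [CategoryVector-class].
#' @export
#' @examples
#' aggregateTiles(c(rep("0", 1), rep("3+", 3), rep("normal", 5)))
aggregateTiles <- function(predictions) {
  predictions <- as.character(predictions)
  if (!all(predictions %in% her2Classes())) {
    .data_error("predictions outside the six-class vocabulary")
  }
  tumor <- predictions[predictions %in% her2TumorClasses()]
  if (length(tumor) == 0L) {
    .notumor_error("no tiles predicted as tumor classes; slide unscorable")
  }
  cnt <- table(factor(tumor, levels = her2TumorClasses()))
  new("CategoryVector", p = as.numeric(cnt) / length(tumor),
      nTumorTiles = length(tumor),
      nTotalTiles = length(predictions))
}

#' Score one slide end-to-end
#'
#' Pipeline: crop the slide into tiles, classify every tile, aggregate
#' the tumor-class proportions, and predict the slide-level HER2 score.
#' The record keeps the per-tile predictions and the quantitative
#' proportion vector. A slide whose tiles are all predicted
#' normal/noise yields an unscorable record, not an error.
#'
#' @param slide an H x W x 3 array, a [TileGrid-class], the list
#'   returned by [generateSlide()], or a path to a PNG/TIFF image.
#' @param tileModel an inference-ready [TLCNModel-class].
#' @param wsiModel a fitted [WHSPNModel-class].
#' @param slideId identifier for the record.
#' @param trueScore reference HER2 score, if known.
#' @return A [SlideRecord-class].
#' @export
scoreSlide <- function(slide, tileModel, wsiModel, slideId = "slide",
                       trueScore = NA_character_) {
  if (is.character(slide) && length(slide) == 1L) {
    slide <- readSlideImage(slide)
  }
  if (is.list(slide) && !is(slide, "TileGrid") && !is.null(slide$image)) {
    if (!is.na(slide$score) && is.na(trueScore)) trueScore <- slide$score
    slide <- slide$image
  }
  grid <- if (is(slide, "TileGrid")) slide else tileSlide(slide,
                                                          slideId = slideId)
  if (length(grid@tiles) == 0L) {
    .data_error("slide produced no tiles")
  }
  imgs <- lapply(grid@tiles, `[[`, "image")
  pred <- predictTiles(tileModel, imgs)
  tp <- data.frame(row = vapply(grid@tiles, `[[`, integer(1), "row"),
                   col = vapply(grid@tiles, `[[`, integer(1), "col"),
                   pred)
  cv <- tryCatch(aggregateTiles(pred$class),
                 her2_notumor_error = function(e) NULL)
  if (is.null(cv)) {
    return(new("SlideRecord", slideId = grid@slideId,
               tilePredictions = tp, categoryVector = NULL,
               trueScore = as.character(trueScore),
               score4 = NA_character_, score3 = NA_character_,
               scorable = FALSE))
  }
  sc <- predictWHSPN(wsiModel, cv)
  new("SlideRecord", slideId = grid@slideId, tilePredictions = tp,
      categoryVector = cv, trueScore = as.character(trueScore),
      score4 = sc$score, score3 = sc$group, scorable = TRUE)
}

#' Accessor for the category vector of a record
#' @param object a [SlideRecord-class].
#' @return The [CategoryVector-class], or NULL for unscorable slides.
#' @export
setGeneric("categoryVector",
           function(object) standardGeneric("categoryVector"))

#' @rdname categoryVector
#' @export
setMethod("categoryVector", "SlideRecord",
          function(object) object@categoryVector)

#' Write a slide record to JSON
#'
#' Serializes the proportion vector, tile counts and scores; tile-level
#' predictions go to a companion CSV.
#'
#' @param record a [SlideRecord-class].
#' @param path output JSON path; the per-tile CSV replaces the
#'   extension with `.tiles.csv`.
#' @return `path`, invisibly.
#' @export
writeSlideRecord <- function(record, path) {
  cv <- record@categoryVector
  out <- list(
    slide_id = record@slideId,
    scorable = record@scorable,
    score4 = record@score4,
    score3 = record@score3,
    true_score = record@trueScore,
    n_tiles = nrow(record@tilePredictions),
    n_tumor_tiles = if (is.null(cv)) 0L else cv@nTumorTiles,
    proportions = if (is.null(cv)) NULL else
      as.list(stats::setNames(cv@p, c("p0", "p1", "p2", "p3")))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  csv <- sub("\\.json$", "", path)
  write.csv(record@tilePredictions, paste0(csv, ".tiles.csv"),
            row.names = FALSE)
  invisible(path)
}
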