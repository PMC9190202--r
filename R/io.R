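# File formats: PNG/TIFF images, CSV manifests. TIFF support is
# optional (Suggests); PNG is the default interchange format.

#' Read a slide or tile image
#'
#' @param path PNG or TIFF file.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
readSlideImage <- function(path) {
  if (!file.exists(path)) .data_error(paste("no such image:", path))
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      .data_error("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  .as_rgb_array(img)
}

#' Write an image to PNG (or TIFF by extension)
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeSlideImage <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      .data_error("writing TIFF requires the 'tiff' package")
    }
    tiff::writeTIFF(img, path)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Write a tile dataset to disk
#'
#' Emits one PNG per tile plus `manifest.csv` with columns
#' `path,label,slide_id,split` (paths relative to the manifest).
#'
#' @param dataset a [TileSet-class].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeTileSet <- function(dataset, dir) {
  .check_tileset(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset@images)
  rel <- sprintf("tile_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset@images[[i]], file.path(dir, rel[i]))
  }
  manifest <- data.frame(path = rel,
                         label = as.character(dataset@labels),
                         slide_id = dataset@slideId,
                         split = as.character(dataset@split))
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a tile dataset from a manifest
#'
#' @param manifest path to a CSV with columns `path,label,slide_id,split`
#'   (image paths relative to the manifest's directory).
#' @return A [TileSet-class].
#' @export
readTileSet <- function(manifest) {
  if (!file.exists(manifest)) {
    .data_error(paste("no such manifest:", manifest))
  }
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("path", "label", "slide_id", "split")
  if (!all(need %in% names(df))) {
    .data_error("manifest needs columns path, label, slide_id, split")
  }
  base <- dirname(manifest)
  images <- lapply(df$path, function(p) readSlideImage(file.path(base, p)))
  new("TileSet", images = images,
      labels = factor(df$label, levels = her2Classes()),
      slideId = as.character(df$slide_id),
      split = factor(df$split, levels = c("train", "val", "test")))
}

#' Write a tile grid to disk
#'
#' Emits one PNG per tile plus `tiles.csv` with columns
#' `path,row,col,x0,y0`.
#'
#' @param grid a [TileGrid-class].
#' @param dir output directory.
#' @return The manifest path, invisibly.
#' @export
writeTileGrid <- function(grid, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(grid@tiles, function(tl) {
    rel <- sprintf("tile_r%03d_c%03d.png", tl$row, tl$col)
    png::writePNG(tl$image, file.path(dir, rel))
    data.frame(path = rel, row = tl$row, col = tl$col,
               x0 = tl$x0, y0 = tl$y0)
  })
  mp <- file.path(dir, "tiles.csv")
  write.csv(do.call(rbind, rows), mp, row.names = FALSE)
  invisible(mp)
}

#' Read a pre-tiled slide directory
#'
#' @param manifest path to `tiles.csv` (columns `path,row,col,x0,y0`).
#' @param slideId identifier for the grid.
#' @return A [TileGrid-class].
#' @export
readTileGrid <- function(manifest, slideId = "slide") {
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  tiles <- lapply(seq_len(nrow(df)), function(i) {
    list(row = df$row[i], col = df$col[i], x0 = df$x0[i], y0 = df$y0[i],
         image = readSlideImage(file.path(base, df$path[i])))
  })
  sz <- if (length(tiles)) dim(tiles[[1L]]$image)[1L] else 256L
  new("TileGrid", slideId = slideId, tiles = tiles,
      tileSize = as.integer(sz), stride = as.integer(sz))
}

#' Read / write category-vector tables
#'
#' CSV with columns `slide_id,p0,p1,p2,p3,label`.
#' @param path CSV file.
#' @return data.frame.
#' @export
readCategoryVectors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("p0", "p1", "p2", "p3") %in% names(df))) {
    .data_error("vector table needs columns p0, p1, p2, p3")
  }
  df
}

#' @rdname readCategoryVectors
#' @param df data.frame with columns `p0..p3` and optionally `slide_id`,
#'   `label`.
#' @export
writeCategoryVectors <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
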