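# ---- mosaic composition -----------------------------------------------------

#' Compose the mosaic from tiles and global positions
#'
#' Positions are rounded to the nearest integer pixel and tiles are pasted
#' into the output frame in row-major scan order, later tiles overwriting
#' earlier ones in overlap regions -- no blending, so stitching errors stay
#' visible as seams rather than being smoothed away. Pixels covered by no
#' tile are zero. The frame size is the tight bounding box of the placed
#' tiles.
#'
#' @param grid a `tile_grid` (see [split_image_to_grid()] or
#'   [load_tile_grid()]).
#' @param positions a `tile_positions` data.frame (`row`, `col`, `x`, `y`).
#' @param max_frame_dim guard against runaway transforms: composing fails if
#'   either frame dimension exceeds this (default 50000 pixels).
#' @return a `mosaic_result`: list with `image`, `positions` (with rounded
#'   `x`, `y` columns added), `frame_size` `(height, width)`.
#' @export
compose <- function(grid, positions, max_frame_dim = 50000L) {
  M <- grid$M
  N <- grid$N
  H <- grid$H
  W <- grid$W
  stopifnot(nrow(positions) == M * N)
  rx <- round(positions$x)
  ry <- round(positions$y)
  fw <- max(rx) + W
  fh <- max(ry) + H
  if (fw > max_frame_dim || fh > max_frame_dim) {
    stop(sprintf("mosaic frame %dx%d exceeds max_frame_dim = %d",
                 fh, fw, max_frame_dim))
  }
  img <- matrix(0, fh, fw)
  ord <- order(positions$row, positions$col)   # row-major scan order
  for (i in ord) {
    tl <- get_tile(grid, positions$row[i], positions$col[i])
    img[ry[i] + seq_len(H), rx[i] + seq_len(W)] <- tl
  }
  positions$x_px <- rx
  positions$y_px <- ry
  structure(list(image = img, positions = positions,
                 frame_size = c(fh, fw)),
            class = "mosaic_result")
}

#' @export
print.mosaic_result <- function(x, ...) {
  cat(sprintf("<mosaic_result: %dx%d frame, %d tiles>\n",
              x$frame_size[1], x$frame_size[2], nrow(x$positions)))
  invisible(x)
}

#' Write a mosaic (or any intensity matrix) as TIFF or PNG
#'
#' @param image numeric matrix in `[0, 1]`, or a `mosaic_result`.
#' @param path output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @export
write_image <- function(image, path) {
  if (inherits(image, "mosaic_result")) image <- image$image
  image[image < 0] <- 0
  image[image > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path)
  } else if (ext == "png") {
    png::writePNG(image, path)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Read an image as a grayscale intensity matrix in `[0, 1]`
#'
#' RGB images are converted to luminance (Rec. 709 weights); an alpha
#' channel, if present, is dropped.
#'
#' @param path TIFF or PNG file.
#' @return numeric matrix.
#' @export
read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path) else
    if (ext == "png") png::readPNG(path) else
      stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}
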