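# ---- evaluation metrics -----------------------------------------------------

# grid-adjacent (north and west) pairs of an MxN grid as (ref, mov) rows/cols
adjacent_pairs <- function(M, N) {
  pairs <- list()
  if (M > 1L) {
    g <- expand.grid(col = 0:(N - 1L), row = 0:(M - 2L))
    pairs[[1]] <- data.frame(r1 = g$row, c1 = g$col,
                             r2 = g$row + 1L, c2 = g$col)
  }
  if (N > 1L) {
    g <- expand.grid(col = 0:(N - 2L), row = 0:(M - 1L))
    pairs[[2]] <- data.frame(r1 = g$row, c1 = g$col,
                             r2 = g$row, c2 = g$col + 1L)
  }
  do.call(rbind, pairs)
}

#' Mean RMSE over the overlap regions of adjacent tile pairs
#'
#' Ground-truth-free stitching quality: for every grid-adjacent pair of
#' tiles, the two placed tile rectangles (positions rounded to pixels) are
#' intersected; the root-mean-square difference of the two tiles'
#' intensities over that intersection measures how well the overlap content
#' agrees. The result is the mean over pairs with a nonempty intersection.
#' Intensities are on the normalized `[0, 1]` scale. Pairs whose placed
#' rectangles do not intersect are excluded and counted (attribute
#' `n_excluded`); if no pair overlaps at all, the result is `NA` -- the
#' failure mode where adjacent tiles end up disjoint.
#'
#' @param grid a `tile_grid`.
#' @param positions a `tile_positions` data.frame.
#' @return mean overlap RMSE (or `NA`), with attributes `n_pairs` and
#'   `n_excluded`.
#' @export
overlap_rmse <- function(grid, positions) {
  M <- grid$M
  N <- grid$N
  H <- grid$H
  W <- grid$W
  pr <- adjacent_pairs(M, N)
  if (is.null(pr)) {
    return(structure(NA_real_, n_pairs = 0L, n_excluded = 0L))
  }
  key <- paste(positions$row, positions$col)
  px <- round(positions$x)[match(paste(pr$r1, pr$c1), key)]
  py <- round(positions$y)[match(paste(pr$r1, pr$c1), key)]
  qx <- round(positions$x)[match(paste(pr$r2, pr$c2), key)]
  qy <- round(positions$y)[match(paste(pr$r2, pr$c2), key)]
  vals <- numeric(0)
  n_excluded <- 0L
  for (i in seq_len(nrow(pr))) {
    x0 <- max(px[i], qx[i]); x1 <- min(px[i], qx[i]) + W - 1L
    y0 <- max(py[i], qy[i]); y1 <- min(py[i], qy[i]) + H - 1L
    if (x1 < x0 || y1 < y0) {
      n_excluded <- n_excluded + 1L
      next
    }
    a <- get_tile(grid, pr$r1[i], pr$c1[i])
    b <- get_tile(grid, pr$r2[i], pr$c2[i])
    sa <- a[(y0 - py[i] + 1L):(y1 - py[i] + 1L),
            (x0 - px[i] + 1L):(x1 - px[i] + 1L), drop = FALSE]
    sb <- b[(y0 - qy[i] + 1L):(y1 - qy[i] + 1L),
            (x0 - qx[i] + 1L):(x1 - qx[i] + 1L), drop = FALSE]
    vals <- c(vals, sqrt(mean((sa - sb)^2)))
  }
  if (!length(vals)) {
    warning("no adjacent tile pair overlaps at the computed positions")
    return(structure(NA_real_, n_pairs = nrow(pr), n_excluded = n_excluded))
  }
  structure(mean(vals), n_pairs = nrow(pr), n_excluded = n_excluded)
}

#' Mean centroid distance between stitched and ground-truth tile placements
#'
#' For each tile, the Euclidean distance between its centroid in the
#' stitched frame and in the ground-truth frame; the mean over tiles is
#' returned. Both position sets must use the same frame normalization
#' (typically both shifted so min x = min y = 0). Since all tiles share the
#' same dimensions, centroid distances equal top-left corner distances.
#'
#' @param positions,truth_positions data.frames with columns `row`, `col`,
#'   `x`, `y` covering the same tile set.
#' @return mean centroid distance in pixels.
#' @export
centroid_distance_error <- function(positions, truth_positions) {
  key_a <- paste(positions$row, positions$col)
  key_b <- paste(truth_positions$row, truth_positions$col)
  if (nrow(positions) != nrow(truth_positions) || !all(key_a %in% key_b)) {
    stop("position sets cover different tile sets")
  }
  i <- match(key_a, key_b)
  mean(sqrt((positions$x - truth_positions$x[i])^2 +
              (positions$y - truth_positions$y[i])^2))
}

#' MSE and PSNR between a stitched image and its ground truth
#'
#' When the two images differ in size they are cropped to the common
#' top-left-aligned intersection (with a warning) before comparison --
#' stitched frames can carry a few rows/columns of excess border. PSNR is
#' `10 log10(peak^2 / mse)` and is `+Inf` exactly when `mse` is zero.
#'
#' @param stitched,truth numeric intensity matrices.
#' @param peak peak intensity value (1 for normalized images, 255 for 8-bit).
#' @return list with `mse` and `psnr` (dB).
#' @export
image_mse_psnr <- function(stitched, truth, peak = 1) {
  da <- dim(stitched)
  db <- dim(truth)
  if (!all(da == db)) {
    warning(sprintf("image dimensions differ (%dx%d vs %dx%d); %s",
                    da[1], da[2], db[1], db[2],
                    "cropping to the common intersection"))
    h <- min(da[1], db[1])
    w <- min(da[2], db[2])
    if (h < 1 || w < 1) stop("images do not intersect")
    stitched <- stitched[seq_len(h), seq_len(w), drop = FALSE]
    truth <- truth[seq_len(h), seq_len(w), drop = FALSE]
  }
  mse <- mean((stitched - truth)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  list(mse = mse, psnr = psnr)
}

#' Normalize positions so the minimum x and y are zero
#' @param positions a positions data.frame with `x`, `y` columns.
#' @export
normalize_positions <- function(positions) {
  positions$x <- positions$x - min(positions$x)
  positions$y <- positions$y - min(positions$y)
  positions
}
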