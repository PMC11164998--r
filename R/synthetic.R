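# ---- tile grid container ----------------------------------------------------

#' Construct a tile grid
#'
#' @param tiles list of `M * N` intensity matrices in row-major order.
#' @param M,N grid dimensions.
#' @param overlap_fraction nominal overlap fraction between adjacent tiles.
#' @return a `tile_grid`: list with `tiles`, `M`, `N`, `H`, `W`,
#'   `overlap_fraction`.
#' @export
tile_grid <- function(tiles, M, N, overlap_fraction) {
  stopifnot(length(tiles) == M * N)
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all tiles in a grid must share the same dimensions")
  }
  structure(list(tiles = tiles, M = as.integer(M), N = as.integer(N),
                 H = dims[1, 1], W = dims[2, 1],
                 overlap_fraction = overlap_fraction),
            class = "tile_grid")
}

#' @rdname tile_grid
#' @param grid a `tile_grid`.
#' @param row,col 0-based grid indices.
#' @export
get_tile <- function(grid, row, col) {
  grid$tiles[[row * grid$N + col + 1L]]
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid: %dx%d tiles of %dx%d px, overlap %.0f%%>\n",
              x$M, x$N, x$H, x$W, 100 * x$overlap_fraction))
  invisible(x)
}

# ---- synthetic grid configuration -------------------------------------------

#' Configuration for synthetic tile-grid generation
#'
#' Describes how a ground-truthed grid is cut from a source image: grid
#' shape, tile size, overlap, per-tile integer stage jitter, a shading field
#' (simulating uncorrected fixed-pattern vignetting, applied identically to
#' every tile), additive Gaussian noise, and tiles to blank out as
#' featureless background.
#'
#' @param rows,cols grid dimensions M and N.
#' @param overlap_fraction nominal overlap fraction (default 0.30).
#' @param tile_size `(height, width)` of each tile in pixels.
#' @param jitter_px maximum per-axis uniform integer stage error (pixels).
#' @param shading `"none"`, `"gaussian-vignette"` or `"linear-gradient"`.
#' @param shading_amplitude fraction of intensity lost at the darkest point
#'   of the shading field (0.3 = corners 30% darker than center).
#' @param noise_sigma additive Gaussian noise sd on the `[0, 1]` scale.
#' @param background_tiles data.frame (`row`, `col`) of tiles replaced by
#'   constant background, or `NULL`.
#' @param pattern `"texture"` or `"usaf"` (used by convenience callers).
#' @param seed RNG seed for jitter and noise.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(rows, cols, overlap_fraction = 0.30,
                         tile_size = c(200L, 200L), jitter_px = 0L,
                         shading = c("none", "gaussian-vignette",
                                     "linear-gradient"),
                         shading_amplitude = 0, noise_sigma = 0,
                         background_tiles = NULL,
                         pattern = c("texture", "usaf"), seed = 0L) {
  shading <- match.arg(shading)
  pattern <- match.arg(pattern)
  stopifnot(rows >= 1, cols >= 1, overlap_fraction > 0, overlap_fraction < 1,
            jitter_px >= 0, shading_amplitude >= 0, shading_amplitude < 1,
            noise_sigma >= 0)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 overlap_fraction = overlap_fraction,
                 tile_size = as.integer(tile_size),
                 jitter_px = as.integer(jitter_px), shading = shading,
                 shading_amplitude = shading_amplitude,
                 noise_sigma = noise_sigma,
                 background_tiles = background_tiles,
                 pattern = pattern, seed = as.integer(seed)),
            class = "synth_config")
}

# minimum source-image size for a config (before the jitter margin)
required_source_size <- function(config) {
  H <- config$tile_size[1]
  W <- config$tile_size[2]
  step_y <- round(H * (1 - config$overlap_fraction))
  step_x <- round(W * (1 - config$overlap_fraction))
  c((config$rows - 1L) * step_y + H + 2L * config$jitter_px,
    (config$cols - 1L) * step_x + W + 2L * config$jitter_px)
}

# ---- source image generators ------------------------------------------------

#' Generate a histology-like random texture image
#'
#' Band-limited random texture: a low-frequency background wash, a mild
#' fine-grained component, and a dense scatter of small bright and dark
#' Gaussian blobs standing in for nuclei and debris. The blob density
#' (about one per 64 px^2) and contrast are chosen so a
#' determinant-of-Hessian detector at the bright-field threshold finds
#' dozens of keypoints in even a 5%-of-tile strip. Deterministic per seed.
#'
#' @param height,width image dimensions in pixels.
#' @param seed RNG seed.
#' @return intensity matrix in `[0, 1]`.
#' @export
generate_texture_image <- function(height, width, seed = 0L) {
  stopifnot(height > 0, width > 0)
  set.seed(seed)
  base <- blur_gauss(matrix(stats::runif(height * width), height, width), 6)
  base <- 0.5 + 0.8 * (base - mean(base))
  fine <- blur_gauss(matrix(stats::runif(height * width), height, width), 1)
  img <- base + 0.25 * (fine - mean(fine))

  n_blobs <- round(height * width / 64)
  bx <- sample.int(width, n_blobs, replace = TRUE)
  by <- sample.int(height, n_blobs, replace = TRUE)
  amp <- sample(c(-1, 1), n_blobs, replace = TRUE) *
    stats::runif(n_blobs, 0.5, 0.9)
  sig_class <- sample(1:3, n_blobs, replace = TRUE)
  sig_vals <- c(1.3, 1.8, 2.4)
  for (k in 1:3) {
    sel <- sig_class == k
    if (!any(sel)) next
    s <- sig_vals[k]
    delta <- matrix(0, height, width)
    idx <- cbind(by[sel], bx[sel])
    # scale deltas so each blob peaks near its drawn amplitude after blurring
    delta[idx] <- delta[idx] + amp[sel] * 2 * pi * s^2
    img <- img + blur_gauss(delta, s)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a binary resolution-target pattern
#'
#' A deterministic binary (0/1) image in the style of optical resolution
#' test slides: groups of three-bar elements at several scales plus small
#' square markers, clustered in the central region, with wide empty margins.
#' Sharp corners provide detectable features inside the cluster while the
#' margins guarantee featureless overlaps for tiles near the border --
#' exercising the invalid-link repair path of the stitching pipeline.
#'
#' @param height,width image dimensions in pixels.
#' @param margin_fraction fraction of each dimension left empty on every
#'   side (default 0.18).
#' @return binary intensity matrix with values in `{0, 1}`.
#' @export
generate_usaf_pattern <- function(height, width, margin_fraction = 0.18) {
  stopifnot(height > 0, width > 0)
  img <- matrix(0, height, width)
  draw <- function(y0, y1, x0, x1) {
    y0 <- max(1L, y0); x0 <- max(1L, x0)
    y1 <- min(height, y1); x1 <- min(width, x1)
    if (y1 >= y0 && x1 >= x0) img[y0:y1, x0:x1] <<- 1
    invisible(NULL)
  }
  my <- round(margin_fraction * height)
  mx <- round(margin_fraction * width)
  cell <- 72L
  bar_widths <- c(3L, 4L, 6L, 8L, 10L)
  yy <- seq(my + 1L, height - my - cell, by = cell)
  xx <- seq(mx + 1L, width - mx - cell, by = cell)
  k <- 0L
  for (y in yy) {
    for (x in xx) {
      k <- k + 1L
      bw <- bar_widths[(k %% length(bar_widths)) + 1L]
      len <- 5L * bw
      if (k %% 2L == 0L) {
        for (b in 0:2) {            # horizontal three-bar element
          draw(y + b * 2L * bw, y + b * 2L * bw + bw - 1L, x, x + len - 1L)
        }
      } else {
        for (b in 0:2) {            # vertical three-bar element
          draw(y, y + len - 1L, x + b * 2L * bw, x + b * 2L * bw + bw - 1L)
        }
      }
      # square marker with sharp corners, offset within the cell
      sq <- 2L * bw
      draw(y + len + 4L, y + len + 3L + sq, x + len + 4L, x + len + 3L + sq)
    }
  }
  img
}

# shading gain field shared by all tiles (fixed-pattern vignetting)
shading_field <- function(H, W, type, amplitude) {
  if (type == "none" || amplitude == 0) return(matrix(1, H, W))
  if (type == "gaussian-vignette") {
    cy <- (H - 1) / 2
    cx <- (W - 1) / 2
    sv <- 0.35 * min(H, W)
    r2 <- outer((seq_len(H) - 1 - cy)^2, (seq_len(W) - 1 - cx)^2, `+`)
    g <- exp(-r2 / (2 * sv^2))
    (1 - amplitude) + amplitude * (g - min(g)) / (max(g) - min(g))
  } else {                             # linear-gradient
    gx <- (seq_len(W) - 1) / (W - 1)
    matrix((1 - amplitude) + amplitude * gx, H, W, byrow = TRUE)
  }
}

# ---- grid splitting ---------------------------------------------------------

#' Split a source image into an overlapping tile grid with ground truth
#'
#' Cuts an M x N grid of tiles from `image` with the configured overlap.
#' Tile (r, c) is cropped at its nominal stage position
#' `(c W (1-o), r H (1-o))` plus an independent uniform integer jitter per
#' axis; the actual crop positions are returned as ground truth. After
#' cropping, the shading gain field (identical for every tile) is applied,
#' then additive Gaussian noise; tiles listed in `background_tiles` are
#' replaced by the image's median background level before noise.
#'
#' @param image source intensity matrix in `[0, 1]`.
#' @param config a [synth_config()].
#' @return list with `grid` (a `tile_grid`) and `truth` (data.frame `row`,
#'   `col`, `x`, `y` of the actual crop positions in the source frame).
#' @export
split_image_to_grid <- function(image, config) {
  M <- config$rows
  N <- config$cols
  H <- config$tile_size[1]
  W <- config$tile_size[2]
  o <- config$overlap_fraction
  j <- config$jitter_px
  need <- required_source_size(config)
  if (nrow(image) < need[1] || ncol(image) < need[2]) {
    stop(sprintf("source image %dx%d too small; need at least %dx%d",
                 nrow(image), ncol(image), need[1], need[2]))
  }
  step_y <- round(H * (1 - o))
  step_x <- round(W * (1 - o))
  set.seed(config$seed)
  jit_x <- if (j > 0) matrix(sample(-j:j, M * N, replace = TRUE), M, N) else
    matrix(0L, M, N)
  jit_y <- if (j > 0) matrix(sample(-j:j, M * N, replace = TRUE), M, N) else
    matrix(0L, M, N)

  gain <- shading_field(H, W, config$shading, config$shading_amplitude)
  bg_level <- stats::median(image)
  is_bg <- matrix(FALSE, M, N)
  if (!is.null(config$background_tiles)) {
    for (i in seq_len(nrow(config$background_tiles))) {
      is_bg[config$background_tiles$row[i] + 1L,
            config$background_tiles$col[i] + 1L] <- TRUE
    }
  }

  tiles <- vector("list", M * N)
  truth <- data.frame(row = integer(M * N), col = integer(M * N),
                      x = numeric(M * N), y = numeric(M * N))
  k <- 0L
  for (r in 0:(M - 1L)) {
    for (c in 0:(N - 1L)) {
      k <- k + 1L
      x0 <- j + c * step_x + jit_x[r + 1L, c + 1L]
      y0 <- j + r * step_y + jit_y[r + 1L, c + 1L]
      tl <- image[y0 + seq_len(H), x0 + seq_len(W), drop = FALSE]
      if (is_bg[r + 1L, c + 1L]) tl <- matrix(bg_level, H, W)
      tl <- tl * gain
      if (config$noise_sigma > 0) {
        tl <- tl + matrix(stats::rnorm(H * W, 0, config$noise_sigma), H, W)
      }
      tl[tl < 0] <- 0
      tl[tl > 1] <- 1
      tiles[[k]] <- tl
      truth$row[k] <- r
      truth$col[k] <- c
      truth$x[k] <- x0
      truth$y[k] <- y0
    }
  }
  list(grid = tile_grid(tiles, M, N, o), truth = truth)
}

#' Generate a complete synthetic grid (source image + split)
#'
#' Convenience wrapper: builds the source image implied by
#' `config$pattern` at the required size and splits it.
#'
#' @param config a [synth_config()].
#' @return list with `image` (source), `grid`, `truth`.
#' @export
generate_synthetic_grid <- function(config) {
  need <- required_source_size(config)
  image <- if (config$pattern == "usaf") {
    generate_usaf_pattern(need[1], need[2])
  } else {
    generate_texture_image(need[1], need[2], seed = config$seed)
  }
  out <- split_image_to_grid(image, config)
  list(image = image, grid = out$grid, truth = out$truth)
}
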