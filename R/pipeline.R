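# ---- pipeline configuration -------------------------------------------------

#' Stitching pipeline configuration
#'
#' @param overlap_fraction nominal overlap fraction between adjacent tiles
#'   (required; stage metadata of the acquisition).
#' @param strip_fraction stage-1 feature strip as a fraction of tile
#'   width/height (default 0.05).
#' @param slack_fraction stage-range slack fraction (default 0.02).
#' @param modality detector preset; see [detector_config()].
#' @param response_threshold explicit detector threshold, used when
#'   `modality` is `NULL`.
#' @param graph `"mst"` (Prim minimum spanning tree) or `"spt"` (Dijkstra
#'   shortest path tree) for global alignment.
#' @param penalty_constant penalty added to the maximum finite edge weight
#'   for repaired links (default 1).
#' @param seed pipeline-level RNG seed (threaded to MSAC).
#' @param ... further arguments passed to [detector_config()].
#' @return a list of class `stitch_config`.
#' @export
stitch_config <- function(overlap_fraction, strip_fraction = 0.05,
                          slack_fraction = 0.02, modality = "brightfield",
                          response_threshold = 1000,
                          graph = c("mst", "spt"), penalty_constant = 1,
                          seed = 0L, ...) {
  graph <- match.arg(graph)
  stopifnot(strip_fraction > 0, strip_fraction <= overlap_fraction,
            overlap_fraction < 1, slack_fraction >= 0,
            slack_fraction < overlap_fraction)
  det <- detector_config(modality = modality,
                         response_threshold = response_threshold,
                         seed = seed, ...)
  structure(list(overlap_fraction = overlap_fraction,
                 strip_fraction = strip_fraction,
                 slack_fraction = slack_fraction,
                 graph = graph, penalty_constant = penalty_constant,
                 seed = as.integer(seed), detector = det),
            class = "stitch_config")
}

# ---- end-to-end stitching ---------------------------------------------------

#' Stitch a tile grid into a mosaic
#'
#' Runs the full pipeline: two-stage pairwise registration of all
#' `2MN - (M+N)` north/west links, stage-model filtering, row/column-average
#' repair of invalid links, graph construction with normalized
#' inverse-match-count weights, global positioning by MST or SPT, and
#' blend-free composition. Deterministic for a fixed config seed.
#'
#' @param grid a `tile_grid`.
#' @param config a [stitch_config()].
#' @return a list of class `stitch_result`: `mosaic` (a `mosaic_result`),
#'   `positions` (`tile_positions`), `links` (repaired `link_table`),
#'   `raw_links` (pre-repair), `graph`, `metrics` (with `overlap_rmse`),
#'   `counts` (strip/fallback/invalid/repaired link counts), `timing`
#'   (seconds per stage).
#' @export
stitch <- function(grid, config) {
  M <- grid$M
  N <- grid$N
  H <- grid$H
  W <- grid$W
  t0 <- proc.time()[["elapsed"]]

  links <- vector("list", 2L * M * N - (M + N))
  k <- 0L
  if (M > 1L) {
    for (r in 0:(M - 2L)) {
      for (c in 0:(N - 1L)) {
        k <- k + 1L
        links[[k]] <- register_pair(get_tile(grid, r, c),
                                    get_tile(grid, r + 1L, c),
                                    direction = "north",
                                    overlap_fraction = config$overlap_fraction,
                                    strip_fraction = config$strip_fraction,
                                    slack_fraction = config$slack_fraction,
                                    config = config$detector,
                                    ref_pos = c(r, c))
      }
    }
  }
  if (N > 1L) {
    for (r in 0:(M - 1L)) {
      for (c in 0:(N - 2L)) {
        k <- k + 1L
        links[[k]] <- register_pair(get_tile(grid, r, c),
                                    get_tile(grid, r, c + 1L),
                                    direction = "west",
                                    overlap_fraction = config$overlap_fraction,
                                    strip_fraction = config$strip_fraction,
                                    slack_fraction = config$slack_fraction,
                                    config = config$detector,
                                    ref_pos = c(r, c))
      }
    }
  }
  links <- if (k > 0L) do.call(rbind, links[seq_len(k)]) else
    make_link(c(0L, 0L), c(0L, 0L), "west")[0, ]
  links <- filter_translation(links, W, H, config$overlap_fraction,
                              config$slack_fraction)
  raw <- link_table(links, M, N)
  t_pairwise <- proc.time()[["elapsed"]] - t0

  t1 <- proc.time()[["elapsed"]]
  repaired <- repair_links(raw)
  graph <- build_graph(repaired, config$penalty_constant)
  positions <- if (config$graph == "mst") mst_positions(graph) else
    spt_positions(graph)
  t_global <- proc.time()[["elapsed"]] - t1

  t2 <- proc.time()[["elapsed"]]
  mosaic <- compose(grid, positions)
  t_compose <- proc.time()[["elapsed"]] - t2

  counts <- list(n_links = nrow(repaired),
                 n_strip = sum(raw$stage_used == "strip"),
                 n_full_overlap = sum(raw$stage_used == "full_overlap"),
                 n_invalid = sum(raw$status == "invalid"),
                 n_repaired = sum(repaired$stage_used == "repaired"))
  orm <- overlap_rmse(grid, positions)
  structure(list(mosaic = mosaic, positions = positions, links = repaired,
                 raw_links = raw, graph = graph,
                 metrics = list(overlap_rmse = orm),
                 counts = counts,
                 timing = list(pairwise_s = t_pairwise,
                               global_s = t_global,
                               compose_s = t_compose,
                               stitching_s = t_pairwise + t_global)),
            class = "stitch_result")
}

#' @export
print.stitch_result <- function(x, ...) {
  cat(sprintf("<stitch_result: %d links (%d strip, %d fallback, %d repaired)>\n",
              x$counts$n_links, x$counts$n_strip, x$counts$n_full_overlap,
              x$counts$n_repaired))
  cat(sprintf("  frame %dx%d, overlap RMSE %.4g, stitching %.2fs\n",
              x$mosaic$frame_size[1], x$mosaic$frame_size[2],
              as.numeric(x$metrics$overlap_rmse), x$timing$stitching_s))
  invisible(x)
}

#' Evaluate a stitching result against ground truth
#'
#' Computes the full metric report: overlap RMSE (ground-truth-free),
#' centroid distance error against the true tile positions (both position
#' sets normalized to a (0, 0) origin first), and MSE/PSNR against the
#' source image the grid was cut from.
#'
#' @param result a `stitch_result`.
#' @param grid the stitched `tile_grid`.
#' @param truth_positions data.frame of true tile positions (`row`, `col`,
#'   `x`, `y`).
#' @param truth_image optional source image for MSE/PSNR.
#' @param peak peak intensity for PSNR (default 1).
#' @return list with `overlap_rmse`, `d_err`, `mse`, `psnr`,
#'   `stitching_time_s`.
#' @export
evaluate_result <- function(result, grid, truth_positions,
                            truth_image = NULL, peak = 1) {
  # centroids are measured in the composed frame, where tiles sit at
  # integer pixel positions
  placed <- result$mosaic$positions
  placed$x <- placed$x_px
  placed$y <- placed$y_px
  d_err <- centroid_distance_error(normalize_positions(placed),
                                   normalize_positions(truth_positions))
  mse <- NA_real_
  psnr <- NA_real_
  if (!is.null(truth_image)) {
    truth_norm <- normalize_positions(truth_positions)
    truth_norm$x <- round(truth_norm$x)
    truth_norm$y <- round(truth_norm$y)
    ref <- compose(grid, truth_norm)
    mp <- image_mse_psnr(result$mosaic$image, ref$image, peak = peak)
    mse <- mp$mse
    psnr <- mp$psnr
  }
  list(overlap_rmse = as.numeric(result$metrics$overlap_rmse),
       d_err = d_err, mse = mse, psnr = psnr,
       stitching_time_s = result$timing$stitching_s)
}

# ---- tile-grid file I/O -----------------------------------------------------

#' Load a tile grid from a directory of images
#'
#' Filenames are generated from `pattern` via `sprintf`: a pattern with two
#' integer conversions receives `(row, col)` (plus `index_base`); a pattern
#' with one conversion receives the sequential acquisition index in the
#' given scan order (`"row-major"` or `"serpentine"`, i.e. boustrophedon).
#'
#' @param dir directory containing the tile images.
#' @param rows,cols grid dimensions.
#' @param pattern filename pattern without extension,
#'   e.g. `"r%02d_c%02d"` or `"tile_%03d"`.
#' @param ext file extension (`"tif"`, `"tiff"` or `"png"`).
#' @param scan_order acquisition order for single-index patterns.
#' @param overlap_fraction nominal overlap recorded on the grid.
#' @param index_base 0 or 1; first row/col/tile index used in filenames.
#' @return a `tile_grid` of grayscale tiles in `[0, 1]`.
#' @export
load_tile_grid <- function(dir, rows, cols, pattern = "r%02d_c%02d",
                           ext = "tif",
                           scan_order = c("row-major", "serpentine"),
                           overlap_fraction, index_base = 0L) {
  scan_order <- match.arg(scan_order)
  two_idx <- lengths(regmatches(pattern, gregexpr("%[0-9]*d", pattern))) == 2L
  tiles <- vector("list", rows * cols)
  for (r in 0:(rows - 1L)) {
    for (c in 0:(cols - 1L)) {
      if (two_idx) {
        fname <- sprintf(pattern, r + index_base, c + index_base)
      } else {
        cc <- if (scan_order == "serpentine" && r %% 2L == 1L)
          cols - 1L - c else c
        fname <- sprintf(pattern, r * cols + cc + index_base)
      }
      path <- file.path(dir, paste0(fname, ".", ext))
      if (!file.exists(path)) {
        stop(sprintf("missing tile (%d, %d): %s", r, c, path))
      }
      tiles[[r * cols + c + 1L]] <- read_image_gray(path)
    }
  }
  tile_grid(tiles, rows, cols, overlap_fraction)
}

#' Write a tile grid to a directory
#'
#' @param grid a `tile_grid`.
#' @param dir output directory (created if needed).
#' @param pattern two-index filename pattern.
#' @param ext `"tif"`, `"tiff"` or `"png"`.
#' @return the directory path, invisibly.
#' @export
write_tile_grid <- function(grid, dir, pattern = "r%02d_c%02d", ext = "tif") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in 0:(grid$M - 1L)) {
    for (c in 0:(grid$N - 1L)) {
      write_image(get_tile(grid, r, c),
                  file.path(dir, paste0(sprintf(pattern, r, c), ".", ext)))
    }
  }
  invisible(dir)
}

#' Write/read tile positions as CSV
#' @param positions positions data.frame (`row`, `col`, `x`, `y`).
#' @param path file path.
#' @export
write_positions <- function(positions, path) {
  utils::write.csv(as.data.frame(positions)[, c("row", "col", "x", "y")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
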