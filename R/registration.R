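# ---- pairwise registration --------------------------------------------------

# one-row data.frame representation of a pairwise link
make_link <- function(ref, mov, direction, t_x = NA_real_, t_y = NA_real_,
                      n_matched = NA_integer_, status = "invalid",
                      stage_used = "none") {
  data.frame(ref_row = ref[1], ref_col = ref[2],
             mov_row = mov[1], mov_col = mov[2],
             direction = direction, t_x = t_x, t_y = t_y,
             n_matched = n_matched, status = status,
             stage_used = stage_used, stringsAsFactors = FALSE)
}

# detect features inside a 0-based rectangle of a tile; the crop is padded by
# the descriptor support so descriptors near the rectangle edge sample real
# tile content wherever the tile provides it
detect_in_rect <- function(tile, x0, x1, y0, y1, pad, config) {
  H <- nrow(tile)
  W <- ncol(tile)
  cx0 <- max(0L, as.integer(floor(x0 - pad)))
  cx1 <- min(W - 1L, as.integer(ceiling(x1 + pad)))
  cy0 <- max(0L, as.integer(floor(y0 - pad)))
  cy1 <- min(H - 1L, as.integer(ceiling(y1 + pad)))
  region <- tile[(cy0 + 1L):(cy1 + 1L), (cx0 + 1L):(cx1 + 1L), drop = FALSE]
  fs <- detect_features(region, config$response_threshold,
                        region_offset = c(cx0, cy0),
                        sigmas = config$sigmas,
                        max_keypoints = config$max_keypoints)
  keep <- fs$keypoints$x >= x0 & fs$keypoints$x <= x1 &
    fs$keypoints$y >= y0 & fs$keypoints$y <= y1
  feature_set(fs$keypoints[keep, , drop = FALSE],
              fs$descriptors[keep, , drop = FALSE])
}

# detection rectangles for one stage of one link direction.
# Reference and moving rectangles cover the same physical strip: the strip
# sits just inside the shared tile edge (inset by the descriptor pad so both
# tiles supply real content around it); the moving-tile rectangle is widened
# by the stage slack so the strip stays covered under stage jitter.
link_regions <- function(direction, W, H, overlap_fraction, strip_fraction,
                         slack_fraction, pad, stage) {
  m <- ceiling(slack_fraction * if (direction == "west") W else H)
  if (direction == "west") {
    t_nom <- W * (1 - overlap_fraction)
    if (stage == "strip") {
      s <- max(3, round(strip_fraction * W))
      rx <- c(W - s - pad, W - 1 - pad)
      mx <- c(rx[1] - t_nom - m, rx[2] - t_nom + m)
    } else {
      rx <- c(t_nom - m, W - 1)
      mx <- c(0, W - 1 - t_nom + m)
    }
    list(ref = list(x = rx, y = c(0, H - 1)),
         mov = list(x = mx, y = c(0, H - 1)))
  } else {
    t_nom <- H * (1 - overlap_fraction)
    if (stage == "strip") {
      s <- max(3, round(strip_fraction * H))
      ry <- c(H - s - pad, H - 1 - pad)
      my <- c(ry[1] - t_nom - m, ry[2] - t_nom + m)
    } else {
      ry <- c(t_nom - m, H - 1)
      my <- c(0, H - 1 - t_nom + m)
    }
    list(ref = list(x = c(0, W - 1), y = ry),
         mov = list(x = c(0, W - 1), y = my))
  }
}

# is (t_x, t_y) inside the mechanically plausible stage range?
translation_in_range <- function(t_x, t_y, direction, W, H,
                                 overlap_fraction, slack_fraction) {
  sw <- slack_fraction * W
  sh <- slack_fraction * H
  ifelse(direction == "west",
         t_x >= W * (1 - overlap_fraction) - sw &
           t_x <= W * (1 - overlap_fraction) + sw & abs(t_y) <= sh,
         t_y >= H * (1 - overlap_fraction) - sh &
           t_y <= H * (1 - overlap_fraction) + sh & abs(t_x) <= sw)
}

#' Register one pair of adjacent tiles
#'
#' Two-stage restricted-region registration. Stage 1 detects and matches
#' blob features in a narrow strip (default 5% of the tile width/height) of
#' the overlap at the shared edge and estimates the translation by MSAC.
#' If no acceptable translation is found there -- too few matches, too small
#' a consensus, or an estimate outside the plausible stage range -- stage 2
#' repeats the process on the entire nominal overlap region. If both stages
#' fail the link is returned invalid with NaN-equivalent sentinel values.
#'
#' @param ref,mov reference and moving tile intensity matrices in `[0, 1]`.
#'   For a `"west"` link the reference is the west (left) tile; for a
#'   `"north"` link the reference is the north (upper) tile.
#' @param direction `"west"` or `"north"`.
#' @param overlap_fraction nominal overlap fraction between adjacent tiles.
#' @param strip_fraction stage-1 strip size as a fraction of tile
#'   width/height (default 0.05).
#' @param slack_fraction stage-range slack as a fraction of tile
#'   width/height (default 0.02).
#' @param config a [detector_config()].
#' @param ref_pos,mov_pos optional `(row, col)` grid indices recorded on the
#'   returned link.
#' @param stages which stages to attempt, in order (mainly for testing).
#' @return one-row link data.frame with columns `ref_row`, `ref_col`,
#'   `mov_row`, `mov_col`, `direction`, `t_x`, `t_y`, `n_matched`, `status`,
#'   `stage_used`.
#' @export
register_pair <- function(ref, mov, direction = c("west", "north"),
                          overlap_fraction, strip_fraction = 0.05,
                          slack_fraction = 0.02,
                          config = detector_config(),
                          ref_pos = c(0L, 0L), mov_pos = NULL,
                          stages = c("strip", "full_overlap")) {
  direction <- match.arg(direction)
  if (!all(dim(ref) == dim(mov))) {
    stop("tile dimension mismatch: ", paste(dim(ref), collapse = "x"),
         " vs ", paste(dim(mov), collapse = "x"))
  }
  stopifnot(strip_fraction > 0, strip_fraction <= overlap_fraction,
            overlap_fraction < 1)
  if (is.null(mov_pos)) {
    mov_pos <- if (direction == "west") ref_pos + c(0L, 1L) else
      ref_pos + c(1L, 0L)
  }
  H <- nrow(ref)
  W <- ncol(ref)
  pad <- ceiling(3.5 * max(config$sigmas))

  for (stage in stages) {
    stg <- if (stage == "strip") "strip" else "full"
    rg <- link_regions(direction, W, H, overlap_fraction, strip_fraction,
                       slack_fraction, pad, stg)
    fs_ref <- detect_in_rect(ref, rg$ref$x[1], rg$ref$x[2],
                             rg$ref$y[1], rg$ref$y[2], pad, config)
    fs_mov <- detect_in_rect(mov, rg$mov$x[1], rg$mov$x[2],
                             rg$mov$y[1], rg$mov$y[2], pad, config)
    mt <- match_features(fs_ref, fs_mov, ratio = config$match_ratio)
    est <- estimate_translation_msac(mt, inlier_tol = config$inlier_tol,
                                     confidence = config$confidence,
                                     max_iters = config$max_iters,
                                     min_matches = config$min_matches,
                                     min_inliers = config$min_inliers,
                                     seed = config$seed)
    if (!is.null(est) &&
        translation_in_range(est$t_x, est$t_y, direction, W, H,
                             overlap_fraction, slack_fraction)) {
      return(make_link(ref_pos, mov_pos, direction,
                       t_x = est$t_x, t_y = est$t_y,
                       n_matched = est$n_inliers, status = "valid",
                       stage_used = if (stage == "strip") "strip" else
                         "full_overlap"))
    }
  }
  make_link(ref_pos, mov_pos, direction)
}

#' Screen link translations against the stage model
#'
#' A translation is mechanically plausible only within the nominal overlap
#' position plus/minus a slack of 2% of the tile width/height (stage
#' repeatability). For a west link the valid range is
#' `t_x` in `[W(1-o) - s_f W, W(1-o) + s_f W]` and `|t_y| <= s_f H`; a north
#' link swaps the roles of the axes. Links outside the range are invalidated:
#' their translation and matched count become `NA` sentinels.
#'
#' @param links link data.frame (one or more rows).
#' @param W,H tile width and height in pixels.
#' @param overlap_fraction nominal overlap fraction.
#' @param slack_fraction slack as a fraction of tile dimension (default 0.02).
#' @return the links with out-of-range rows invalidated.
#' @export
filter_translation <- function(links, W, H, overlap_fraction,
                               slack_fraction = 0.02) {
  if (nrow(links) == 0L) return(links)
  ok <- links$status == "valid" &
    translation_in_range(links$t_x, links$t_y, links$direction, W, H,
                         overlap_fraction, slack_fraction)
  bad <- links$status == "valid" & !ok
  links$status[bad] <- "invalid"
  links$t_x[bad] <- NA_real_
  links$t_y[bad] <- NA_real_
  links$n_matched[bad] <- NA_integer_
  links
}
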