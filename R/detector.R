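# ---- low-level image helpers ------------------------------------------------

#' Separable Gaussian smoothing with replicate padding
#'
#' @param img numeric matrix (rows = y, columns = x).
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same dimensions.
#' @keywords internal
blur_gauss <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(img)
  W <- ncol(img)
  tmp <- matrix(0, H, W)
  for (i in seq_along(k)) {
    idx <- pmin(pmax(seq_len(H) + (i - r - 1L), 1L), H)
    tmp <- tmp + k[i] * img[idx, , drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (i in seq_along(k)) {
    idx <- pmin(pmax(seq_len(W) + (i - r - 1L), 1L), W)
    out <- out + k[i] * tmp[, idx, drop = FALSE]
  }
  out
}

# shift a matrix by (dy, dx) with replicate padding at the borders
shift_mat <- function(m, dy, dx) {
  H <- nrow(m)
  W <- ncol(m)
  m[pmin(pmax(seq_len(H) + dy, 1L), H), pmin(pmax(seq_len(W) + dx, 1L), W),
    drop = FALSE]
}

# scale-normalized determinant of the Hessian of a smoothed image
doh_response <- function(L, sigma) {
  Lxx <- shift_mat(L, 0L, 1L) - 2 * L + shift_mat(L, 0L, -1L)
  Lyy <- shift_mat(L, 1L, 0L) - 2 * L + shift_mat(L, -1L, 0L)
  Lxy <- (shift_mat(L, 1L, 1L) + shift_mat(L, -1L, -1L) -
            shift_mat(L, 1L, -1L) - shift_mat(L, -1L, 1L)) / 4
  sigma^4 * (Lxx * Lyy - Lxy^2)
}

# bilinear sampling at 0-based (xs, ys), clamped to the image domain
sample_bilinear <- function(img, xs, ys) {
  H <- nrow(img)
  W <- ncol(img)
  xs <- pmin(pmax(xs, 0), W - 1)
  ys <- pmin(pmax(ys, 0), H - 1)
  x0 <- floor(xs)
  y0 <- floor(ys)
  x1 <- pmin(x0 + 1, W - 1)
  y1 <- pmin(y0 + 1, H - 1)
  fx <- xs - x0
  fy <- ys - y0
  i00 <- (x0) * H + y0 + 1
  i01 <- (x1) * H + y0 + 1
  i10 <- (x0) * H + y1 + 1
  i11 <- (x1) * H + y1 + 1
  (1 - fy) * ((1 - fx) * img[i00] + fx * img[i01]) +
    fy * ((1 - fx) * img[i10] + fx * img[i11])
}

# ---- detector configuration -------------------------------------------------

#' Blob detector and matcher settings
#'
#' Bundles the parameters of the scale-space determinant-of-Hessian blob
#' detector, the descriptor matcher and the robust translation estimator.
#' The `modality` presets map imaging modes to the response thresholds that
#' work well in practice: bright-field images carry strong, high-contrast
#' blobs (nuclei, debris), so a high threshold (1000) keeps only dominant
#' features; phase-contrast and fluorescence images are flatter, so the
#' threshold drops to 1.
#'
#' Thresholds are expressed on a 0--255 intensity scale (the conventional
#' scale for Hessian-determinant responses); images stored in `[0, 1]` are
#' rescaled internally before detection.
#'
#' @param modality one of `"brightfield"`, `"phase"`, `"fluorescence"`, or
#'   `NULL` to use `response_threshold` directly.
#' @param response_threshold minimum scale-normalized Hessian-determinant
#'   response for a keypoint to be retained. Ignored when `modality` is given.
#' @param sigmas Gaussian scales (pixels) of the detection scale-space.
#' @param max_keypoints keep at most this many strongest keypoints per region.
#' @param match_ratio Lowe-style ratio-test threshold on descriptor distances.
#' @param inlier_tol MSAC inlier tolerance in pixels.
#' @param confidence MSAC confidence for adaptive sampling.
#' @param max_iters maximum MSAC hypotheses; when the number of putative
#'   matches is below this, all single-match hypotheses are scored
#'   exhaustively (deterministic).
#' @param min_matches minimum putative matches to attempt estimation.
#' @param min_inliers minimum consensus size to accept an estimate.
#' @param seed integer seed for MSAC sampling.
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(modality = NULL,
                            response_threshold = 1000,
                            sigmas = c(1.2, 1.6, 2.2, 3.0),
                            max_keypoints = 500L,
                            match_ratio = 0.8,
                            inlier_tol = 2,
                            confidence = 0.99,
                            max_iters = 500L,
                            min_matches = 3L,
                            min_inliers = 3L,
                            seed = 0L) {
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("brightfield", "phase", "fluorescence"))
    response_threshold <- switch(modality,
                                 brightfield = 1000,
                                 phase = 1,
                                 fluorescence = 1)
  }
  stopifnot(response_threshold >= 0, all(sigmas > 0), inlier_tol > 0)
  structure(list(modality = modality,
                 response_threshold = response_threshold,
                 sigmas = sigmas,
                 max_keypoints = as.integer(max_keypoints),
                 match_ratio = match_ratio,
                 inlier_tol = inlier_tol,
                 confidence = confidence,
                 max_iters = as.integer(max_iters),
                 min_matches = as.integer(min_matches),
                 min_inliers = as.integer(min_inliers),
                 seed = as.integer(seed)),
            class = "detector_config")
}

# ---- feature detection ------------------------------------------------------

#' Detect scale-space blob features
#'
#' Runs a determinant-of-Hessian blob detector over a Gaussian scale-space:
#' the image is smoothed at each scale, the scale-normalized Hessian
#' determinant is computed, and keypoints are local maxima (over the 3x3
#' spatial neighbourhood and the adjacent scales) whose response meets the
#' threshold. Each keypoint carries a 64-dimensional normalized-patch
#' descriptor sampled on an 8x8 grid with spacing proportional to the
#' keypoint scale; descriptors are mean-subtracted and unit-normalized, which
#' makes matching invariant to local affine intensity changes (gain and
#' offset), e.g. vignetting.
#'
#' @param region numeric matrix of intensities in `[0, 1]` (rows = y).
#' @param response_threshold minimum Hessian-determinant response (on the
#'   0--255 intensity scale) to retain a keypoint.
#' @param region_offset length-2 numeric `(x, y)` added to keypoint
#'   coordinates, mapping them from region-local to tile-local 0-based pixels.
#' @param sigmas detection scales in pixels.
#' @param max_keypoints cap on the number of keypoints (strongest kept).
#' @param intensity_scale multiplier applied before response computation so
#'   thresholds follow the conventional 0--255 scale.
#' @return a `feature_set`: list with `keypoints`
#'   (data.frame `x`, `y`, `sigma`, `response`) and `descriptors`
#'   (numeric matrix, one row per keypoint).
#' @export
detect_features <- function(region, response_threshold,
                            region_offset = c(0, 0),
                            sigmas = c(1.2, 1.6, 2.2, 3.0),
                            max_keypoints = 500L,
                            intensity_scale = 255) {
  stopifnot(is.matrix(region), response_threshold >= 0)
  empty <- feature_set(data.frame(x = numeric(0), y = numeric(0),
                                  sigma = numeric(0), response = numeric(0)),
                       matrix(numeric(0), 0, 64))
  H <- nrow(region)
  W <- ncol(region)
  if (H < 5 || W < 5) return(empty)
  img <- region * intensity_scale
  ns <- length(sigmas)
  smoothed <- lapply(sigmas, function(s) blur_gauss(img, s))
  resp <- mapply(doh_response, smoothed, sigmas, SIMPLIFY = FALSE)

  kp <- vector("list", ns)
  margin <- 2L
  for (si in seq_len(ns)) {
    R <- resp[[si]]
    is_max <- R >= response_threshold
    for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
                   c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
      is_max <- is_max & (R > shift_mat(R, d[1], d[2]))
      if (!any(is_max)) break
    }
    if (si > 1L) is_max <- is_max & (R >= resp[[si - 1L]])
    if (si < ns) is_max <- is_max & (R >= resp[[si + 1L]])
    # exclude a border band where finite differences use replicated pixels
    if (any(is_max)) {
      is_max[c(seq_len(margin), H - seq_len(margin) + 1L), ] <- FALSE
      is_max[, c(seq_len(margin), W - seq_len(margin) + 1L)] <- FALSE
    }
    if (any(is_max)) {
      idx <- which(is_max)
      kp[[si]] <- data.frame(x = ((idx - 1L) %/% H),
                             y = ((idx - 1L) %% H),
                             sigma = sigmas[si],
                             response = R[idx])
    }
  }
  kp <- do.call(rbind, kp[!vapply(kp, is.null, logical(1))])
  if (is.null(kp) || nrow(kp) == 0L) return(empty)
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]

  desc <- patch_descriptors(smoothed, sigmas, kp)
  kp$x <- kp$x + region_offset[1]
  kp$y <- kp$y + region_offset[2]
  rownames(kp) <- NULL
  feature_set(kp, desc)
}

# 8x8 normalized intensity patches sampled at the keypoint scale
patch_descriptors <- function(smoothed, sigmas, kp) {
  grid <- (seq_len(8) - 4.5)   # spacing multiplied by sigma per keypoint
  off_x <- rep(grid, times = 8)
  off_y <- rep(grid, each = 8)
  desc <- matrix(0, nrow(kp), 64)
  for (si in seq_along(sigmas)) {
    rows <- which(kp$sigma == sigmas[si])
    if (!length(rows)) next
    s <- sigmas[si]
    xs <- outer(kp$x[rows], off_x * s, `+`)
    ys <- outer(kp$y[rows], off_y * s, `+`)
    desc[rows, ] <- sample_bilinear(smoothed[[si]], xs, ys)
  }
  desc <- desc - rowMeans(desc)
  nrm <- sqrt(rowSums(desc^2))
  ok <- nrm > 1e-8
  desc[ok, ] <- desc[ok, , drop = FALSE] / nrm[ok]
  desc[!ok, ] <- 0
  desc
}

#' @rdname detect_features
#' @param keypoints keypoint data.frame.
#' @param descriptors descriptor matrix, one row per keypoint.
#' @export
feature_set <- function(keypoints, descriptors) {
  stopifnot(nrow(keypoints) == nrow(descriptors))
  structure(list(keypoints = keypoints, descriptors = descriptors),
            class = "feature_set")
}

#' Number of keypoints in a feature set
#' @param fs a `feature_set`.
#' @export
n_features <- function(fs) nrow(fs$keypoints)

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set: %d keypoints, %d-d descriptors>\n",
              n_features(x), ncol(x$descriptors)))
  invisible(x)
}
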