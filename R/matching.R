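# ---- descriptor matching ----------------------------------------------------

#' Match two feature sets by descriptor distance
#'
#' Nearest-neighbour matching in descriptor space with a Lowe-style ratio
#' test and a mutual-best check: a pair (i, j) is kept when j is the nearest
#' neighbour of i, the distance to j is at most `ratio` times the distance to
#' i's second-nearest neighbour, and i is in turn the nearest neighbour of j.
#' Each keypoint therefore appears in at most one correspondence.
#'
#' @param fs_ref,fs_mov `feature_set` objects for the reference and moving
#'   regions.
#' @param ratio ratio-test threshold (default 0.8).
#' @param mutual require the match to be mutual-best (default `TRUE`).
#' @return data.frame with one row per correspondence: `ref`, `mov`
#'   (keypoint indices), `x_ref`, `y_ref`, `x_mov`, `y_mov`, `dist`.
#' @export
match_features <- function(fs_ref, fs_mov, ratio = 0.8, mutual = TRUE) {
  empty <- data.frame(ref = integer(0), mov = integer(0),
                      x_ref = numeric(0), y_ref = numeric(0),
                      x_mov = numeric(0), y_mov = numeric(0),
                      dist = numeric(0))
  na <- n_features(fs_ref)
  nb <- n_features(fs_mov)
  if (na == 0L || nb == 0L) return(empty)
  A <- fs_ref$descriptors
  B <- fs_mov$descriptors
  D2 <- matrix(rowSums(A^2), na, nb) +
    matrix(rowSums(B^2), na, nb, byrow = TRUE) - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0

  best <- max.col(-D2, ties.method = "first")
  d1 <- D2[cbind(seq_len(na), best)]
  if (nb >= 2L) {
    D2b <- D2
    D2b[cbind(seq_len(na), best)] <- Inf
    d2 <- D2b[cbind(seq_len(na), max.col(-D2b, ties.method = "first"))]
    keep <- sqrt(d1) <= ratio * sqrt(d2)
  } else {
    keep <- rep(TRUE, na)
  }
  if (mutual) {
    best_rev <- max.col(-t(D2), ties.method = "first")
    keep <- keep & (best_rev[best] == seq_len(na))
  }
  if (!any(keep)) return(empty)
  i <- which(keep)
  j <- best[keep]
  data.frame(ref = i, mov = j,
             x_ref = fs_ref$keypoints$x[i], y_ref = fs_ref$keypoints$y[i],
             x_mov = fs_mov$keypoints$x[j], y_mov = fs_mov$keypoints$y[j],
             dist = sqrt(d1[keep]))
}

# ---- robust translation estimation ------------------------------------------

#' Estimate a translation from correspondences by MSAC
#'
#' M-estimator sample consensus for a pure translation model. Each
#' correspondence yields a one-point hypothesis `(t_x, t_y) = p_ref - p_mov`;
#' hypotheses are scored by the truncated squared residual loss
#' `sum(min(r^2, tol^2))` over all correspondences, and the best-scoring
#' hypothesis wins. The final translation is the mean displacement over that
#' hypothesis's inliers (residual within `inlier_tol`). When the number of
#' correspondences does not exceed `max_iters`, every hypothesis is scored
#' (exhaustive and deterministic); otherwise hypotheses are sampled with the
#' given seed and adaptive early stopping at the requested confidence.
#'
#' The translation convention is the position of the moving tile's top-left
#' corner in the reference tile's frame, x rightward, y downward.
#'
#' @param matches data.frame as returned by [match_features()].
#' @param inlier_tol inlier tolerance in pixels.
#' @param confidence confidence level for adaptive sampling.
#' @param max_iters hypothesis budget.
#' @param min_matches fewer correspondences than this returns not-found.
#' @param min_inliers smaller consensus than this returns not-found.
#' @param seed RNG seed used only in the sampling regime.
#' @return list with `t_x`, `t_y`, `n_inliers`, `score`, `inliers` (indices),
#'   or `NULL` when no acceptable model exists (not-found; not an error).
#' @export
estimate_translation_msac <- function(matches, inlier_tol = 2,
                                      confidence = 0.99, max_iters = 500L,
                                      min_matches = 3L, min_inliers = 3L,
                                      seed = 0L) {
  stopifnot(inlier_tol > 0)
  n <- nrow(matches)
  if (is.null(n) || n < min_matches) return(NULL)
  dx <- matches$x_ref - matches$x_mov
  dy <- matches$y_ref - matches$y_mov
  tol2 <- inlier_tol^2

  score_of <- function(i) {
    r2 <- (dx - dx[i])^2 + (dy - dy[i])^2
    sum(pmin(r2, tol2))
  }

  best_i <- NA_integer_
  best_score <- Inf
  if (n <= max_iters) {
    for (i in seq_len(n)) {
      s <- score_of(i)
      if (s < best_score) {
        best_score <- s
        best_i <- i
      }
    }
  } else {
    set.seed(seed)
    needed <- max_iters
    it <- 0L
    while (it < needed) {
      it <- it + 1L
      i <- sample.int(n, 1L)
      s <- score_of(i)
      if (s < best_score) {
        best_score <- s
        best_i <- i
        w <- mean((dx - dx[i])^2 + (dy - dy[i])^2 <= tol2)
        if (w > 0 && w < 1) {
          needed <- min(max_iters,
                        ceiling(log(1 - confidence) / log(1 - w)))
        } else if (w >= 1) {
          break
        }
      }
    }
  }
  if (is.na(best_i)) return(NULL)
  r2 <- (dx - dx[best_i])^2 + (dy - dy[best_i])^2
  inl <- which(r2 <= tol2)
  if (length(inl) < min_inliers) return(NULL)
  list(t_x = mean(dx[inl]), t_y = mean(dy[inl]),
       n_inliers = length(inl), score = best_score, inliers = inl)
}
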