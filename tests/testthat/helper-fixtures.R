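# shared fixtures and independent oracles for the test suite

# cache generated images across tests within one run
.fixture_env <- new.env(parent = emptyenv())

test_texture <- function(h, w, seed = 1) {
  key <- sprintf("tex_%d_%d_%d", h, w, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_texture_image(h, w, seed = seed)
  }
  .fixture_env[[key]]
}

# a feature set with distinctive (orthogonal-ish) descriptors at given coords
fake_feature_set <- function(x, y, seed = 1) {
  n <- length(x)
  set.seed(seed)
  d <- matrix(rnorm(n * 64), n, 64)
  d <- d - rowMeans(d)
  d <- d / sqrt(rowSums(d^2))
  feature_set(data.frame(x = x, y = y, sigma = 1.6, response = 1000 + seq_len(n)),
              d)
}

# fabricate an exact link table for an MxN grid: true positions given as
# data.frame(row, col, x, y); every link valid with the exact translation
exact_link_table <- function(truth, M, N, n_matched = 20L) {
  key <- paste(truth$row, truth$col)
  one <- function(r1, c1, r2, c2, dir) {
    i <- match(paste(r1, c1), key)
    j <- match(paste(r2, c2), key)
    data.frame(ref_row = r1, ref_col = c1, mov_row = r2, mov_col = c2,
               direction = dir,
               t_x = truth$x[j] - truth$x[i], t_y = truth$y[j] - truth$y[i],
               n_matched = n_matched, status = "valid", stage_used = "strip",
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (M > 1) for (r in 0:(M - 2)) for (c in 0:(N - 1)) {
    rows[[length(rows) + 1]] <- one(r, c, r + 1, c, "north")
  }
  if (N > 1) for (r in 0:(M - 1)) for (c in 0:(N - 2)) {
    rows[[length(rows) + 1]] <- one(r, c, r, c + 1, "west")
  }
  link_table(do.call(rbind, rows), M, N)
}

# nominal (jitter-free) truth positions for an MxN grid
nominal_truth <- function(M, N, H, W, o) {
  g <- expand.grid(col = 0:(N - 1), row = 0:(M - 1))
  data.frame(row = g$row, col = g$col,
             x = g$col * round(W * (1 - o)), y = g$row * round(H * (1 - o)))
}

# ---- independent oracles ----------------------------------------------------

# truncated-loss brute force over all single-correspondence hypotheses
bf_msac_score <- function(matches, tol) {
  dx <- matches$x_ref - matches$x_mov
  dy <- matches$y_ref - matches$y_mov
  scores <- vapply(seq_along(dx), function(i) {
    sum(pmin((dx - dx[i])^2 + (dy - dy[i])^2, tol^2))
  }, numeric(1))
  list(best = which.min(scores), score = min(scores), scores = scores)
}

# minimum spanning tree weight by exhaustive enumeration of edge subsets
bf_mst_weight <- function(n_vertices, edges) {
  idx <- utils::combn(nrow(edges), n_vertices - 1)
  best <- Inf
  for (k in seq_len(ncol(idx))) {
    sel <- edges[idx[, k], ]
    # spanning + acyclic check via union-find
    parent <- seq_len(n_vertices)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    ok <- TRUE
    for (i in seq_len(nrow(sel))) {
      ra <- find(sel$u[i]); rb <- find(sel$v[i])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok && length(unique(vapply(seq_len(n_vertices), find, numeric(1)))) == 1) {
      best <- min(best, sum(sel$weight))
    }
  }
  best
}

# all-pairs shortest paths by Floyd-Warshall
bf_apsp <- function(n_vertices, edges) {
  d <- matrix(Inf, n_vertices, n_vertices)
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]; w <- edges$weight[i]
    d[u, v] <- min(d[u, v], w)
    d[v, u] <- min(d[v, u], w)
  }
  for (k in seq_len(n_vertices)) {
    for (i in seq_len(n_vertices)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# integer-shift normalized cross-correlation oracle for a registration pair:
# search the best (tx, ty) over the given ranges
bf_ncc_shift <- function(ref, mov, tx_range, ty_range) {
  best <- c(NA, NA); best_v <- -Inf
  for (ty in ty_range) for (tx in tx_range) {
    # overlap of mov placed at (tx, ty) in ref frame
    x0 <- max(0, tx); x1 <- min(ncol(ref), tx + ncol(mov)) - 1
    y0 <- max(0, ty); y1 <- min(nrow(ref), ty + nrow(mov)) - 1
    if (x1 - x0 < 10 || y1 - y0 < 10) next
    a <- ref[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
    b <- mov[(y0 - ty + 1):(y1 - ty + 1), (x0 - tx + 1):(x1 - tx + 1)]
    v <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
    if (!is.na(v) && v > best_v) { best_v <- v; best <- c(tx, ty) }
  }
  list(t = best, ncc = best_v)
}
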