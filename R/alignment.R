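# ---- global alignment graph -------------------------------------------------

# vertex id of tile (row, col), 1-based, row-major
vertex_id <- function(row, col, N) row * N + col + 1L

#' Build the weighted tile-adjacency graph
#'
#' Each tile is a vertex, each pairwise link an undirected edge. Edges whose
#' matched-feature count is finite get weight equal to the normalized inverse
#' count: `(1/n) / max(1/n)` over finite-count edges, so finite weights lie
#' in `(0, 1]` and the weakest finite edge has weight exactly 1 -- a more
#' reliable transform (more matches) costs less. Edges with a sentinel count
#' (repaired links) get the maximum finite weight plus a positive constant,
#' which keeps them out of the spanning structure unless no textured route
#' exists.
#'
#' @param table a fully repaired `link_table` (all translations finite).
#' @param penalty_constant positive constant added to the maximum finite
#'   weight for sentinel-count edges (default 1).
#' @return an `alignment_graph`: list with `edges` (data.frame), `M`, `N`,
#'   `n_vertices`, `penalty_weight`.
#' @export
build_graph <- function(table, penalty_constant = 1) {
  M <- attr(table, "M")
  N <- attr(table, "N")
  stopifnot(penalty_constant > 0)
  if (nrow(table) > 0L && any(!is.finite(table$t_x) | !is.finite(table$t_y))) {
    stop("link table contains non-finite translations; run repair_links() first")
  }
  inv <- 1 / table$n_matched
  finite <- is.finite(inv)
  if (any(finite)) {
    w <- inv / max(inv[finite])
    penalty <- max(w[finite]) + penalty_constant
  } else {
    w <- rep(1, nrow(table))
    penalty <- 1 + penalty_constant
  }
  w[!finite] <- penalty
  edges <- data.frame(u = vertex_id(table$ref_row, table$ref_col, N),
                      v = vertex_id(table$mov_row, table$mov_col, N),
                      u_row = table$ref_row, u_col = table$ref_col,
                      v_row = table$mov_row, v_col = table$mov_col,
                      direction = table$direction,
                      t_x = table$t_x, t_y = table$t_y,
                      n_matched = table$n_matched,
                      weight = as.numeric(w))
  structure(list(edges = edges, M = M, N = N,
                 n_vertices = as.integer(M) * as.integer(N),
                 penalty_weight = penalty),
            class = "alignment_graph")
}

#' @export
print.alignment_graph <- function(x, ...) {
  cat(sprintf("<alignment_graph: %dx%d grid, %d vertices, %d edges>\n",
              x$M, x$N, x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Write a graph edge list as CSV
#' @param graph an `alignment_graph`.
#' @param path file path.
#' @param tree_edges optional integer vector of edge indices in the tree.
#' @export
write_graph_edges <- function(graph, path, tree_edges = NULL) {
  e <- graph$edges
  e$in_tree <- if (is.null(tree_edges)) NA else seq_len(nrow(e)) %in% tree_edges
  utils::write.csv(e, path, row.names = FALSE)
  invisible(path)
}

# incidence list: for each vertex, indices of incident edges
incidence_list <- function(graph) {
  adj <- vector("list", graph$n_vertices)
  for (i in seq_len(nrow(graph$edges))) {
    u <- graph$edges$u[i]
    v <- graph$edges$v[i]
    adj[[u]] <- c(adj[[u]], i)
    adj[[v]] <- c(adj[[v]], i)
  }
  adj
}

# accumulate positions over a set of tree edges from a root vertex.
# For each edge, position(moving) = position(reference) + (t_x, t_y).
positions_from_tree <- function(graph, tree_edges, root) {
  nv <- graph$n_vertices
  e <- graph$edges
  adj <- vector("list", nv)
  for (i in tree_edges) {
    adj[[e$u[i]]] <- c(adj[[e$u[i]]], i)
    adj[[e$v[i]]] <- c(adj[[e$v[i]]], i)
  }
  pos <- matrix(NA_real_, nv, 2)
  pos[root, ] <- c(0, 0)
  queue <- root
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    for (i in adj[[u]]) {
      if (e$u[i] == u && is.na(pos[e$v[i], 1])) {
        pos[e$v[i], ] <- pos[u, ] + c(e$t_x[i], e$t_y[i])
        queue <- c(queue, e$v[i])
      } else if (e$v[i] == u && is.na(pos[e$u[i], 1])) {
        pos[e$u[i], ] <- pos[u, ] - c(e$t_x[i], e$t_y[i])
        queue <- c(queue, e$u[i])
      }
    }
  }
  if (anyNA(pos)) stop("alignment graph is disconnected")
  pos[, 1] <- pos[, 1] - min(pos[, 1])
  pos[, 2] <- pos[, 2] - min(pos[, 2])
  pos
}

tile_positions <- function(graph, pos, tree_edges, origin) {
  N <- graph$N
  ids <- seq_len(graph$n_vertices)
  out <- data.frame(row = (ids - 1L) %/% N, col = (ids - 1L) %% N,
                    x = pos[, 1], y = pos[, 2])
  structure(out, class = c("tile_positions", "data.frame"),
            tree_edges = tree_edges, origin = origin, M = graph$M, N = N)
}

#' Global positions from a minimum spanning tree
#'
#' Prim's algorithm grows a minimum spanning tree from tile (0, 0); ties in
#' edge weight are broken lexicographically by the (row, col) of the vertex
#' being added and then by direction, so the tree is reproducible. Tile
#' positions are accumulated along tree edges and shifted so the minimum x
#' and y are zero.
#'
#' @param graph an `alignment_graph`.
#' @return a `tile_positions` data.frame (`row`, `col`, `x`, `y`) with
#'   attributes `tree_edges` (edge indices, `MN - 1` of them) and `origin`.
#' @export
mst_positions <- function(graph) {
  nv <- graph$n_vertices
  e <- graph$edges
  if (nv == 1L) return(tile_positions(graph, matrix(0, 1, 2), integer(0), 1L))
  adj <- incidence_list(graph)
  in_tree <- rep(FALSE, nv)
  in_tree[1L] <- TRUE
  tree <- integer(0)
  # best candidate edge per outside vertex
  best_w <- rep(Inf, nv)
  best_e <- rep(NA_integer_, nv)
  relax_from <- function(u) {
    for (i in adj[[u]]) {
      other <- if (e$u[i] == u) e$v[i] else e$u[i]
      if (!in_tree[other]) {
        if (e$weight[i] < best_w[other] ||
            (e$weight[i] == best_w[other] && !is.na(best_e[other]) &&
             e$direction[i] < e$direction[best_e[other]])) {
          best_w[other] <<- e$weight[i]
          best_e[other] <<- i
        }
      }
    }
  }
  relax_from(1L)
  for (step in seq_len(nv - 1L)) {
    cand <- which(!in_tree & is.finite(best_w))
    if (!length(cand)) stop("alignment graph is disconnected")
    # min weight; ties -> smallest vertex id (lexicographic (row, col))
    nxt <- cand[which.min(best_w[cand])]
    in_tree[nxt] <- TRUE
    tree <- c(tree, best_e[nxt])
    relax_from(nxt)
  }
  pos <- positions_from_tree(graph, tree, 1L)
  tile_positions(graph, pos, tree, 1L)
}

# Dijkstra from one source; deterministic lexicographic tie-breaks.
# Returns list(dist, parent_edge).
dijkstra <- function(graph, source, adj = incidence_list(graph)) {
  nv <- graph$n_vertices
  e <- graph$edges
  dist <- rep(Inf, nv)
  parent <- rep(NA_integer_, nv)
  done <- rep(FALSE, nv)
  dist[source] <- 0
  for (step in seq_len(nv)) {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]   # ties -> smallest vertex id
    done[u] <- TRUE
    for (i in adj[[u]]) {
      v <- if (e$u[i] == u) e$v[i] else e$u[i]
      if (done[v]) next
      nd <- dist[u] + e$weight[i]
      if (nd < dist[v] ||
          (nd == dist[v] && !is.na(parent[v]) &&
           u < if (e$u[parent[v]] == v) e$v[parent[v]] else e$u[parent[v]])) {
        dist[v] <- nd
        parent[v] <- i
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Global positions from a shortest path tree
#'
#' Dijkstra's algorithm is run from every vertex; the origin is the vertex
#' minimizing the sum of shortest-path weights from all other vertices (ties
#' broken by smallest (row, col)), which minimizes the total accumulated
#' edge cost and avoids an arbitrary root choice. The shortest-path tree
#' from that origin supplies the `MN - 1` links; positions are accumulated
#' along its edges and normalized to start at (0, 0).
#'
#' @param graph an `alignment_graph`.
#' @return a `tile_positions` data.frame; see [mst_positions()].
#' @export
spt_positions <- function(graph) {
  nv <- graph$n_vertices
  if (nv == 1L) return(tile_positions(graph, matrix(0, 1, 2), integer(0), 1L))
  adj <- incidence_list(graph)
  sums <- numeric(nv)
  for (s in seq_len(nv)) {
    d <- dijkstra(graph, s, adj)$dist
    if (any(!is.finite(d))) stop("alignment graph is disconnected")
    sums[s] <- sum(d)
  }
  origin <- which.min(sums)   # ties -> smallest vertex id = (row, col) order
  res <- dijkstra(graph, origin, adj)
  tree <- res$parent[!is.na(res$parent)]
  pos <- positions_from_tree(graph, tree, origin)
  tile_positions(graph, pos, tree, origin)
}

#' Shortest-path weights from every vertex to every vertex
#'
#' @param graph an `alignment_graph`.
#' @return numeric matrix `d[i, j]` = shortest-path weight between vertices.
#' @export
shortest_path_weights <- function(graph) {
  adj <- incidence_list(graph)
  t(vapply(seq_len(graph$n_vertices),
           function(s) dijkstra(graph, s, adj)$dist,
           numeric(graph$n_vertices)))
}
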