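# a link table with given matched counts (translations exact nominal)
counted_table <- function(M, N, counts, H = 100, W = 100, o = 0.3) {
  tab <- exact_link_table(nominal_truth(M, N, H, W, o), M, N)
  tab$n_matched <- as.integer(counts)
  tab
}

test_that("edge weights are normalized inverse match counts", {
  tab <- counted_table(2, 2, c(10L, 20L, 40L, 40L))
  g <- build_graph(tab)
  expect_equal(g$edges$weight[1:3], c(1.0, 0.5, 0.25))
  # all counts equal -> all weights 1
  g2 <- build_graph(counted_table(2, 2, rep(7L, 4)))
  expect_equal(g2$edges$weight, rep(1, 4))
  # sentinel count edge gets max finite weight + penalty constant
  tab$n_matched[4] <- NA_integer_
  g3 <- build_graph(tab, penalty_constant = 1)
  expect_equal(g3$edges$weight[4], 2.0)
  expect_true(all(g3$edges$weight[1:3] <= 1))
})

test_that("an unrepaired table is rejected", {
  tab <- counted_table(2, 2, rep(5L, 4))
  tab$t_x[2] <- NA_real_
  expect_error(build_graph(tab), "repair_links")
})

test_that("a single forced edge places two tiles directly", {
  tab <- exact_link_table(data.frame(row = c(0, 0), col = c(0, 1),
                                     x = c(0, 750), y = c(0, 2)), 1, 2)
  g <- build_graph(tab)
  for (pos in list(mst_positions(g), spt_positions(g))) {
    expect_equal(pos$x, c(0, 750))
    expect_equal(pos$y, c(0, 2))
    expect_length(attr(pos, "tree_edges"), 1)
  }
})

test_that("the MST avoids the heavy edge on a 2x2 grid", {
  tab <- counted_table(2, 2, c(40L, 40L, 40L, 2L))  # last edge weight 20x
  g <- build_graph(tab)
  pos <- mst_positions(g)
  tree <- attr(pos, "tree_edges")
  expect_length(tree, 3)
  expect_false(4L %in% tree)
  # oracle: enumerate all spanning trees
  expect_equal(sum(g$edges$weight[tree]), bf_mst_weight(4, g$edges))
})

test_that("MST weight matches exhaustive enumeration on 2x3 grids", {
  for (seed in 1:6) {
    set.seed(seed)
    tab <- counted_table(2, 3, sample(1:50, 7, replace = TRUE))
    g <- build_graph(tab)
    pos <- mst_positions(g)
    expect_equal(sum(g$edges$weight[attr(pos, "tree_edges")]),
                 bf_mst_weight(6, g$edges))
  }
})

test_that("SPT path weights match an all-pairs shortest-path oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    set.seed(seed)
    tab <- counted_table(3, 4, sample(1:50, 17, replace = TRUE))
    g <- build_graph(tab)
    d <- shortest_path_weights(g)
    expect_equal(d, bf_apsp(12, g$edges), tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(g$edges[, c("u", "v")],
                                        directed = FALSE,
                                        vertices = data.frame(name = 1:12))
    expect_equal(d, unname(igraph::distances(ig, weights = g$edges$weight)),
                 tolerance = 1e-12)
  }
})

test_that("with uniform weights the SPT origin is the grid center", {
  tab <- counted_table(3, 3, rep(10L, 12))
  g <- build_graph(tab)
  pos <- spt_positions(g)
  origin <- attr(pos, "origin")
  expect_equal(origin, 5L)  # vertex (1, 1) of the 3x3 grid
})

test_that("edge and tree counts follow the grid bookkeeping", {
  for (mn in list(c(2L, 2L), c(3L, 4L), c(10L, 10L))) {
    M <- mn[1]; N <- mn[2]
    tab <- exact_link_table(nominal_truth(M, N, 50, 50, 0.2), M, N)
    expect_equal(nrow(tab), 2 * M * N - (M + N))
    g <- build_graph(tab)
    expect_equal(nrow(g$edges), 2 * M * N - (M + N))
    expect_length(attr(mst_positions(g), "tree_edges"), M * N - 1)
    expect_length(attr(spt_positions(g), "tree_edges"), M * N - 1)
  }
})

test_that("exact links reproduce ground-truth positions for MST and SPT", {
  M <- 4; N <- 5; H <- 120; W <- 100; o <- 0.25
  truth <- nominal_truth(M, N, H, W, o)
  g <- build_graph(exact_link_table(truth, M, N))
  for (pos in list(mst_positions(g), spt_positions(g))) {
    expect_equal(pos$x, truth$x)
    expect_equal(pos$y, truth$y)
    # tree-edge consistency: pos(mov) - pos(ref) = edge translation
    for (i in attr(pos, "tree_edges")) {
      e <- g$edges[i, ]
      pu <- match(paste(e$u_row, e$u_col), paste(pos$row, pos$col))
      pv <- match(paste(e$v_row, e$v_col), paste(pos$row, pos$col))
      expect_equal(c(pos$x[pv] - pos$x[pu], pos$y[pv] - pos$y[pu]),
                   c(e$t_x, e$t_y))
    }
  }
})

test_that("positions are normalized to a (0, 0) origin", {
  set.seed(11)
  truth <- nominal_truth(3, 3, 100, 100, 0.3)
  truth$x <- truth$x + runif(9, -3, 3)
  truth$y <- truth$y + runif(9, -3, 3)
  g <- build_graph(exact_link_table(truth, 3, 3))
  pos <- mst_positions(g)
  expect_equal(min(pos$x), 0)
  expect_equal(min(pos$y), 0)
})
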