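test_that("texture generation is deterministic per seed and varies by seed", {
  a1 <- generate_texture_image(120, 130, seed = 5)
  a2 <- generate_texture_image(120, 130, seed = 5)
  b <- generate_texture_image(120, 130, seed = 6)
  expect_identical(a1, a2)
  expect_gte(mean(a1 != b), 0.01)
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("the resolution-target pattern is binary with empty margins", {
  img <- generate_usaf_pattern(500, 500)
  expect_true(all(img %in% c(0, 1)))
  expect_gt(mean(img), 0)            # some bars drawn
  m <- round(0.18 * 500)
  expect_true(all(img[1:m, ] == 0))  # top margin empty
  expect_true(all(img[, 1:m] == 0))
  # axis-aligned structure: bar rows contain long constant runs
  expect_identical(generate_usaf_pattern(500, 500), img)
})

test_that("grid splitting respects nominal offsets and jitter bounds", {
  o <- 0.25
  cfg <- synth_config(3, 3, o, c(100, 100), jitter_px = 4, seed = 9)
  img <- test_texture(400, 400, seed = 14)
  out <- split_image_to_grid(img, cfg)
  truth <- out$truth
  step <- round(100 * (1 - o))
  expect_equal(step, 75)
  for (r in 0:2) for (c in 0:1) {
    i <- which(truth$row == r & truth$col == c)
    j <- which(truth$row == r & truth$col == c + 1)
    expect_lte(abs((truth$x[j] - truth$x[i]) - step), 8)  # 2 * jitter
  }
  # tiles really are crops of the source at the recorded positions
  t00 <- get_tile(out$grid, 1, 2)
  i <- which(truth$row == 1 & truth$col == 2)
  expect_equal(t00, img[truth$y[i] + 1:100, truth$x[i] + 1:100])
})

test_that("an undersized source image is a hard error", {
  cfg <- synth_config(10, 10, 0.3, c(200, 200))
  expect_error(split_image_to_grid(matrix(0, 500, 500), cfg), "too small")
})

test_that("background tiles are constant before noise", {
  cfg <- synth_config(2, 2, 0.3, c(80, 80),
                      background_tiles = data.frame(row = 0, col = 1))
  img <- test_texture(200, 200, seed = 15)
  out <- split_image_to_grid(img, cfg)
  bg <- get_tile(out$grid, 0, 1)
  expect_equal(length(unique(as.vector(bg))), 1)
  expect_gt(length(unique(as.vector(get_tile(out$grid, 0, 0)))), 1)
})

test_that("shading and noise are applied per configuration", {
  img <- test_texture(200, 200, seed = 16)
  base <- split_image_to_grid(img, synth_config(2, 2, 0.3, c(80, 80)))
  shaded <- split_image_to_grid(img, synth_config(2, 2, 0.3, c(80, 80),
                                                  shading = "gaussian-vignette",
                                                  shading_amplitude = 0.3))
  g0 <- get_tile(base$grid, 0, 0)
  g1 <- get_tile(shaded$grid, 0, 0)
  ratio <- g1 / pmax(g0, 1e-9)
  expect_lte(max(ratio), 1 + 1e-9)
  expect_lt(min(ratio[g0 > 0.05]), 0.75)  # corners darkened ~30%
  noisy <- split_image_to_grid(img, synth_config(2, 2, 0.3, c(80, 80),
                                                 noise_sigma = 0.02, seed = 1))
  resid <- get_tile(noisy$grid, 0, 0) - g0
  expect_gt(stats::sd(resid), 0.01)
  expect_lt(stats::sd(resid), 0.03)
})

test_that("generate_synthetic_grid sizes the source to the grid", {
  cfg <- synth_config(3, 4, 0.3, c(60, 60), jitter_px = 2)
  syn <- generate_synthetic_grid(cfg)
  expect_equal(dim(syn$image), c(2 * 42 + 60 + 4, 3 * 42 + 60 + 4))
  expect_equal(syn$grid$M, 3)
  expect_equal(syn$grid$N, 4)
  expect_equal(nrow(syn$truth), 12)
})
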