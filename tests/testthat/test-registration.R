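# crop an overlapping west pair from a source image at a known offset
crop_west_pair <- function(img, W, H, t_x, t_y = 0) {
  ref <- img[1:H, 1:W]
  mov <- img[(1 + t_y):(H + t_y), (1 + t_x):(W + t_x)]
  list(ref = ref, mov = mov)
}

test_that("cropped pairs register to the crop offset for several overlaps", {
  img <- test_texture(500, 900, seed = 4)
  W <- 400; H <- 400
  for (o in c(0.10, 0.25, 0.30)) {
    t_x <- round(W * (1 - o))
    pr <- crop_west_pair(img, W, H, t_x)
    lk <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = o)
    expect_equal(lk$status, "valid")
    expect_equal(lk$stage_used, "strip")
    expect_lte(abs(lk$t_x - t_x), 1)
    expect_lte(abs(lk$t_y), 1)
    # oracle: exhaustive integer-shift NCC over the plausible range
    ncc <- bf_ncc_shift(pr$ref, pr$mov, (t_x - 10):(t_x + 10), -3:3)
    expect_equal(ncc$t, c(t_x, 0))
    expect_lte(abs(lk$t_x - ncc$t[1]), 1)
  }
})

test_that("north links register along the vertical axis", {
  img <- test_texture(900, 500, seed = 5)
  W <- 400; H <- 400; o <- 0.3
  t_y <- round(H * (1 - o))
  ref <- img[1:H, 1:W]
  mov <- img[(1 + t_y):(H + t_y), 1:W]
  lk <- register_pair(ref, mov, "north", overlap_fraction = o)
  expect_equal(lk$status, "valid")
  expect_lte(abs(lk$t_y - t_y), 1)
  expect_lte(abs(lk$t_x), 1)
})

test_that("strip and full-overlap stages agree on the same pair", {
  img <- test_texture(500, 900, seed = 6)
  W <- 400; H <- 400; o <- 0.25
  pr <- crop_west_pair(img, W, H, round(W * (1 - o)))
  lk_strip <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = o,
                            stages = "strip")
  lk_full <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = o,
                           stages = "full_overlap")
  expect_equal(lk_strip$status, "valid")
  expect_equal(lk_full$status, "valid")
  expect_equal(lk_full$stage_used, "full_overlap")
  expect_lte(abs(lk_strip$t_x - lk_full$t_x), 1)
  expect_lte(abs(lk_strip$t_y - lk_full$t_y), 1)
})

test_that("a shared multiplicative shading field barely moves the estimate", {
  img <- test_texture(500, 900, seed = 7)
  W <- 400; H <- 400; o <- 0.25
  t_x <- round(W * (1 - o))
  pr <- crop_west_pair(img, W, H, t_x)
  gx <- (seq_len(W) - 1) / (W - 1)
  gain <- matrix(0.7 + 0.6 * gx, H, W, byrow = TRUE)  # +-30% across the tile
  lk0 <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = o)
  lk1 <- register_pair(pr$ref * gain, pr$mov * gain, "west",
                       overlap_fraction = o)
  expect_equal(lk1$status, "valid")
  expect_lt(abs(lk1$t_x - lk0$t_x), 1)
  expect_lt(abs(lk1$t_y - lk0$t_y), 1)
})

test_that("a featureless overlap yields an invalid sentinel link", {
  img <- test_texture(400, 400, seed = 8)
  ref <- img[1:300, 1:300]
  mov <- matrix(0.5, 300, 300)
  lk <- register_pair(ref, mov, "west", overlap_fraction = 0.3)
  expect_equal(lk$status, "invalid")
  expect_true(is.na(lk$t_x) && is.na(lk$t_y) && is.na(lk$n_matched))
})

test_that("mismatched tile dimensions are a hard error", {
  expect_error(register_pair(matrix(0, 100, 100), matrix(0, 100, 90),
                             "west", overlap_fraction = 0.3),
               "dimension mismatch")
})

test_that("registration is deterministic for a fixed seed", {
  img <- test_texture(500, 900, seed = 9)
  pr <- crop_west_pair(img, 400, 400, 300)
  lk1 <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = 0.25)
  lk2 <- register_pair(pr$ref, pr$mov, "west", overlap_fraction = 0.25)
  expect_identical(lk1, lk2)
})

test_that("the stage-model filter accepts and rejects by the 2% window", {
  W <- 1000; H <- 800; o <- 0.25
  mk <- function(dir, t_x, t_y) {
    make_link <- getFromNamespace("make_link", "gridstitch")
    make_link(c(0L, 0L), if (dir == "west") c(0L, 1L) else c(1L, 0L), dir,
              t_x = t_x, t_y = t_y, n_matched = 10L, status = "valid",
              stage_used = "strip")
  }
  keep <- function(lk) {
    filter_translation(lk, W, H, o)$status == "valid"
  }
  # west: valid t_x range [730, 770], |t_y| <= 16
  expect_true(keep(mk("west", 750, 0)))      # nominal stage position
  expect_true(keep(mk("west", 730, 0)))      # exactly at the lower boundary
  expect_true(keep(mk("west", 770, 16)))     # exactly at both upper bounds
  expect_false(keep(mk("west", 700, 0)))     # below 750 - 20
  expect_false(keep(mk("west", 729.5, 0)))
  expect_false(keep(mk("west", 770.5, 0)))
  expect_false(keep(mk("west", 750, 16.5)))
  # north: valid t_y range [584, 616], |t_x| <= 20
  expect_true(keep(mk("north", 0, 600)))
  expect_true(keep(mk("north", -20, 584)))
  expect_true(keep(mk("north", 20, 616)))
  expect_false(keep(mk("north", 0, 583.5)))
  expect_false(keep(mk("north", 20.5, 600)))
  # invalidated links carry sentinels
  bad <- filter_translation(mk("west", 700, 0), W, H, o)
  expect_true(is.na(bad$t_x) && is.na(bad$n_matched))
})
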