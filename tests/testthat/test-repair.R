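# build a small link table and knock out selected links
knockout <- function(table, rows) {
  table$status[rows] <- "invalid"
  table$t_x[rows] <- NA_real_
  table$t_y[rows] <- NA_real_
  table$n_matched[rows] <- NA_integer_
  table
}

test_that("a fully valid table passes through unchanged", {
  tab <- exact_link_table(nominal_truth(3, 3, 100, 100, 0.3), 3, 3)
  expect_identical(repair_links(tab), tab)
})

test_that("invalid north links take the row mean of valid ones", {
  tab <- exact_link_table(nominal_truth(2, 3, 100, 100, 0.3), 2, 3)
  north <- which(tab$direction == "north")   # row 0: three links
  tab$t_x[north] <- c(2.0, 4.0, 0)
  tab$t_y[north] <- c(748.0, 752.0, 0)
  tab <- knockout(tab, north[3])
  rep <- repair_links(tab)
  expect_equal(rep$t_x[north[3]], 3.0)
  expect_equal(rep$t_y[north[3]], 750.0)
  expect_equal(rep$stage_used[north[3]], "repaired")
  expect_true(is.na(rep$n_matched[north[3]]))
  # valid links untouched
  expect_equal(rep$t_x[north[1:2]], c(2.0, 4.0))
})

test_that("an all-invalid row falls back to the global north mean", {
  tab <- exact_link_table(nominal_truth(3, 2, 100, 100, 0.3), 3, 2)
  north <- which(tab$direction == "north")
  # row 0 links valid with mean (1.0, 751.0); row 1 entirely invalid
  r0 <- north[tab$ref_row[north] == 0]
  r1 <- north[tab$ref_row[north] == 1]
  tab$t_x[r0] <- c(0.5, 1.5)
  tab$t_y[r0] <- c(750.0, 752.0)
  tab <- knockout(tab, r1)
  rep <- repair_links(tab)
  expect_equal(rep$t_x[r1], rep(1.0, length(r1)))
  expect_equal(rep$t_y[r1], rep(751.0, length(r1)))
})

test_that("west links repair by reference column", {
  tab <- exact_link_table(nominal_truth(3, 2, 100, 100, 0.3), 3, 2)
  west <- which(tab$direction == "west")     # column 0, one per row
  tab$t_x[west] <- c(69.0, 71.0, 0)
  tab$t_y[west] <- c(-1.0, 3.0, 0)
  tab <- knockout(tab, west[3])
  rep <- repair_links(tab)
  expect_equal(rep$t_x[west[3]], 70.0)
  expect_equal(rep$t_y[west[3]], 1.0)
})

test_that("repair is idempotent and stays in the convex hull", {
  set.seed(3)
  tab <- exact_link_table(nominal_truth(4, 4, 100, 100, 0.3), 4, 4)
  tab$t_x <- tab$t_x + runif(nrow(tab), -2, 2)
  tab$t_y <- tab$t_y + runif(nrow(tab), -2, 2)
  tab <- knockout(tab, sample(nrow(tab), 8))
  rep1 <- repair_links(tab)
  expect_true(all(is.finite(rep1$t_x) & is.finite(rep1$t_y)))
  expect_identical(repair_links(rep1), rep1)
  for (dir in c("north", "west")) {
    valid <- tab$direction == dir & tab$status == "valid"
    fixed <- rep1$direction == dir & rep1$stage_used == "repaired"
    if (!any(fixed)) next
    expect_true(all(rep1$t_x[fixed] >= min(tab$t_x[valid]) &
                      rep1$t_x[fixed] <= max(tab$t_x[valid])))
    expect_true(all(rep1$t_y[fixed] >= min(tab$t_y[valid]) &
                      rep1$t_y[fixed] <= max(tab$t_y[valid])))
  }
})

test_that("a direction with no valid link at all is unrepairable", {
  tab <- exact_link_table(nominal_truth(2, 2, 100, 100, 0.3), 2, 2)
  tab <- knockout(tab, which(tab$direction == "north"))
  expect_error(repair_links(tab), "no valid north link")
})

test_that("link tables round-trip through CSV", {
  tab <- exact_link_table(nominal_truth(3, 3, 100, 100, 0.3), 3, 3)
  tab <- knockout(tab, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_link_table(tab, path)
  back <- read_link_table(path, 3, 3)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
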