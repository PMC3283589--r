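test_that("object mean comes from the clipped seed window", {
  expect_equal(mean_object_intensity(matrix(100, 10, 10), c(4, 4), 3), 100)
  img <- matrix(c(90, 100, 110, 100, 100, 100, 90, 110, 100), 3, 3,
                byrow = TRUE)
  expect_equal(mean_object_intensity(img, c(1, 1), 3), 100)
  # corner seed with d = 3 clips to the in-bounds 2 x 2 block
  img2 <- matrix(1:16, 4, 4)
  expect_equal(mean_object_intensity(img2, c(0, 0), 3),
               mean(img2[1:2, 1:2]))
  expect_error(mean_object_intensity(img2, c(10, 1), 3), "outside")
})

test_that("node costs use nearest-neighbor lookup with clamping", {
  img <- matrix(0, 6, 6)
  img[5, 3] <- 120  # pixel (x = 2, y = 4)
  expect_equal(node_cost(img, cbind(2, 4), 100), 20)
  expect_equal(node_cost(img, cbind(2.4, 3.6), 100), 20)  # rounds to (2, 4)
  expect_equal(node_cost(img, cbind(0, 0), 0), 0)
  # out-of-bounds positions clamp to the nearest edge pixel
  img[1, 6] <- 7
  expect_equal(node_cost(img, cbind(99, -99), 0), 7)
})

test_that("terminal weights telescope back to the costs", {
  expect_equal(terminal_weights(c(5, 3, 7)), c(5, -2, 4))
  expect_equal(terminal_weights(c(4, 4, 4)), c(4, 0, 0))
  expect_equal(terminal_weights(9), 9)
  expect_error(terminal_weights(numeric(0)), "empty")
  set.seed(7)
  for (i in 1:20) {
    costs <- sample(0:50, sample(1:12, 1), replace = TRUE)
    expect_equal(cumsum(terminal_weights(costs)), as.numeric(costs))
  }
})

test_that("intra-column arcs chain each ray downward", {
  expect_equal(nrow(build_intra_arcs(4, 3)), 8)
  expect_equal(nrow(build_intra_arcs(5, 1)), 0)
  a <- build_intra_arcs(1, 5)
  expect_equal(nrow(a), 4)
  expect_equal(a$tail, 2:5)
  expect_equal(a$head, 1:4)
  expect_true(all(!is.finite(a$capacity)))
})

test_that("inter-column arcs target the clamped neighbor level", {
  a0 <- build_inter_arcs(3, 2, 0)
  expect_equal(nrow(a0), 12)
  # delta 0: same level on the neighbor ray
  lvl <- function(id, Z) (id - 1) %% Z + 1
  expect_true(all(lvl(a0$tail, 2) == lvl(a0$head, 2)))

  # bottom nodes clamp at level 1
  a1 <- build_inter_arcs(4, 3, 1)
  bottom <- a1[lvl(a1$tail, 3) == 1, ]
  expect_true(all(lvl(bottom$head, 3) == 1))

  # top node with delta 2 lands two levels down
  a2 <- build_inter_arcs(4, 4, 2)
  top <- a2[lvl(a2$tail, 4) == 4, ]
  expect_true(all(lvl(top$head, 4) == 2))
  expect_equal(nrow(a2), 2 * 4 * 4)
  expect_error(build_inter_arcs(4, 4, -1), "non-negative")
})

test_that("terminal arcs split by weight sign and keep infinite base arcs", {
  arcs <- attach_terminal_arcs(matrix(c(5, -2, 4), nrow = 1))
  s <- 4L; t <- 5L
  expect_equal(arcs$capacity[arcs$tail == s & arcs$head == 2], 2)
  expect_equal(arcs$capacity[arcs$tail == 1 & arcs$head == t], 5)
  expect_equal(arcs$capacity[arcs$tail == 3 & arcs$head == t], 4)
  expect_true(any(arcs$tail == s & arcs$head == 1 & !is.finite(arcs$capacity)))

  # zero weights produce no finite arcs, only the infinite base arcs
  zero <- attach_terminal_arcs(matrix(0, 2, 3))
  expect_true(all(!is.finite(zero$capacity)))
  expect_equal(nrow(zero), 2)
})

test_that("assembled graph has the expected arc structure", {
  img <- matrix(runif(400, 0, 255), 20, 20)
  grid <- sample_nodes(cast_rays(template_square(), c(10, 10), 6, 8), 5)
  g <- build_segmentation_graph(grid, img, delta = 2)
  expect_s3_class(g, "segmentation_graph")
  inf_arcs <- g$arcs[!is.finite(g$arcs$capacity) & g$arcs$tail <= 30, ]
  expect_equal(nrow(inf_arcs), 6 * 4 + 2 * 6 * 5)  # A_z + A_r
  expect_equal(max(c(g$arcs$tail, g$arcs$head)), 6 * 5 + 2)
  # telescoping identity on every ray
  expect_equal(t(apply(g$weight, 1, cumsum)), g$cost, tolerance = 1e-9)
  # terminal arcs have finite non-negative capacities
  fin <- g$arcs[is.finite(g$arcs$capacity), ]
  expect_true(all(fin$capacity >= 0))
  expect_true(all(fin$tail == g$source | fin$head == g$sink))
})

test_that("crossed inter-arc counts match the published cut costs", {
  expect_identical(count_crossing_arcs(2, 2, 1, 4), 2L)
  expect_identical(count_crossing_arcs(2, 3, 1, 4), 2L)
  expect_identical(count_crossing_arcs(2, 4, 1, 5), 4L)
})

test_that("directed severed-arc count follows the clamped-difference formula", {
  for (Z in c(4, 6)) {
    for (delta in 0:3) {
      for (z1 in seq_len(Z)) {
        for (z2 in seq_len(Z)) {
          expect_identical(
            count_crossing_arcs(z1, z2, delta, Z, directed = TRUE),
            as.integer(max(0, z1 - z2 - delta) + max(0, z2 - z1 - delta))
          )
        }
      }
    }
  }
})

test_that("graph exports as a readable edge list", {
  g <- graph_from_costs(rbind(c(1, 2), c(0, 3), c(2, 2)), 1)
  path <- withr::local_tempfile(fileext = ".txt")
  export_graph(g, path)
  lines <- readLines(path)
  expect_length(lines, nrow(g$arcs))
  expect_true(any(grepl("^s ", lines)))
  expect_true(any(grepl(" t ", lines)))
  expect_true(any(grepl(" inf$", lines)))
})
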