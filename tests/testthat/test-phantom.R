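test_that("rectangle phantom counts foreground and truth separately", {
  ph <- make_rectangle_phantom(phantom_spec(noise_sd = 0))
  expect_equal(sum(ph$truth), 40 * 28)
  expect_equal(sum(ph$image == 200), 40 * 28)
  expect_equal(sort(unique(as.vector(ph$image))), c(50, 200))

  # erased corner shrinks the drawn object but not the ground truth
  ph2 <- make_rectangle_phantom(phantom_spec(noise_sd = 0,
                                             missing_corners = c(br = 6)))
  expect_equal(sum(ph2$image == 200), 40 * 28 - 36)
  expect_equal(sum(ph2$truth), 40 * 28)

  # erased edge strip bookkeeping: strip of depth 2 spanning ~half the top
  ph3 <- make_rectangle_phantom(phantom_spec(
    noise_sd = 0,
    missing_edges = list(list(side = "top", from = 0.25, to = 0.5, depth = 2))))
  strip <- sum(ph2$truth) - 0  # truth unchanged
  expect_equal(sum(ph3$truth), 40 * 28)
  expect_lt(sum(ph3$image == 200), 40 * 28)

  expect_error(make_rectangle_phantom(phantom_spec(center = c(5, 5))),
               "outside the image")
})

test_that("phantom noise is reproducible, clamped and integer-valued", {
  spec <- phantom_spec(noise_sd = 25, seed = 42)
  a <- make_rectangle_phantom(spec)
  b <- make_rectangle_phantom(spec)
  expect_identical(a$image, b$image)
  expect_true(all(a$image >= 0 & a$image <= 255))
  expect_identical(a$image, round(a$image))
  # different seed, different noise
  c2 <- make_rectangle_phantom(phantom_spec(noise_sd = 25, seed = 7))
  expect_false(identical(a$image, c2$image))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_rectangle_phantom(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("vertebra phantom degenerates to the rectangle and adds neighbors", {
  spec <- phantom_spec(noise_sd = 0, concavity = 0, corner_radius = 0)
  rect <- make_rectangle_phantom(spec)
  vert <- make_vertebra_phantom(spec)
  expect_identical(vert$image, rect$image)
  expect_identical(vert$truth, rect$truth)

  conc <- make_vertebra_phantom(phantom_spec(noise_sd = 0, concavity = 4,
                                             corner_radius = 0))
  expect_lt(sum(conc$truth), sum(rect$truth))

  two <- make_vertebra_phantom(phantom_spec(noise_sd = 0, concavity = 2,
                                            corner_radius = 2,
                                            neighbor_gap = 4))
  solo <- make_vertebra_phantom(phantom_spec(noise_sd = 0, concavity = 2,
                                             corner_radius = 2))
  expect_identical(two$truth, solo$truth)  # truth is the main structure only
  expect_gt(sum(two$image == 200), sum(solo$image == 200))

  expect_error(phantom_spec(concavity = 30), "half the object width")
  expect_error(phantom_spec(fg = 100, bg = 100), "must differ")
})

test_that("rotated phantom keeps its area approximately", {
  straight <- make_vertebra_phantom(phantom_spec(noise_sd = 0, concavity = 2,
                                                 corner_radius = 2))
  rot <- make_vertebra_phantom(phantom_spec(noise_sd = 0, concavity = 2,
                                            corner_radius = 2, rotation = 20))
  expect_lt(abs(sum(rot$truth) - sum(straight$truth)) / sum(straight$truth),
            0.05)
  expect_false(identical(rot$truth, straight$truth))
})

test_that("phantom specs round-trip through key=value files", {
  spec <- phantom_spec(obj_width = 30, obj_height = 22, noise_sd = 4,
                       seed = 9, missing_corners = c(br = 5, tl = 3),
                       missing_edges = list(
                         list(side = "top", from = 0.2, to = 0.5, depth = 2)),
                       concavity = 2.5, neighbor_gap = 3)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back, spec)
  # generated images are identical either way
  expect_identical(make_rectangle_phantom(spec)$image,
                   make_rectangle_phantom(back)$image)
})
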