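test_that("pipeline segments a clean rectangle to high overlap", {
  ph <- make_rectangle_phantom(phantom_spec(noise_sd = 0))
  fit <- segment_image(ph$image, c(64, 64), template = "rectangle:40:28",
                       diameter_mm = 60)
  expect_s3_class(fit, "square_cut")
  expect_gte(dice(fit$mask, ph$truth), 0.95)

  g <- glance(fit)
  expect_equal(g$mask_pixels, sum(fit$mask))
  expect_equal(g$delta, 4L)
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  expect_equal(td$radius_raw,
               attr(fit$cut$grid, "spacing") * fit$cut$boundary)
  expect_output(print(fit), "boundary cost")
})

test_that("zero delta yields a uniformly scaled template contour", {
  ph <- sweep_phantom()
  fit <- segment_image(ph$image, c(64, 64), n_rays = 30, n_nodes = 40,
                       delta = 0, diameter_mm = 52, iterations = 0)
  fan <- cast_rays(template_square(), c(64, 64), 30, 26)
  ratio <- fit$contour$radius / fan$dist
  expect_lt(max(ratio) - min(ratio), 1e-9)
})

test_that("invalid configurations are rejected up front", {
  img <- matrix(100, 20, 20)
  expect_error(segment_image(img, c(50, 5)), "outside the image")
  expect_error(segment_image(img, c(5, 5), n_rays = 2), "at least 3")
  expect_error(segment_image(img, c(5, 5), n_nodes = 0), "at least 1")
  expect_error(segment_image(img, c(5, 5), delta = -1), "non-negative")
  expect_error(segment_image(img, c(5, 5), diameter_mm = 0), "positive")
  expect_error(segment_image(img, c(5, 5), spacing_mm = -1), "positive")
})

test_that("file-based run matches the in-memory pipeline bit for bit", {
  dir <- withr::local_tempdir()
  ph <- run_phantom("rectangle", phantom_spec(noise_sd = 0),
                    image_path = file.path(dir, "ph.png"),
                    truth_path = file.path(dir, "truth.png"))
  fit_file <- run_segment(file.path(dir, "ph.png"), c(64, 64),
                          mask_path = file.path(dir, "mask.png"),
                          contour_path = file.path(dir, "contour.txt"),
                          report_path = file.path(dir, "report.json"),
                          template = "rectangle:40:28", diameter_mm = 60)
  fit_mem <- segment_image(ph$image, c(64, 64), template = "rectangle:40:28",
                           diameter_mm = 60)
  expect_identical(fit_file$cut$boundary, fit_mem$cut$boundary)
  expect_identical(fit_file$mask, fit_mem$mask)
  expect_identical(read_mask(file.path(dir, "mask.png")), fit_mem$mask)

  # the run report reproduces the run exactly
  rep <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  refit <- segment_image(ph$image, rep$seed,
                         template = polygon_template(rep$template_vertices),
                         n_rays = rep$n_rays, n_nodes = rep$n_nodes,
                         delta = rep$delta, diameter_mm = rep$diameter_mm,
                         spacing_mm = rep$spacing_mm, window = rep$window,
                         kernel = rep$kernel, iterations = rep$iterations)
  expect_identical(refit$mask, fit_file$mask)
  expect_equal(rep$boundary_nodes, fit_mem$cut$boundary)

  ev <- run_evaluate(file.path(dir, "mask.png"), file.path(dir, "truth.png"),
                     out_csv = file.path(dir, "eval.csv"))
  expect_equal(ev$dsc, dice(fit_mem$mask, ph$truth))
  back <- utils::read.csv(file.path(dir, "eval.csv"))
  expect_equal(back$dsc, ev$dsc)
})

test_that("command-line interface dispatches and reports error codes", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  img <- file.path(dir, "ph.pgm")
  truth <- file.path(dir, "truth.pgm")
  suppressMessages({
    st <- cli_main(c("phantom", "--kind", "rectangle", "-o", img,
                     "--truth", truth))
  })
  expect_identical(st, 0L)
  expect_true(file.exists(img) && file.exists(truth))

  mask <- file.path(dir, "mask.pgm")
  suppressMessages({
    st2 <- cli_main(c("segment", "-i", img, "--seed-x", "64", "--seed-y", "64",
                      "--template", "rectangle:40:28", "--diameter-mm", "60",
                      "--spacing-mm", "1", "-o", mask,
                      "--report", file.path(dir, "rep.json")))
  })
  expect_identical(st2, 0L)
  # the CLI writes the same mask as the library call on the same file
  fit <- run_segment(img, c(64, 64), template = "rectangle:40:28",
                     diameter_mm = 60)
  expect_identical(read_mask(mask), fit$mask)

  suppressMessages({
    st3 <- cli_main(c("evaluate", "--auto", mask, "--ref", truth,
                      "-o", file.path(dir, "eval.csv")))
  })
  expect_identical(st3, 0L)

  suppressMessages({
    expect_identical(cli_main(c("segment", "-i", "missing.png",
                                "--seed-x", "1", "--seed-y", "1")), 2L)
    expect_identical(cli_main(c("segment", "-i", img, "--seed-x", "999",
                                "--seed-y", "1")), 3L)
    expect_identical(cli_main(c("segment", "-i", img, "--seed-x", "64",
                                "--seed-y", "64", "--rays", "2")), 4L)
  })
})
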