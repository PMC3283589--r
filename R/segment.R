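#' Segment a 2D grayscale image with a template-constrained graph cut
#'
#' Runs the full pipeline: normalize the template, cast rays from the seed,
#' sample the non-uniform node grid, build the graph from intensity costs,
#' solve the minimum s-t cut, smooth the resulting contour and rasterize the
#' binary mask.
#'
#' @param image numeric intensity matrix (row = y, column = x, 0-based
#'   coordinates).
#' @param seed numeric `c(x, y)` seed point inside the object.
#' @param template a [polygon_template], or a character spec accepted by
#'   [read_template()] (default `"square"`).
#' @param n_rays rays cast from the seed (default 30).
#' @param n_nodes nodes sampled per ray (default 30).
#' @param delta integer stiffness; 0 forces the exact template shape,
#'   larger values allow more flexible contours (default 4).
#' @param diameter_mm template diameter in mm (default 40); the template's
#'   unit radius maps to `diameter_mm / 2 / spacing_mm` pixels.
#' @param spacing_mm isotropic pixel spacing in mm (default 1).
#' @param window side length `d` of the seed window for the object-mean
#'   estimate (default 5 pixels).
#' @param kernel,iterations contour smoothing (default `[0.25 0.5 0.25]`,
#'   one iteration; `iterations = 0` disables smoothing).
#' @return An object of class `square_cut`: list with `contour` (tibble from
#'   [boundary_to_contour()]), `mask` (0/1 matrix), `cut` (the
#'   `cut_boundary`), `graph` (the `segmentation_graph`), and `config` (all
#'   effective parameters). Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' ph <- make_rectangle_phantom(phantom_spec(noise_sd = 0))
#' fit <- segment_image(ph$image, seed = c(64, 64), diameter_mm = 60)
#' glance(fit)
#' dice(fit$mask, ph$truth)
#' @export
segment_image <- function(image, seed, template = "square",
                          n_rays = 30L, n_nodes = 30L, delta = 4L,
                          diameter_mm = 40, spacing_mm = 1, window = 5L,
                          kernel = c(0.25, 0.5, 0.25), iterations = 1L) {
  if (is.character(template)) template <- read_template(template)
  if (n_rays < 3L) stop("`n_rays` must be at least 3", call. = FALSE)
  if (n_nodes < 1L) stop("`n_nodes` must be at least 1", call. = FALSE)
  if (delta < 0L) stop("`delta` must be non-negative", call. = FALSE)
  if (diameter_mm <= 0) stop("`diameter_mm` must be positive", call. = FALSE)
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive", call. = FALSE)
  if (seed[1L] < 0 || seed[1L] >= ncol(image) ||
      seed[2L] < 0 || seed[2L] >= nrow(image)) {
    stop("seed point lies outside the image", call. = FALSE)
  }
  scale <- diameter_mm / 2 / spacing_mm
  fan <- cast_rays(template, seed, n_rays, scale)
  grid <- sample_nodes(fan, n_nodes)
  graph <- build_segmentation_graph(grid, image, delta, window = window)
  cut <- solve_min_cut(graph)
  contour <- boundary_to_contour(cut, kernel, iterations)
  mask <- contour_to_mask(contour, ncol(image), nrow(image))
  structure(
    list(contour = contour, mask = mask, cut = cut, graph = graph,
         config = list(template = template, seed = as.numeric(seed),
                       n_rays = n_rays, n_nodes = n_nodes,
                       delta = as.integer(delta), diameter_mm = diameter_mm,
                       spacing_mm = spacing_mm, window = window,
                       kernel = kernel, iterations = iterations,
                       mean_intensity = graph$mean_intensity)),
    class = "square_cut"
  )
}

#' @export
print.square_cut <- function(x, ...) {
  cfg <- x$config
  cat("Template graph-cut segmentation\n")
  cat(sprintf("  rays: %d  nodes/ray: %d  delta: %d  diameter: %g mm\n",
              cfg$n_rays, cfg$n_nodes, cfg$delta, cfg$diameter_mm))
  cat(sprintf("  seed: (%g, %g)  object mean intensity: %.2f\n",
              cfg$seed[1L], cfg$seed[2L], cfg$mean_intensity))
  cat(sprintf("  boundary cost: %g  mask pixels: %d\n",
              x$cut$total_cost, sum(x$mask)))
  invisible(x)
}

#' Tidy a segmentation fit into one row per ray
#'
#' @param x a `square_cut` from [segment_image()].
#' @param ... unused.
#' @return Tibble with columns `ray`, `angle`, `boundary_node`,
#'   `boundary_cost`, `radius_raw`, `radius`, `x`, `y`.
#' @method tidy square_cut
#' @export
tidy.square_cut <- function(x, ...) {
  dirs <- attr(x$cut$grid, "directions")
  cont <- x$contour
  tibble::tibble(
    ray = cont$ray,
    angle = atan2(dirs[, "dy"], dirs[, "dx"]) %% (2 * pi),
    boundary_node = x$cut$boundary,
    boundary_cost = x$graph$cost[cbind(seq_len(x$cut$n_rays), x$cut$boundary)],
    radius_raw = cont$radius_raw,
    radius = cont$radius,
    x = cont$x,
    y = cont$y
  )
}

#' One-row summary of a segmentation fit
#'
#' @inheritParams tidy.square_cut
#' @return Tibble with columns `n_rays`, `n_nodes`, `delta`, `total_cost`,
#'   `mean_intensity`, `mask_pixels`, `mask_area_mm2`.
#' @method glance square_cut
#' @export
glance.square_cut <- function(x, ...) {
  tibble::tibble(
    n_rays = x$config$n_rays,
    n_nodes = x$config$n_nodes,
    delta = x$config$delta,
    total_cost = x$cut$total_cost,
    mean_intensity = x$config$mean_intensity,
    mask_pixels = sum(x$mask),
    mask_area_mm2 = sum(x$mask) * x$config$spacing_mm^2
  )
}

#' Plot a segmentation fit over its image
#'
#' Gray raster of the segmented image with the closed contour and the seed
#' point overlaid.
#'
#' @param object a `square_cut`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot square_cut
#' @export
autoplot.square_cut <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(0:(ncol(object$mask) - 1L), each = nrow(object$mask)),
    y = rep(0:(nrow(object$mask) - 1L), times = ncol(object$mask)),
    mask = as.vector(object$mask) > 0
  )
  cont <- dplyr::bind_rows(object$contour, object$contour[1L, ])
  seed <- object$config$seed
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$mask)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey15", `TRUE` = "grey70"),
                               guide = "none") +
    ggplot2::geom_path(data = cont,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       color = "red", linewidth = 0.8) +
    ggplot2::annotate("point", x = seed[1L], y = seed[2L],
                      color = "cyan", size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot an intensity image with an optional contour overlay
#'
#' @param image numeric intensity matrix.
#' @param contour optional data frame with `x`, `y` columns (closed for
#'   plotting).
#' @return A ggplot object.
#' @export
plot_gray_image <- function(image, contour = NULL) {
  df <- tibble::tibble(
    x = rep(0:(ncol(image) - 1L), each = nrow(image)),
    y = rep(0:(nrow(image) - 1L), times = ncol(image)),
    intensity = as.vector(image)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$x, y = .data$y,
                                      fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(contour)) {
    cont <- dplyr::bind_rows(contour, contour[1L, ])
    p <- p + ggplot2::geom_path(data = cont,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                color = "red", linewidth = 0.8)
  }
  p
}
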