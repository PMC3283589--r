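#' Intersect a ray with a closed polygon
#'
#' Computes the distance from `origin` along `direction` to the nearest
#' crossing with the closed polygon outline (each edge is a straight segment
#' between consecutive vertices; the outline closes from the last vertex back
#' to the first). Line-line intersection per edge; the smallest positive ray
#' parameter wins, so for non-convex outlines the nearest hit is returned.
#'
#' @param origin numeric `c(x, y)` ray origin.
#' @param direction numeric `c(x, y)`, need not be unit length; the returned
#'   distance is in units of `direction`'s length.
#' @param template a [polygon_template] (or any two-column vertex matrix).
#' @return The smallest positive ray parameter at which the ray crosses the
#'   outline.
#' @export
intersect_ray_polygon <- function(origin, direction, template) {
  v <- if (is.data.frame(template) && all(c("x", "y") %in% names(template))) {
    cbind(template$x, template$y)
  } else {
    as.matrix(template)[, 1:2, drop = FALSE]
  }
  if (sum(direction^2) == 0) stop("ray direction must be non-zero", call. = FALSE)
  p <- v
  q <- v[c(2:nrow(v), 1L), , drop = FALSE]
  ex <- q[, 1L] - p[, 1L]
  ey <- q[, 2L] - p[, 2L]
  # solve origin + t*d = p + u*e  for each edge
  det <- direction[1L] * (-ey) - direction[2L] * (-ex)
  rx <- p[, 1L] - origin[1L]
  ry <- p[, 2L] - origin[2L]
  ok <- abs(det) > 1e-14
  t_par <- (rx * (-ey) + ry * ex) / det
  u_par <- (direction[1L] * ry - direction[2L] * rx) / det
  hit <- ok & t_par > 1e-12 & u_par >= -1e-12 & u_par <= 1 + 1e-12
  if (!any(hit)) {
    stop("ray does not intersect the template outline; ",
         "the template must enclose its centroid", call. = FALSE)
  }
  min(t_par[hit])
}

#' Cast equiangular rays from a seed point through a template
#'
#' Sends `n_rays` rays radially from the seed point. Ray `r` points at angle
#' `2*pi*(r-1)/n_rays` from the +x axis (counterclockwise); each ray's
#' intersection distance with the normalized template outline is recorded.
#' The template sits centered at the seed, scaled by `scale` pixels (the
#' physical half-diameter), so ray `r` meets the scaled outline at
#' `scale * dist[r]` pixels from the seed.
#'
#' @param template a [polygon_template].
#' @param seed numeric `c(x, y)` seed point in pixel coordinates (0-based,
#'   x = column, y = row).
#' @param n_rays number of rays (>= 3).
#' @param scale template half-diameter in pixels (> 0); the normalized
#'   template's unit radius maps to this many pixels.
#' @return A tibble of class `ray_fan` with columns `ray` (1..n_rays),
#'   `angle` (radians), `dx`, `dy` (unit direction) and `dist` (template
#'   intersection distance in normalized units, in (0, 1]). Attributes `seed`
#'   and `scale` carry the placement.
#' @export
cast_rays <- function(template, seed, n_rays, scale) {
  stopifnot(length(seed) == 2L, is.finite(seed))
  if (n_rays < 3L) stop("`n_rays` must be at least 3", call. = FALSE)
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  angle <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  dx <- cos(angle)
  dy <- sin(angle)
  dist <- vapply(seq_len(n_rays), function(r) {
    intersect_ray_polygon(c(0, 0), c(dx[r], dy[r]), template)
  }, numeric(1L))
  out <- tibble::tibble(ray = seq_len(n_rays), angle = angle,
                        dx = dx, dy = dy, dist = dist)
  attr(out, "seed") <- as.numeric(seed)
  attr(out, "scale") <- as.numeric(scale)
  class(out) <- c("ray_fan", class(out))
  out
}

#' Sample graph nodes along a ray fan
#'
#' Places `n_nodes` nodes on every ray. The spacing on ray `r` is
#' `scale * dist[r] / n_nodes`, so node `z` (1-based) sits at radius
#' `z * spacing[r]`: every ray carries the same number of nodes, the first
#' node is one spacing away from the seed, and the last node lies exactly on
#' the scaled template outline. Rays that meet the outline closer to the
#' centroid get proportionally tighter node spacing — the non-uniform,
#' non-equidistant sampling that encodes the shape prior.
#'
#' @param fan a `ray_fan` from [cast_rays()].
#' @param n_nodes nodes per ray (>= 1).
#' @return A tibble of class `ray_node_grid` with columns `ray`, `node`
#'   (1..n_nodes), `radius` (pixels) and `x`, `y` (pixel coordinates).
#'   Attributes: `seed`, `scale`, `n_rays`, `n_nodes`, `spacing` (per-ray
#'   node spacing in pixels).
#' @export
sample_nodes <- function(fan, n_nodes) {
  if (n_nodes < 1L) stop("`n_nodes` must be at least 1", call. = FALSE)
  seed <- attr(fan, "seed")
  scale <- attr(fan, "scale")
  spacing <- scale * fan$dist / n_nodes
  grid <- tibble::tibble(
    ray = rep(fan$ray, each = n_nodes),
    node = rep(seq_len(n_nodes), times = nrow(fan)),
    radius = rep(spacing, each = n_nodes) * rep(seq_len(n_nodes), times = nrow(fan))
  )
  grid$x <- seed[1L] + rep(fan$dx, each = n_nodes) * grid$radius
  grid$y <- seed[2L] + rep(fan$dy, each = n_nodes) * grid$radius
  attr(grid, "seed") <- seed
  attr(grid, "scale") <- scale
  attr(grid, "n_rays") <- nrow(fan)
  attr(grid, "n_nodes") <- as.integer(n_nodes)
  attr(grid, "spacing") <- spacing
  attr(grid, "directions") <- cbind(dx = fan$dx, dy = fan$dy)
  class(grid) <- c("ray_node_grid", class(grid))
  grid
}
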