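#' Smooth a closed contour's radii with a circular kernel
#'
#' Applies a 3-tap circular convolution to the per-ray radial distances:
#' `radii'[r] = k[1]*radii[r-1] + k[2]*radii[r] + k[3]*radii[r+1]` (indices
#' wrap around), repeated `iterations` times. The default kernel
#' `[0.25 0.5 0.25]` with one iteration is the reference setting. Because the
#' kernel weights sum to one, the mean radius is conserved and the maximum
#' radius can never grow.
#'
#' @param radii numeric vector of radial distances, one per ray (length >= 3).
#' @param kernel numeric length-3 kernel summing to 1.
#' @param iterations how many times to apply the kernel (0 = no-op).
#' @return Smoothed radii, same length.
#' @export
smooth_contour <- function(radii, kernel = c(0.25, 0.5, 0.25), iterations = 1L) {
  if (length(radii) < 3L) stop("need at least 3 radii", call. = FALSE)
  if (length(kernel) != 3L || abs(sum(kernel) - 1) > 1e-9) {
    stop("`kernel` must have 3 weights summing to 1", call. = FALSE)
  }
  if (iterations < 0L) stop("`iterations` must be non-negative", call. = FALSE)
  for (i in seq_len(iterations)) {
    # stats::filter with sides = 2 computes k[1]*x[t+1] + k[2]*x[t] + k[3]*x[t-1];
    # flip so k[1] multiplies the previous ray
    radii <- as.numeric(stats::filter(radii, rev(kernel), sides = 2L,
                                      circular = TRUE))
  }
  radii
}

#' Convert a cut boundary into a contour
#'
#' Maps the per-ray boundary node levels of a [solve_min_cut()] result to
#' radial distances and pixel coordinates, optionally smoothing the radii
#' first.
#'
#' @param cut a `cut_boundary` whose graph was built from a `ray_node_grid`.
#' @param kernel,iterations smoothing parameters for [smooth_contour()];
#'   `iterations = 0` returns the raw node positions.
#' @return A tibble of class `contour` with columns `ray`, `radius_raw`,
#'   `radius`, `x`, `y`; attribute `seed` carries the contour's center.
#' @export
boundary_to_contour <- function(cut, kernel = c(0.25, 0.5, 0.25),
                                iterations = 1L) {
  grid <- cut$grid
  if (is.null(grid)) {
    stop("this cut_boundary carries no node grid (cost-table graph)", call. = FALSE)
  }
  spacing <- attr(grid, "spacing")
  dirs <- attr(grid, "directions")
  seed <- attr(grid, "seed")
  radius_raw <- spacing * cut$boundary
  radius <- smooth_contour(radius_raw, kernel, iterations)
  out <- tibble::tibble(
    ray = seq_len(cut$n_rays),
    radius_raw = radius_raw,
    radius = radius,
    x = seed[1L] + dirs[, "dx"] * radius,
    y = seed[2L] + dirs[, "dy"] * radius
  )
  attr(out, "seed") <- seed
  class(out) <- c("contour", class(out))
  out
}

#' Rasterize a closed contour into a binary mask
#'
#' Fills the closed polygon obtained by connecting consecutive contour points
#' (and the last back to the first). A pixel is set to 1 when its center lies
#' inside the polygon under the even-odd rule; centers lying exactly on an
#' edge are included. Degenerate (zero-area) contours yield an all-zero mask
#' with a warning.
#'
#' @param contour data frame with columns `x`, `y` (0-based pixel
#'   coordinates), at least 3 rows.
#' @param width,height mask dimensions in pixels.
#' @return Integer 0/1 matrix of size `height` x `width` (row = y, col = x).
#' @export
contour_to_mask <- function(contour, width, height) {
  px <- contour$x
  py <- contour$y
  if (length(px) < 3L) stop("need at least 3 contour points", call. = FALSE)
  area2 <- abs(sum(px * py[c(2:length(py), 1L)] - px[c(2:length(px), 1L)] * py))
  if (area2 < 1e-12) {
    warning("degenerate zero-area contour; returning an empty mask")
    return(matrix(0L, nrow = height, ncol = width))
  }
  cx <- rep(0:(width - 1L), each = height)
  cy <- rep(0:(height - 1L), times = width)
  inside <- points_in_polygon(cx, cy, px, py)
  matrix(as.integer(inside), nrow = height, ncol = width)
}

# Even-odd rule with deterministic edge handling: a point exactly on an edge
# is inside. Vectorized over points; loops over polygon edges.
points_in_polygon <- function(qx, qy, px, py, eps = 1e-9) {
  n <- length(px)
  inside <- rep(FALSE, length(qx))
  on_edge <- rep(FALSE, length(qx))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # point-on-segment test
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((qx - xi) * dx + (qy - yi) * dy) / len2))
      d2 <- (xi + tt * dx - qx)^2 + (yi + tt * dy - qy)^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((qx - xi)^2 + (qy - yi)^2 <= eps^2)
    }
    # even-odd crossing test (half-open rule on y to count shared vertices once)
    crosses <- ((yi > qy) != (yj > qy))
    if (any(crosses)) {
      xcross <- xi + (qy - yi) * dx / (yj - yi)
      inside <- xor(inside, crosses & (qx < xcross))
    }
    j <- i
  }
  inside | on_edge
}
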